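#' Fit the ribosome turnover number to observed expression ratios
#'
#' Fits the single adjustable parameter `k_cat` of the growth law to a table
#' of observed expression ratios by bounded least squares on the ratio
#' scale. During the fit, `k_on` is held at its diffusion-limited value and
#' `[P]` at the value in `params` (they are species constants, not fitted);
#' `K_m` does not enter the square-root form of the law at all.
#'
#' Observations may be molar tRNA-per-ribosome ratios
#' (`units = "molar_tc_per_ribosome"`) or tRNA/rRNA mass ratios
#' (`units = "mass_trna_per_rrna"`); the model curve is scaled by
#' `m_tRNA/m_rRNA` for the latter. All observations must share one units
#' flag.
#'
#' @param observations data.frame with columns `mu` (h^-1), `ratio` (> 0)
#'   and optionally `units` (single flag, default molar).
#' @param params a [translation_params()] template supplying `a`, `k_on`,
#'   `P_conc`, masses and `k_deg`.
#' @param bounds search interval for `k_cat` (s^-1).
#' @param log_scale fit on log(ratio) instead of the ratio scale
#'   (off by default).
#' @return object of class `"kcat_fit"`: list with `k_cat_hat`, `sse`, `r2`
#'   (squared Pearson correlation of observed and fitted), `nrmse`, `n_obs`,
#'   `units`, `fitted` (the fitted curve at the observed `mu`).
#' @export
fit_kcat <- function(observations, params,
                     bounds = c(0.1, 200), log_scale = FALSE) {
  stopifnot(inherits(params, "translation_params"))
  if (!all(c("mu", "ratio") %in% names(observations)))
    stop("observations need columns 'mu' and 'ratio'", call. = FALSE)
  obs <- observations
  if (nrow(obs) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(obs$mu <= 0) || any(obs$ratio <= 0))
    stop("mu and ratio must be > 0", call. = FALSE)
  if (length(unique(obs$mu)) < 2L)
    stop("observations at a single growth rate cannot constrain k_cat",
         call. = FALSE)
  units <- if ("units" %in% names(obs)) unique(obs$units) else
    "molar_tc_per_ribosome"
  if (length(units) != 1L)
    stop("mixed units in observations; fit one units flag at a time",
         call. = FALSE)
  if (!units %in% c("molar_tc_per_ribosome", "mass_trna_per_rrna"))
    stop("unknown units flag: ", units, call. = FALSE)
  scale <- if (units == "mass_trna_per_rrna") params$m_tRNA / params$m_rRNA else 1

  model <- function(k_cat) {
    optimal_tc_per_ribosome(obs$mu, params, k_cat = k_cat) * scale
  }
  objective <- if (log_scale) {
    function(k) sum((log(model(k)) - log(obs$ratio))^2)
  } else {
    function(k) sum((model(k) - obs$ratio)^2)
  }
  opt <- stats::optimize(objective, interval = bounds, tol = 1e-6)
  k_hat <- opt$minimum
  # reject pile-ups at the bounds as non-convergence
  if (k_hat <= bounds[1] + 1e-3 || k_hat >= bounds[2] - 1e-3)
    stop(sprintf("k_cat fit did not converge inside bounds (%g, %g)",
                 bounds[1], bounds[2]), call. = FALSE)
  fitted <- model(k_hat)
  structure(list(
    k_cat_hat = k_hat,
    sse = sum((fitted - obs$ratio)^2),
    r2 = stats::cor(obs$ratio, fitted)^2,
    nrmse = nrmse(obs$ratio, fitted),
    n_obs = nrow(obs),
    units = units,
    fitted = fitted), class = "kcat_fit")
}

#' @export
print.kcat_fit <- function(x, ...) {
  cat(sprintf("<kcat_fit> k_cat = %.2f s^-1 on %d observations (%s): r2 = %.3f, NRMSE = %.3f\n",
              x$k_cat_hat, x$n_obs, x$units, x$r2, x$nrmse))
  invisible(x)
}

#' Effective ribosome turnover number
#'
#' From the steady-state balance `mu [P] = k_eff [R]`:
#' `k_eff = (mu/3600) P_conc / rib_conc` in s^-1. An independent,
#' measurement-based estimate to compare with the fitted `k_cat`.
#'
#' @param mu growth rate (h^-1).
#' @param P_conc protein concentration (uM residues).
#' @param rib_conc ribosome concentration (uM).
#' @export
effective_kcat <- function(mu, P_conc, rib_conc) {
  if (any(mu < 0) || any(P_conc <= 0)) stop("mu must be >= 0 and P_conc > 0",
                                            call. = FALSE)
  if (any(rib_conc <= 0)) stop("'rib_conc' must be > 0", call. = FALSE)
  (mu / 3600) * P_conc / rib_conc
}

#' Normalized root-mean-square error
#'
#' RMSE of `predicted - observed`, divided by the mean of the observed
#' values.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch", call. = FALSE)
  if (length(observed) < 1L) stop("need at least one value", call. = FALSE)
  m <- mean(observed)
  if (m == 0) stop("observed mean is zero; NRMSE undefined", call. = FALSE)
  sqrt(mean((predicted - observed)^2)) / m
}

#' Pearson and Spearman correlations with p-values
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `pearson_r`, `pearson_r2`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`.
#' @export
correlation_suite <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate),
       pearson_r2 = unname(pe$estimate)^2,
       pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate),
       spearman_p = sp$p.value)
}
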