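#' Kinetic and mass parameters of the coarse-grained translation model
#'
#' Bundles the molecular masses and Michaelis-Menten kinetic constants of the
#' coarse-grained elongation model in which the active ribosome consumes
#' ternary complexes (TC; EF-Tu·GTP·aminoacyl-tRNA) as its substrate. The
#' dimensionless constants `a = m_R/m_TC` (ribosome/TC mass ratio) and
#' `r = a * m_tRNA/m_rRNA` (tRNA mass fraction of a TC over the rRNA mass
#' fraction of the ribosome) are derived from the masses.
#'
#' Units are fixed at the public interface: masses in kDa, rates in s^-1
#' (`k_deg` in h^-1), concentrations in uM, `k_on` in uM^-1 s^-1. Growth
#' rates are accepted in h^-1 throughout the package and converted
#' internally.
#'
#' @param m_R ribosome molecular mass (kDa).
#' @param m_TC ternary-complex molecular mass (kDa).
#' @param m_tRNA tRNA molecular mass (kDa).
#' @param m_rRNA total rRNA mass per ribosome (kDa).
#' @param k_cat ribosome turnover number (s^-1); `NA` allowed when only the
#'   mass constants are needed.
#' @param K_m Michaelis constant of the ribosome for TC (uM). When omitted
#'   it is derived as `k_cat/k_on`; when given it is validated against that
#'   approximation (a conflict above 1 percent warns and the explicit value
#'   wins).
#' @param k_on diffusion-limited TC-ribosome binding constant (uM^-1 s^-1).
#' @param P_conc total cellular protein concentration in amino-acid
#'   residues (uM).
#' @param k_deg first-order protein degradation rate (h^-1), default 0.
#'
#' @return An object of class `"translation_params"`: a list with the fields
#'   above plus the derived ratios `a` and `r`.
#' @seealso [default_ecoli_params()], [default_yeast_mass_params()]
#' @export
translation_params <- function(m_R, m_TC, m_tRNA, m_rRNA,
                               k_cat = NA_real_, K_m = NA_real_,
                               k_on = NA_real_, P_conc = NA_real_,
                               k_deg = 0) {
  masses <- c(m_R = m_R, m_TC = m_TC, m_tRNA = m_tRNA, m_rRNA = m_rRNA)
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all molecular masses must be strictly positive", call. = FALSE)
  for (nm in c("k_cat", "K_m", "k_on", "P_conc")) {
    val <- get(nm)
    if (!is.na(val) && val <= 0)
      stop(sprintf("'%s' must be strictly positive when set", nm), call. = FALSE)
  }
  if (is.na(k_deg) || k_deg < 0)
    stop("'k_deg' must be >= 0", call. = FALSE)

  a <- m_R / m_TC
  r <- a * m_tRNA / m_rRNA

  if (is.na(K_m) && !is.na(k_cat) && !is.na(k_on)) {
    K_m <- k_cat / k_on
  } else if (!is.na(K_m) && !is.na(k_cat) && !is.na(k_on)) {
    K_m_implied <- k_cat / k_on
    if (abs(K_m - K_m_implied) / K_m_implied > 0.01)
      warning(sprintf(
        "explicit K_m = %.4g uM deviates from k_cat/k_on = %.4g uM by more than 1%%; keeping the explicit K_m",
        K_m, K_m_implied), call. = FALSE)
  }

  structure(
    list(m_R = m_R, m_TC = m_TC, m_tRNA = m_tRNA, m_rRNA = m_rRNA,
         a = a, r = r,
         k_cat = k_cat, K_m = K_m, k_on = k_on,
         P_conc = P_conc, k_deg = k_deg),
    class = "translation_params")
}

#' @export
print.translation_params <- function(x, ...) {
  cat("Coarse-grained translation parameters\n")
  cat(sprintf("  masses (kDa): ribosome %.1f, TC %.1f, tRNA %.1f, rRNA %.1f\n",
              x$m_R, x$m_TC, x$m_tRNA, x$m_rRNA))
  cat(sprintf("  a = m_R/m_TC = %.3f, r = a*m_tRNA/m_rRNA = %.3f\n", x$a, x$r))
  cat(sprintf("  k_cat = %s s^-1, K_m = %s uM, k_on = %s uM^-1 s^-1\n",
              format(x$k_cat), format(x$K_m), format(x$k_on)))
  cat(sprintf("  [P] = %s uM residues, k_deg = %g h^-1\n",
              format(x$P_conc), x$k_deg))
  invisible(x)
}

#' Default E. coli translation parameters
#'
#' Parameter set for *Escherichia coli*: ribosome mass 2307.0 kDa, TC mass
#' 69.6 kDa (so `a` = 33.1), tRNA 25.8 kDa, rRNA 1480 kDa (so `r` = 0.58);
#' `k_cat` = 22 s^-1 (maximal observed translation rate), `K_m` = 102 uM
#' (34 expressed tRNA species x 3 uM per single TC), diffusion-limited
#' `k_on` = 0.216 uM^-1 s^-1 (= k_cat/K_m), and a total protein
#' concentration of 1.16e6 uM amino-acid residues.
#'
#' @param k_deg protein degradation rate (h^-1); default 0. A typical
#'   measured E. coli range is 0.02-0.04 h^-1.
#' @return A [translation_params()] object.
#' @export
default_ecoli_params <- function(k_deg = 0) {
  translation_params(m_R = 2307.0, m_TC = 69.6, m_tRNA = 25.8, m_rRNA = 1480,
                     k_cat = 22, K_m = 102, k_on = 0.216,
                     P_conc = 1.16e6, k_deg = k_deg)
}

#' Default S. cerevisiae mass parameters
#'
#' Eukaryotic mass constants from *Saccharomyces cerevisiae* sequence data:
#' ribosome 3044.4 kDa, TC 75.6 kDa, tRNA 25.6 kDa, rRNA 1750 kDa, giving
#' `a` = 40.3 and `r` = 0.59. Kinetic fields are left unset; only the mass
#' ratios are needed to rescale the growth law for eukaryotic microbes.
#'
#' @return A [translation_params()] object with `k_cat`, `K_m`, `k_on`,
#'   `P_conc` set to `NA`.
#' @export
default_yeast_mass_params <- function() {
  translation_params(m_R = 3044.4, m_TC = 75.6, m_tRNA = 25.6, m_rRNA = 1750)
}

#' Read / write parameter sets as flat key = value files
#'
#' A minimal flat config dialect (one `key = value` per line, `#` comments,
#' keys exactly the field names of [translation_params()]) so parameter sets
#' can be versioned alongside analyses.
#'
#' @param path file path.
#' @return `read_params()` returns a [translation_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric parameter value in ", path, call. = FALSE)
  allowed <- c("m_R", "m_TC", "m_tRNA", "m_rRNA", "k_cat", "K_m", "k_on",
               "P_conc", "k_deg")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- as.list(vals)
  names(args) <- keys
  do.call(translation_params, args)
}

#' @rdname read_params
#' @param params a [translation_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "translation_params"))
  keys <- c("m_R", "m_TC", "m_tRNA", "m_rRNA", "k_cat", "K_m", "k_on",
            "P_conc", "k_deg")
  vals <- unlist(params[keys])
  keep <- !is.na(vals)
  writeLines(sprintf("%s = %.15g", keys[keep], vals[keep]), path)
  invisible(path)
}
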