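#' Protein synthesis flux at a given growth rate
#'
#' In balanced exponential growth the protein production rate must match
#' dilution (plus degradation): `v = (mu + k_deg) * [P]`, with the rate
#' converted from h^-1 to s^-1.
#'
#' @param mu growth rate (h^-1), vectorised.
#' @param params a [translation_params()] object with `P_conc` set.
#' @return flux in uM amino acids s^-1.
#' @export
protein_synthesis_flux <- function(mu, params) {
  stopifnot(inherits(params, "translation_params"))
  if (any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  if (is.na(params$P_conc)) stop("'P_conc' is not set in params", call. = FALSE)
  (mu + params$k_deg) / 3600 * params$P_conc
}

#' Mass-optimal ternary-complex concentration
#'
#' The TC concentration minimizing the combined mass density
#' `c = [R] m_R + [TC] m_TC` subject to a fixed synthesis flux
#' `v = k_cat [R] [TC]/(K_m + [TC])` is, in closed form,
#' `[TC]* = sqrt(a K_m v / k_cat)`.
#'
#' @param v protein synthesis flux (uM s^-1), vectorised.
#' @inheritParams protein_synthesis_flux
#' @return concentration (uM).
#' @export
optimal_tc_conc <- function(v, params) {
  stopifnot(inherits(params, "translation_params"))
  if (any(v < 0)) stop("'v' must be >= 0", call. = FALSE)
  sqrt(params$a * params$K_m * v / params$k_cat)
}

#' Mass-optimal ribosome concentration
#'
#' The ribosome concentration paired with [optimal_tc_conc()] at flux `v`:
#' `[R]* = v/k_cat + sqrt(K_m v / (a k_cat))`.
#'
#' @inheritParams optimal_tc_conc
#' @return concentration (uM).
#' @export
optimal_rib_conc <- function(v, params) {
  stopifnot(inherits(params, "translation_params"))
  if (any(v < 0)) stop("'v' must be >= 0", call. = FALSE)
  v / params$k_cat + sqrt(params$K_m * v / (params$a * params$k_cat))
}

#' Optimal TC-per-ribosome expression ratio (the RNA growth law)
#'
#' The ratio of the mass-optimal TC and ribosome concentrations as a
#' function of growth rate. With the diffusion-limited approximation
#' `K_m = k_cat/k_on`, the ratio of the two closed-form optima reduces to
#'
#'   `[TC]/[R] = a k_cat / (sqrt(a mu [P] k_on) + k_cat)`
#'
#' with `mu` in s^-1 inside the radical. It decreases monotonically with
#' growth rate and tends to `a` as `mu -> 0` (the substrate-saturated
#' slow-growth limit). With `k_deg > 0` the flux argument is
#' `(mu + k_deg)[P]`.
#'
#' @param mu growth rate (h^-1), vectorised.
#' @param params a [translation_params()] object with `k_cat`, `k_on` and
#'   `P_conc` set.
#' @param k_cat optional override of the turnover number (s^-1); used by the
#'   fitting routine, which varies only this parameter.
#' @return dimensionless TC/ribosome (equivalently tRNA/ribosome molar) ratio.
#' @export
optimal_tc_per_ribosome <- function(mu, params, k_cat = params$k_cat) {
  stopifnot(inherits(params, "translation_params"))
  if (any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  if (is.na(k_cat) || is.na(params$k_on) || is.na(params$P_conc))
    stop("k_cat, k_on and P_conc must be set", call. = FALSE)
  v <- (mu + params$k_deg) / 3600 * params$P_conc
  params$a * k_cat / (sqrt(params$a * v * params$k_on) + k_cat)
}

#' Optimal tRNA/rRNA mass ratio
#'
#' The growth law on the mass scale: the molar TC/ribosome ratio scaled by
#' `m_tRNA/m_rRNA`, i.e. `r k_cat / (sqrt(a mu [P] k_on) + k_cat)`. Tends to
#' `r` as `mu -> 0`.
#'
#' @inheritParams optimal_tc_per_ribosome
#' @return dimensionless mass ratio M_tRNA/M_rRNA.
#' @export
trna_rrna_mass_ratio <- function(mu, params, k_cat = params$k_cat) {
  optimal_tc_per_ribosome(mu, params, k_cat = k_cat) *
    params$m_tRNA / params$m_rRNA
}

#' Combined ribosome + TC mass density
#'
#' `c = [R] m_R + [TC] m_TC`, in kDa uM.
#'
#' @param tc_conc,rib_conc concentrations (uM), vectorised.
#' @inheritParams protein_synthesis_flux
#' @export
combined_mass_density <- function(tc_conc, rib_conc, params) {
  stopifnot(inherits(params, "translation_params"))
  if (any(tc_conc < 0) || any(rib_conc < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  rib_conc * params$m_R + tc_conc * params$m_TC
}

#' Total protein concentration from proteome copy numbers
#'
#' `[P] = sum(N_i L_i) / (V_cell N_A)` in uM of amino-acid residues, where
#' `N_i` is the copy number per cell and `L_i` the protein length. Any cell
#' volume correction factor (e.g. the 0.67 rescaling of older volumetric
#' measurements) is applied by the caller to `cell_volume_L`.
#'
#' @param copy_numbers numeric vector of per-protein copy numbers.
#' @param lengths_aa numeric vector of protein lengths (amino acids).
#' @param cell_volume_L cell volume in litres (1 fL = 1e-15 L).
#' @return concentration (uM of residues).
#' @export
protein_concentration <- function(copy_numbers, lengths_aa, cell_volume_L) {
  if (length(copy_numbers) == 0L)
    stop("empty proteome", call. = FALSE)
  if (length(copy_numbers) != length(lengths_aa))
    stop("copy_numbers and lengths_aa must have equal length", call. = FALSE)
  if (any(copy_numbers <= 0) || any(lengths_aa <= 0) || cell_volume_L <= 0)
    stop("counts, lengths and volume must be positive", call. = FALSE)
  n_avogadro <- 6.02214076e23
  sum(copy_numbers * lengths_aa) / (cell_volume_L * n_avogadro) * 1e6
}

#' Growth-law predictions over a growth-rate grid
#'
#' Evaluates the mass-optimal allocation over a grid of growth rates and
#' returns a table with one row per rate: flux, optimal concentrations, the
#' TC/ribosome ratio and the tRNA/rRNA mass ratio.
#'
#' @param mu_grid growth rates (h^-1).
#' @inheritParams protein_synthesis_flux
#' @return data.frame with columns `mu`, `v`, `tc_conc`, `rib_conc`,
#'   `tc_per_ribosome`, `trna_rrna_mass_ratio`.
#' @export
predict_allocation <- function(mu_grid, params) {
  v <- protein_synthesis_flux(mu_grid, params)
  data.frame(
    mu = mu_grid,
    v = v,
    tc_conc = optimal_tc_conc(v, params),
    rib_conc = optimal_rib_conc(v, params),
    tc_per_ribosome = optimal_tc_per_ribosome(mu_grid, params),
    trna_rrna_mass_ratio = trna_rrna_mass_ratio(mu_grid, params))
}
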