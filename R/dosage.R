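#' Replication timing settings for the Cooper-Helmstetter dosage model
#'
#' @param C chromosome replication time (h). Defaults to `NA`; usually set
#'   from the genome length via [c_period()].
#' @param D time between replication termination and division (h); cancels
#'   in every dosage *ratio* and matters only for absolute dosages.
#' @param k_rep replication fork speed (bp s^-1), default 1000, used when
#'   `C` is derived from a genome length.
#' @param n_rrna_per_ribosome rRNA genes per ribosome (5S, 16S, 23S), 3.
#' @return object of class `"dosage_settings"`.
#' @export
dosage_settings <- function(C = NA_real_, D = 20 / 60, k_rep = 1000,
                            n_rrna_per_ribosome = 3L) {
  if (!is.na(C) && C <= 0) stop("'C' must be > 0", call. = FALSE)
  if (D < 0) stop("'D' must be >= 0", call. = FALSE)
  if (k_rep <= 0) stop("'k_rep' must be > 0", call. = FALSE)
  if (n_rrna_per_ribosome < 1) stop("'n_rrna_per_ribosome' must be >= 1",
                                    call. = FALSE)
  structure(list(C = C, D = D, k_rep = k_rep,
                 n_rrna_per_ribosome = as.integer(n_rrna_per_ribosome)),
            class = "dosage_settings")
}

#' C period from genome length
#'
#' Two replication forks proceed from oriC, so one full chromosome
#' replication takes `C = L / (2 k_rep)`, returned in hours.
#'
#' @param genome_length chromosome length (bp).
#' @param k_rep replication fork speed (bp s^-1).
#' @export
c_period <- function(genome_length, k_rep = 1000) {
  if (any(genome_length <= 0) || any(k_rep <= 0))
    stop("genome_length and k_rep must be > 0", call. = FALSE)
  genome_length / (2 * k_rep) / 3600
}

.resolve_C <- function(settings) {
  if (is.na(settings$C))
    stop("settings$C is not set; derive it with c_period()", call. = FALSE)
  settings$C
}

#' Average per-cell gene dosage
#'
#' Cooper-Helmstetter average copy number of a gene at relative position
#' `p` (0 at oriC, 1 at the terminus) in cells growing at rate `mu`:
#' `exp(mu * (C (1 - p) + D))`, equivalently `2^((C(1-p)+D)/tau)` with
#' `tau = ln 2 / mu`. Equals 1 at `mu = 0`.
#'
#' @param position relative chromosomal position in `[0, 1]`, vectorised.
#' @param mu growth rate (h^-1).
#' @param settings a [dosage_settings()] object with `C` set.
#' @return average gene copies per cell.
#' @export
gene_dosage <- function(position, mu, settings) {
  stopifnot(inherits(settings, "dosage_settings"))
  if (any(position < 0 | position > 1))
    stop("'position' must lie in [0, 1]", call. = FALSE)
  if (any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  C <- .resolve_C(settings)
  exp(mu * (C * (1 - position) + settings$D))
}

#' Dosage ratio of two genes
#'
#' `X_i / X_j = exp(mu C (p_j - p_i))`; the D period cancels.
#'
#' @param position_i,position_j relative positions in `[0, 1]`.
#' @inheritParams gene_dosage
#' @export
dosage_ratio <- function(position_i, position_j, mu, settings) {
  stopifnot(inherits(settings, "dosage_settings"))
  if (any(c(position_i, position_j) < 0 | c(position_i, position_j) > 1))
    stop("positions must lie in [0, 1]", call. = FALSE)
  if (any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  C <- .resolve_C(settings)
  exp(mu * C * (position_j - position_i))
}

#' Aggregate tRNA/rRNA (tRNA/ribosome) gene dosage ratio
#'
#' Total tRNA gene dosage over total ribosome-equivalent rRNA dosage:
#' `sum_t exp(mu C (1 - p_t)) / ((1/n) sum_r exp(mu C (1 - p_r)))` with
#' `n = 3` rRNA genes per ribosome. The common factor `exp(mu D)` cancels.
#' At `mu = 0` this is the genomic copy ratio `N_tRNA / (N_rRNA / n)`.
#'
#' @param trna_positions,rrna_positions numeric vectors of relative
#'   positions in `[0, 1]`, one entry per gene.
#' @inheritParams gene_dosage
#' @export
aggregate_trna_rrna_dosage_ratio <- function(trna_positions, rrna_positions,
                                             mu, settings) {
  stopifnot(inherits(settings, "dosage_settings"))
  if (length(trna_positions) == 0L || length(rrna_positions) == 0L)
    stop("position lists must be nonempty", call. = FALSE)
  pos <- c(trna_positions, rrna_positions)
  if (any(pos < 0 | pos > 1)) stop("positions must lie in [0, 1]", call. = FALSE)
  if (any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  C <- .resolve_C(settings)
  n <- settings$n_rrna_per_ribosome
  vapply(mu, function(m) {
    sum(exp(m * C * (1 - trna_positions))) /
      (sum(exp(m * C * (1 - rrna_positions))) / n)
  }, numeric(1))
}

#' Genomic tRNA/rRNA copy ratio per chromosome
#'
#' Gene copy ratio ignoring replication: `N_tRNA / (N_rRNA / n)`. This is the
#' `mu = 0` limit of [aggregate_trna_rrna_dosage_ratio()].
#'
#' @param n_trna_genes,n_rrna_genes gene counts per chromosome.
#' @param n rRNA genes per ribosome (default 3).
#' @export
genomic_copy_ratio <- function(n_trna_genes, n_rrna_genes, n = 3L) {
  if (any(n_trna_genes <= 0)) stop("'n_trna_genes' must be positive", call. = FALSE)
  if (any(n_rrna_genes <= 0)) stop("'n_rrna_genes' must be positive", call. = FALSE)
  n_trna_genes / (n_rrna_genes / n)
}
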