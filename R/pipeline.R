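# Orchestration of the three paper-level analyses. Each runner is a plain
# function over in-memory objects (or TSV paths) and optionally writes a
# TSV + JSON report pair plus a run manifest.

.read_obs <- function(observations) {
  if (is.character(observations)) {
    observations <- utils::read.delim(observations, stringsAsFactors = FALSE)
    if ("mu_per_h" %in% names(observations) && !"mu" %in% names(observations))
      names(observations)[names(observations) == "mu_per_h"] <- "mu"
  }
  observations
}

.write_report <- function(report, tables, out_dir, stem) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.table(tables[[nm]],
                       file.path(out_dir, sprintf("%s_%s.tsv", stem, nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a machine-readable run manifest
#'
#' Records input file paths with md5 checksums, the seed and any parameter
#' values, sufficient to reproduce a deterministic run byte-identically.
#'
#' @param out_dir output directory.
#' @param inputs character vector of input file paths (existing files are
#'   checksummed).
#' @param seed integer seed used (or `NA`).
#' @param params optional named list of parameter values.
#' @export
write_manifest <- function(out_dir, inputs = character(), seed = NA_integer_,
                           params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  existing <- inputs[file.exists(inputs)]
  manifest <- list(
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(existing)), existing)),
    seed = seed,
    params = params,
    package_version = as.character(utils::packageVersion("rnagrowthlaw")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Growth-law analysis for a single species (E. coli style)
#'
#' Compares observed TC/ribosome expression ratios against the
#' fixed-parameter growth-law prediction (no fitting), reporting the squared
#' Pearson correlation and NRMSE of observed vs predicted; alongside,
#' evaluates the aggregate tRNA/rRNA gene dosage ratio and the genomic copy
#' ratio over a growth-rate grid for the species' gene positions.
#'
#' @param observations data.frame (or TSV path) with columns `mu` (h^-1) and
#'   `ratio`; optional `units` as in [fit_kcat()].
#' @param params a [translation_params()]; default E. coli.
#' @param genome optional [genome_record()] supplying gene positions and the
#'   genome length for the dosage curve.
#' @param mu_grid growth rates for the prediction/dosage curves.
#' @param out_dir optional directory for the TSV + JSON report.
#' @return list with `observed` (table incl. predictions), `r2`, `nrmse`,
#'   `curve` (predictions over `mu_grid`, incl. dosage ratio columns when a
#'   genome is given), `genomic_copy_ratio` (or `NA`).
#' @export
run_ecoli_analysis <- function(observations, params = default_ecoli_params(),
                               genome = NULL,
                               mu_grid = seq(0.1, 2.5, by = 0.05),
                               out_dir = NULL) {
  obs <- .read_obs(observations)
  if (!all(c("mu", "ratio") %in% names(obs)))
    stop("observations need columns 'mu' and 'ratio'", call. = FALSE)
  units <- if ("units" %in% names(obs)) unique(obs$units) else
    "molar_tc_per_ribosome"
  if (length(units) != 1L) stop("mixed units in observations", call. = FALSE)
  scale <- if (units == "mass_trna_per_rrna") params$m_tRNA / params$m_rRNA else 1

  obs$predicted <- optimal_tc_per_ribosome(obs$mu, params) * scale
  r2 <- stats::cor(obs$ratio, obs$predicted)^2
  fit_nrmse <- nrmse(obs$ratio, obs$predicted)

  curve <- predict_allocation(mu_grid, params)
  copy_ratio <- NA_real_
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_record"))
    g <- genome$genes
    tp <- g$position[g$gene_class == "tRNA"]
    rp <- g$position[startsWith(g$gene_class, "rRNA")]
    settings <- dosage_settings(C = c_period(genome$genome_length))
    curve$dosage_ratio <- aggregate_trna_rrna_dosage_ratio(tp, rp, mu_grid,
                                                           settings)
    copy_ratio <- genomic_copy_ratio(length(tp), length(rp))
  }

  report <- list(analysis = "single_species_growth_law",
                 n_obs = nrow(obs), units = units,
                 r2 = r2, nrmse = fit_nrmse,
                 genomic_copy_ratio = copy_ratio)
  if (!is.null(out_dir)) {
    .write_report(report, list(observed = obs, curve = curve),
                  out_dir, "ecoli_analysis")
    write_manifest(out_dir,
                   inputs = if (is.character(observations)) observations else character(),
                   params = list(k_cat = params$k_cat, a = params$a))
  }
  c(report, list(observed = obs, curve = curve))
}

#' Per-species k_cat fits and comparison with effective turnover numbers
#'
#' Fits `k_cat` for each species in a multi-species observation table and,
#' when per-species `mu`, `P_conc`, `rib_conc` measurements are supplied,
#' computes the effective turnover number `k_eff = mu [P]/[R]` and the
#' Pearson r^2 between fitted and effective values. Species whose ratios
#' show no growth-rate dependence (|Spearman rho| < 0.2 with p > 0.05) are
#' excluded from fitting with a warning, since a fit is meaningless there.
#'
#' @param observations data.frame (or TSV path) with columns `species`,
#'   `mu`, `ratio`, optional `units`.
#' @param params template [translation_params()]; `k_on` and `P_conc` are
#'   held fixed during fitting.
#' @param keff_table optional data.frame with columns `species`, `mu`,
#'   `P_conc`, `rib_conc` for the independent k_eff estimate.
#' @param out_dir optional report directory.
#' @return list with `fits` (per-species table), `excluded` (labels),
#'   `r2_kcat_keff` (or `NA`).
#' @export
run_species_fits <- function(observations, params = default_ecoli_params(),
                             keff_table = NULL, out_dir = NULL) {
  obs <- .read_obs(observations)
  if (!all(c("species", "mu", "ratio") %in% names(obs)))
    stop("observations need columns 'species', 'mu', 'ratio'", call. = FALSE)

  rows <- list(); excluded <- character()
  for (sp in unique(obs$species)) {
    sub <- obs[obs$species == sp, , drop = FALSE]
    if (nrow(sub) < 3L || length(unique(sub$mu)) < 2L) {
      excluded <- c(excluded, sp)
      warning("species '", sp, "' excluded: too few distinct growth rates",
              call. = FALSE)
      next
    }
    dep <- suppressWarnings(
      stats::cor.test(sub$mu, sub$ratio, method = "spearman"))
    if (is.na(dep$estimate) ||
        (abs(dep$estimate) < 0.2 && dep$p.value > 0.05)) {
      excluded <- c(excluded, sp)
      warning("species '", sp, "' excluded: no growth-rate dependence ",
              sprintf("(Spearman rho = %.2f, p = %.2g)", dep$estimate,
                      dep$p.value), call. = FALSE)
      next
    }
    fit <- fit_kcat(sub, params)
    rows[[sp]] <- data.frame(species = sp, k_cat_hat = fit$k_cat_hat,
                             r2 = fit$r2, nrmse = fit$nrmse,
                             n_obs = fit$n_obs,
                             spearman_rho = unname(dep$estimate),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no fittable species", call. = FALSE)
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL

  r2_kk <- NA_real_
  if (!is.null(keff_table)) {
    keff_table <- .read_obs(keff_table)
    keff <- vapply(split(keff_table, keff_table$species), function(d)
      mean(effective_kcat(d$mu, d$P_conc, d$rib_conc)), numeric(1))
    fits$k_eff <- unname(keff[fits$species])
    ok <- !is.na(fits$k_eff)
    if (sum(ok) >= 3)
      r2_kk <- stats::cor(fits$k_cat_hat[ok], fits$k_eff[ok])^2
  }

  report <- list(analysis = "per_species_kcat_fits",
                 n_species_fit = nrow(fits),
                 excluded = as.list(excluded),
                 r2_kcat_keff = r2_kk)
  if (!is.null(out_dir))
    .write_report(report, list(fits = fits), out_dir, "species_fits")
  list(fits = fits, excluded = excluded, r2_kcat_keff = r2_kk)
}

#' Cross-species gene-position survey
#'
#' For a set of genome records with known maximal growth rates: per-species
#' mean class positions, growth class, aggregate tRNA/rRNA dosage ratio at
#' `mu_max` (C period from genome length, shared `k_rep`), and genomic copy
#' ratio; Spearman correlations of positions and dosage ratios against
#' `mu_max` (per growth class, with contrast-based p-values when a rooted
#' tree is supplied); Wilcoxon tests of positions against 0.5; and F tests
#' comparing dosage-ratio dispersion (on the log scale) between fast and
#' slow growers.
#'
#' @param genomes list of [genome_record()] objects with `tau_min` set.
#'   Species missing either gene class are dropped with a warning.
#' @param k_rep replication fork speed (bp s^-1) shared across species.
#' @param tree optional rooted binary [ape::phylo] whose tip labels match
#'   the species names; enables PIC p-values.
#' @param out_dir optional report directory.
#' @return list with `table` (per-species), `correlations`, `wilcoxon`,
#'   `f_tests`.
#' @export
run_position_survey <- function(genomes, k_rep = 1000, tree = NULL,
                                out_dir = NULL) {
  rows <- list()
  for (g in genomes) {
    stopifnot(inherits(g, "genome_record"))
    mc <- mean_class_positions(g)
    if (mc$n_tRNA == 0L || mc$n_rRNA == 0L) {
      warning("species '", g$species, "' dropped: missing a gene class",
              call. = FALSE)
      next
    }
    if (is.na(g$mu_max)) {
      warning("species '", g$species, "' dropped: no growth rate", call. = FALSE)
      next
    }
    settings <- dosage_settings(C = c_period(g$genome_length, k_rep),
                                k_rep = k_rep)
    tp <- g$genes$position[g$genes$gene_class == "tRNA"]
    rp <- g$genes$position[startsWith(g$genes$gene_class, "rRNA")]
    rows[[g$species]] <- data.frame(
      species = g$species,
      genome_length = g$genome_length,
      C = settings$C,
      mu_max = g$mu_max,
      growth_class = g$growth_class,
      position_tRNA = mc$position_tRNA,
      position_rRNA = mc$position_rRNA,
      n_tRNA = mc$n_tRNA,
      n_rRNA = mc$n_rRNA,
      dosage_ratio_mu_max = aggregate_trna_rrna_dosage_ratio(
        tp, rp, g$mu_max, settings),
      genomic_ratio = genomic_copy_ratio(mc$n_tRNA, mc$n_rRNA),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable genomes", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  cors <- list()
  for (cls in intersect(c("fast", "slow"), unique(tab$growth_class))) {
    sub <- tab[tab$growth_class == cls, , drop = FALSE]
    if (nrow(sub) < 3L) next
    for (var in c("position_rRNA", "position_tRNA", "dosage_ratio_mu_max",
                  "genomic_ratio")) {
      cs <- correlation_suite(sub[[var]], sub$mu_max)
      p_ic <- NA_real_
      if (!is.null(tree) && all(sub$species %in% tree$tip.label) &&
          nrow(sub) >= 4L) {
        sub_tree <- ape::keep.tip(tree, sub$species)
        if (!ape::is.binary(sub_tree)) sub_tree <- resolve_polytomies(sub_tree)
        cx <- pic_contrasts(sub_tree,
                            stats::setNames(sub[[var]], sub$species))
        cy <- pic_contrasts(sub_tree,
                            stats::setNames(sub$mu_max, sub$species))
        p_ic <- pic_correlation_test(cx, cy)$p_value
      }
      cors[[paste(cls, var, sep = ".")]] <- data.frame(
        growth_class = cls, variable = var,
        spearman_rho = cs$spearman_rho, spearman_p = cs$spearman_p,
        p_ic = p_ic, n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cors)
  rownames(correlations) <- NULL

  wil <- list()
  for (cls in intersect(c("fast", "slow"), unique(tab$growth_class))) {
    sub <- tab[tab$growth_class == cls, , drop = FALSE]
    for (var in c("position_rRNA", "position_tRNA")) {
      p <- tryCatch(one_sample_wilcoxon(sub[[var]], 0.5),
                    error = function(e) NA_real_)
      wil[[paste(cls, var, sep = ".")]] <- data.frame(
        growth_class = cls, variable = var, null = 0.5, p = p,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  wilcoxon <- do.call(rbind, wil)
  rownames(wilcoxon) <- NULL

  f_tests <- NULL
  if (all(c("fast", "slow") %in% tab$growth_class)) {
    fast <- tab[tab$growth_class == "fast", , drop = FALSE]
    slow <- tab[tab$growth_class == "slow", , drop = FALSE]
    if (nrow(fast) >= 2L && nrow(slow) >= 2L) {
      f_tests <- data.frame(
        variable = c("log_dosage_ratio_mu_max", "log_genomic_ratio"),
        p = c(variance_f_test(log(slow$dosage_ratio_mu_max),
                              log(fast$dosage_ratio_mu_max)),
              variance_f_test(log(slow$genomic_ratio),
                              log(fast$genomic_ratio))),
        stringsAsFactors = FALSE)
    }
  }

  report <- list(analysis = "position_survey",
                 n_species = nrow(tab),
                 k_rep = k_rep)
  if (!is.null(out_dir))
    .write_report(report,
                  list(table = tab, correlations = correlations,
                       wilcoxon = wilcoxon,
                       f_tests = if (is.null(f_tests))
                         data.frame(variable = character(), p = numeric())
                       else f_tests),
                  out_dir, "position_survey")
  list(table = tab, correlations = correlations, wilcoxon = wilcoxon,
       f_tests = f_tests)
}
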