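# Synthetic-data generators: genomes with positioned rRNA/tRNA genes,
# expression ratios drawn around the growth law, and Yule trees with
# Brownian traits. Every generator is a pure function of (spec, seed).

#' Specification for the synthetic cross-species survey
#'
#' Defines the statistical structure the generator emulates: species with
#' log-uniform minimal doubling times, circular single-chromosome genomes,
#' rRNA genes in 5S/16S/23S operon triplets near oriC (class position mean
#' 0.20, sd 0.17 — the E. coli values), tRNA genes singly and further out
#' (mean 0.45, sd 0.27), gene counts increasing with maximal growth rate,
#' and multiplicative lognormal noise (sigma 0.15) on expression ratios.
#' Position means decline mildly with `mu_max` (slope -0.03 per h^-1) so
#' that fast growers carry their rRNA/tRNA genes closer to oriC, as
#' observed across bacteria.
#'
#' @param n_species number of species to generate.
#' @param seed integer seed; fully determines all outputs.
#' @param tau_min_range range of minimal doubling times (h), sampled
#'   log-uniformly.
#' @param genome_length_range chromosome length range (bp).
#' @param rrna_position_mean,rrna_position_sd truncated-normal law on [0,1]
#'   for rRNA operon positions.
#' @param trna_position_mean,trna_position_sd same for tRNA genes.
#' @param position_mu_slope shift of both class means per unit `mu_max`
#'   (h); negative moves genes toward oriC in fast growers.
#' @param noise_sd_log lognormal sigma for simulated expression ratios.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_species = 60L,
                           seed = 20260921L,
                           tau_min_range = c(0.25, 10),
                           genome_length_range = c(1.8e6, 9e6),
                           rrna_position_mean = 0.20, rrna_position_sd = 0.17,
                           trna_position_mean = 0.45, trna_position_sd = 0.27,
                           position_mu_slope = -0.03,
                           noise_sd_log = 0.15) {
  stopifnot(n_species >= 1,
            rrna_position_mean >= 0, rrna_position_mean <= 1,
            trna_position_mean >= 0, trna_position_mean <= 1,
            noise_sd_log >= 0)
  structure(list(n_species = as.integer(n_species), seed = as.integer(seed),
                 tau_min_range = tau_min_range,
                 genome_length_range = genome_length_range,
                 rrna_position_mean = rrna_position_mean,
                 rrna_position_sd = rrna_position_sd,
                 trna_position_mean = trna_position_mean,
                 trna_position_sd = trna_position_sd,
                 position_mu_slope = position_mu_slope,
                 noise_sd_log = noise_sd_log),
            class = "synthetic_spec")
}

# rejection-sampled truncated normal on [0, 1]
.rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= 0 & draw <= 1])
  }
  out[seq_len(n)]
}

#' Generate one synthetic genome
#'
#' Draws a circular chromosome with a random oriC, places `n_operons`
#' rRNA operons (each a 16S/23S/5S triplet at essentially one position) and
#' single tRNA genes at class-law positions, assigns each gene to a
#' replichore uniformly, and optionally writes a GFF3 annotation plus a
#' DoriC-style oriC TSV. Gene counts scale with the species' maximal growth
#' rate: `n_operons = max(1, round(1 + 2.5 mu_max))` and
#' `n_trna = max(25, round(30 + 15 mu_max))` plus Poisson jitter, echoing
#' the observed increase of rRNA and tRNA gene numbers with `mu_max`.
#'
#' @param spec a [synthetic_spec()].
#' @param species_index 1-based index; the per-species seed is
#'   `spec$seed + species_index`.
#' @param out_dir if non-`NULL`, writes `<species>.gff3` and
#'   `<species>_oric.tsv` there.
#' @return a [genome_record()] (with attribute `files` when written).
#' @export
generate_genome <- function(spec, species_index, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  species <- sprintf("synthsp%03d", species_index)
  set.seed(spec$seed + species_index)

  L <- round(stats::runif(1, spec$genome_length_range[1],
                          spec$genome_length_range[2]))
  tau <- exp(stats::runif(1, log(spec$tau_min_range[1]),
                          log(spec$tau_min_range[2])))
  mu_max <- log(2) / tau
  oric <- sample.int(L, 1)

  n_operons <- max(1L, stats::rpois(1, max(1, 1 + 2.5 * mu_max)))
  n_trna <- max(25L, stats::rpois(1, max(25, 30 + 15 * mu_max)))

  shift <- spec$position_mu_slope * mu_max
  r_mean <- min(max(spec$rrna_position_mean + shift, 0.02), 0.98)
  t_mean <- min(max(spec$trna_position_mean + shift, 0.02), 0.98)

  op_pos <- .rtruncnorm01(n_operons, r_mean, spec$rrna_position_sd)
  t_pos <- .rtruncnorm01(n_trna, t_mean, spec$trna_position_sd)

  to_coord <- function(pos) {
    side <- sample(c(-1, 1), length(pos), replace = TRUE)
    ((round(oric + side * pos * L / 2) - 1) %% L) + 1
  }

  # rRNA operon layout: 16S, 23S, 5S consecutive downstream of the anchor
  rrna_len <- c(rRNA_16S = 1542, rRNA_23S = 2904, rRNA_5S = 120)
  offs <- c(0, 1542 + 200, 1542 + 200 + 2904 + 100)
  anchors <- to_coord(op_pos)
  rrna <- do.call(rbind, lapply(seq_len(n_operons), function(k) {
    st <- ((anchors[k] + offs - 1) %% L) + 1
    en <- ((st + rrna_len - 1 - 1) %% L) + 1
    data.frame(
      gene_id = sprintf("%s_rrn%02d_%s", species, k,
                        c("16S", "23S", "5S")),
      gene_class = names(rrna_len),
      start = st, end = en, strand = "+",
      product = paste(c("16S", "23S", "5S"), "ribosomal RNA"),
      stringsAsFactors = FALSE)
  }))
  t_start <- to_coord(t_pos)
  t_end <- ((t_start + 76 - 1 - 1) %% L) + 1
  trna <- data.frame(
    gene_id = sprintf("%s_trna%03d", species, seq_len(n_trna)),
    gene_class = "tRNA", start = t_start, end = t_end,
    strand = sample(c("+", "-"), n_trna, replace = TRUE),
    product = "tRNA-Xxx", stringsAsFactors = FALSE)

  genes <- rbind(rrna, trna)
  genes$midpoint <- gene_midpoint(genes$start, genes$end, L)
  rec <- genome_record(species, genes[, c("gene_id", "gene_class", "start",
                                          "end", "strand", "midpoint")],
                       genome_length = L, oric = oric, tau_min = tau)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gff <- file.path(out_dir, paste0(species, ".gff3"))
    .write_gff3(genes, species, L, gff)
    oric_file <- file.path(out_dir, paste0(species, "_oric.tsv"))
    writeLines(c("accession\toric_start\toric_end",
                 sprintf("%s\t%d\t%d", species,
                         max(1L, oric - 100L), min(L, oric + 100L))),
               oric_file)
    attr(rec, "files") <- c(annotation = gff, oric = oric_file)
  }
  rec
}

.write_gff3 <- function(genes, seqid, L, path) {
  type <- ifelse(genes$gene_class == "tRNA", "tRNA", "rRNA")
  # wrapped features (start > end) use the circular GFF3 end > L convention
  end <- ifelse(genes$end < genes$start, genes$end + L, genes$end)
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", seqid, L),
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
            seqid, type, genes$start, end, genes$strand,
            genes$gene_id, genes$product))
  writeLines(lines, path)
  invisible(path)
}

#' Generate the full synthetic survey
#'
#' Calls [generate_genome()] for each species and returns the list of
#' genome records.
#'
#' @inheritParams generate_genome
#' @export
generate_survey <- function(spec, out_dir = NULL) {
  lapply(seq_len(spec$n_species), function(i)
    generate_genome(spec, i, out_dir = out_dir))
}

#' Simulate expression-ratio observations around the growth law
#'
#' `ratio_i = optimal_tc_per_ribosome(mu_i) * exp(e_i)` with
#' `e_i ~ Normal(0, noise_sd_log^2)`, seeded. With `noise_sd_log = 0` the
#' model values are returned exactly; the lognormal noise is
#' positivity-preserving and median-unbiased.
#'
#' @param params a [translation_params()] with kinetics set.
#' @param mu_grid growth rates (h^-1), all > 0.
#' @param noise_sd_log lognormal sigma.
#' @param seed integer seed.
#' @param species label stored in the output.
#' @return data.frame with columns `species`, `mu`, `ratio`, `units`,
#'   `source`.
#' @export
simulate_expression_ratios <- function(params, mu_grid, noise_sd_log = 0.15,
                                       seed = 1L, species = "synthetic") {
  if (any(mu_grid <= 0)) stop("'mu_grid' must be > 0", call. = FALSE)
  set.seed(seed)
  model <- optimal_tc_per_ribosome(mu_grid, params)
  eps <- stats::rnorm(length(mu_grid), 0, noise_sd_log)
  data.frame(species = species, mu = mu_grid, ratio = model * exp(eps),
             units = "molar_tc_per_ribosome", source = "simulated",
             stringsAsFactors = FALSE)
}

#' Yule tree with Brownian-motion tip traits
#'
#' Pure-birth tree on `n_tips` (ape's birth-death sampler with death rate
#' 0) and one or more independent traits evolved by Brownian motion with
#' variance rate `sigma2` from root value 0.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate Yule speciation rate.
#' @param sigma2 Brownian variance per unit branch length.
#' @param seed integer seed.
#' @param n_traits number of independent traits.
#' @return list with `tree` (phylo) and `traits` (matrix, tips x traits,
#'   rownames = tip labels).
#' @export
generate_tree_with_traits <- function(n_tips, birth_rate = 1, sigma2 = 1,
                                      seed = 1L, n_traits = 1L) {
  if (n_tips < 3L) stop("'n_tips' must be >= 3", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  traits <- vapply(seq_len(n_traits), function(j)
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0),
    numeric(n_tips))
  rownames(traits) <- tree$tip.label
  colnames(traits) <- paste0("trait", seq_len(n_traits))
  list(tree = tree, traits = traits)
}
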