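#!/usr/bin/env Rscript
# Single-species growth-law analysis: compare simulated expression ratios
# with the fixed-parameter optimal allocation (no free parameters), and set
# the gene-dosage ratio curve of one synthetic genome beside it.
# Run analysis/01_simulate.R first.

suppressMessages(library(rnagrowthlaw))

in_dir <- "results/synthetic"
out_dir <- "results/growth_law"

params <- default_ecoli_params()
cat(sprintf("parameters: a = %.1f, r = %.2f, K_m = %g uM, k_on = %g\n",
            params$a, params$r, params$K_m, params$k_on))
cat(sprintf("optimal TC/ribosome at mu = 1.5 h^-1: %.2f (~%d tRNAs per ribosome)\n",
            optimal_tc_per_ribosome(1.5, params),
            round(optimal_tc_per_ribosome(1.5, params))))

# the genome generated for species 1 supplies gene positions for the
# dosage curve (re-derived from the same spec + seed as 01_simulate.R)
spec <- synthetic_spec(n_species = 60L, seed = 20260921L)
genome <- generate_genome(spec, 1)

res <- run_ecoli_analysis(file.path(in_dir, "expression_ratios_single.tsv"),
                          params, genome = genome, out_dir = out_dir)
cat(sprintf("observed vs predicted over %d points: r^2 = %.2f, NRMSE = %.2f\n",
            res$n_obs, res$r2, res$nrmse))
cat(sprintf("genomic tRNA/rRNA copy ratio of the genome: %.2f\n",
            res$genomic_copy_ratio))
cat(sprintf("dosage ratio falls from %.2f (mu = %.1f) to %.2f (mu = %.1f)\n",
            res$curve$dosage_ratio[1], res$curve$mu[1],
            tail(res$curve$dosage_ratio, 1), tail(res$curve$mu, 1)))
cat("report written under", out_dir, "\n")
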