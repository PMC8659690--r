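# Test-side oracles, kept independent of the implementation paths they check.

# Combined mass density of Eq-7 form: c([TC]) at fixed flux v, with the
# ribosome concentration re-solved from the Michaelis-Menten rate law.
mass_density_at_tc <- function(tc, v, params) {
  rib <- v / params$k_cat * (params$K_m / tc + 1)
  rib * params$m_R + tc * params$m_TC
}

# Golden-section minimizer driven to an interval width of `tol` (1e-9 by
# default); derivative-free, no reliance on stats::optimize.
golden_section <- function(f, lower, upper, tol = 1e-9) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while ((b - a) > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

# Linear map of tip traits to contrasts, recovered column by column; used to
# verify that contrasts whiten the Brownian-motion covariance: D V D' = I.
contrast_matrix <- function(tree) {
  n <- length(tree$tip.label)
  vapply(seq_len(n), function(i) {
    e <- stats::setNames(numeric(n), tree$tip.label)
    e[i] <- 1
    as.numeric(pic_contrasts(tree, e))
  }, numeric(n - 1))
}

# Dual-encoded annotation fixture: the same 3 rRNA + 5 tRNA features (plus
# one pseudo-tRNA that parsers must drop) written as GFF3 and as a GenBank
# flat file. Genome length 1e6, one tRNA wraps the origin.
fixture_features <- function() {
  data.frame(
    gene_id = c("rrsA", "rrlA", "rrfA", paste0("t", 1:5), "tps"),
    type = c("rRNA", "rRNA", "rRNA", rep("tRNA", 6)),
    start = c(100101, 102000, 105300, 200001, 350000, 500000, 700011,
              999951, 800000),
    end = c(101642, 104903, 105419, 200076, 350075, 500075, 700086,
            50, 800075),
    strand = c("+", "+", "+", "+", "-", "+", "-", "+", "+"),
    product = c("16S ribosomal RNA", "23S ribosomal RNA",
                "5S ribosomal RNA", rep("tRNA-Ala", 5), "tRNA-Gly"),
    pseudo = c(rep(FALSE, 8), TRUE),
    stringsAsFactors = FALSE)
}

write_fixture_gff3 <- function(path, feats = fixture_features(), L = 1e6) {
  attrs <- sprintf("ID=%s;product=%s%s", feats$gene_id, feats$product,
                   ifelse(feats$pseudo, ";pseudo=true", ""))
  # origin-wrapping features on circular chromosomes are encoded with
  # end > genome length in GFF3
  end <- ifelse(feats$end < feats$start, feats$end + L, feats$end)
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region chr 1 %d", as.integer(L)),
    sprintf("chr\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
            feats$type, feats$start, end, feats$strand, attrs)),
    path)
  path
}

write_fixture_genbank <- function(path, feats = fixture_features(), L = 1e6) {
  loc <- ifelse(
    feats$start <= feats$end,
    sprintf("%d..%d", feats$start, feats$end),
    sprintf("join(%d..%d,1..%d)", feats$start, as.integer(L), feats$end))
  loc <- ifelse(feats$strand == "-", sprintf("complement(%s)", loc), loc)
  blocks <- unlist(lapply(seq_len(nrow(feats)), function(i) {
    c(sprintf("     %-16s%s", feats$type[i], loc[i]),
      sprintf("                     /locus_tag=\"%s\"", feats$gene_id[i]),
      sprintf("                     /product=\"%s\"", feats$product[i]),
      if (feats$pseudo[i]) "                     /pseudo")
  }))
  writeLines(c(
    sprintf("LOCUS       TESTCHR  %d bp    DNA     circular BCT 01-JAN-2020",
            as.integer(L)),
    "DEFINITION  synthetic test chromosome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000000",
    "                     /organism=\"synthetic\"",
    blocks,
    "ORIGIN",
    "//"), path)
  path
}
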