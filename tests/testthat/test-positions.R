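test_that("gene midpoints handle ordinary, point and origin-wrapping features", {
  expect_equal(gene_midpoint(100, 200, 1e6), 150)
  expect_equal(gene_midpoint(1, 1, 1e6), 1)
  expect_equal(gene_midpoint(101, 102, 1e6), 101.5)  # half-integers kept
  # wrapping gene 999951..50 on a 1 Mb circle: midpoint at bp 1 (+- 0.5 bp)
  mid <- gene_midpoint(999951, 50, 1e6)
  d <- min(abs(mid - 1), 1e6 - abs(mid - 1))
  expect_lte(d, 0.5)
  expect_error(gene_midpoint(0, 10, 1e6), "coordinates")
  expect_error(gene_midpoint(10, 2e6, 1e6), "coordinates")
})

test_that("relative position is the normalized shortest circular distance to oriC", {
  L <- 4e6
  expect_equal(relative_position(1.5e6, 1.5e6, L), 0)
  expect_equal(relative_position(3.5e6, 1.5e6, L), 1)       # opposite
  expect_equal(relative_position(2.5e6, 1.5e6, L), 0.5)     # quarter genome
  expect_equal(relative_position(0.5e6, 1.5e6, L), 0.5)     # other replichore
  expect_true(all(relative_position(seq(1, L, length.out = 50), 1.2e6, L) >= 0))
  expect_true(all(relative_position(seq(1, L, length.out = 50), 1.2e6, L) <= 1))
})

test_that("positions are invariant under coordinate rotation and reflection through oriC", {
  L <- 2.5e6
  set.seed(31)
  mids <- sample.int(L, 40)
  oric <- 7e5
  base <- relative_position(mids, oric, L)
  for (offset in c(1e5, 1.3e6, 2.4e6)) {
    rot <- ((mids + offset - 1) %% L) + 1
    rot_oric <- ((oric + offset - 1) %% L) + 1
    expect_equal(relative_position(rot, rot_oric, L), base)
  }
  refl <- ((2 * oric - mids - 1) %% L) + 1
  expect_equal(relative_position(refl, oric, L), base)
})

test_that("growth classification uses the 1 h doubling-time boundary inclusively", {
  expect_equal(classify_growth(c(0.5, 1.0, 2)), c("fast", "fast", "slow"))
  expect_error(classify_growth(0), "> 0")
})

test_that("GFF3 parsing yields classed records and excludes pseudo-genes", {
  gff <- write_fixture_gff3(withr::local_tempfile(fileext = ".gff3"))
  rec <- parse_annotation(gff)
  expect_equal(nrow(rec), 8)  # pseudo-tRNA dropped
  expect_equal(attr(rec, "n_pseudo_excluded"), 1)
  expect_equal(attr(rec, "genome_length"), 1e6)
  expect_equal(sum(rec$gene_class == "tRNA"), 5)
  expect_setequal(rec$gene_class[rec$gene_class != "tRNA"],
                  c("rRNA_16S", "rRNA_23S", "rRNA_5S"))
  expect_equal(rec$gene_class[rec$gene_id == "rrsA"], "rRNA_16S")
  # the wrapping tRNA got a circular midpoint near bp 1
  mid <- rec$midpoint[rec$start > rec$end]
  expect_length(mid, 1)
  expect_lte(min(abs(mid - 1), 1e6 - abs(mid - 1)), 0.5)
})

test_that("GenBank and GFF3 encodings of the same fixture parse identically", {
  gff <- write_fixture_gff3(withr::local_tempfile(fileext = ".gff3"))
  gbk <- write_fixture_genbank(withr::local_tempfile(fileext = ".gbk"))
  a <- parse_annotation(gff)
  b <- parse_annotation(gbk)
  a <- a[order(a$gene_id), ]; b <- b[order(b$gene_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[c("gene_id", "gene_class", "start", "end", "strand",
                   "midpoint")],
               b[c("gene_id", "gene_class", "start", "end", "strand",
                   "midpoint")])
})

test_that("annotations without tRNA/rRNA features are an explicit error", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 1000",
               "chr\ttest\tCDS\t1\t300\t.\t+\t.\tID=c1"), path)
  expect_error(parse_annotation(path), "no tRNA/rRNA")
  expect_error(parse_annotation(withr::local_tempfile()), "not found")
})

test_that("unclassifiable rRNA features are pooled but flagged", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 100000",
               "chr\ttest\trRNA\t10\t500\t.\t+\t.\tID=r1;product=ribosomal RNA",
               "chr\ttest\ttRNA\t900\t976\t.\t+\t.\tID=t1;product=tRNA-Ala"),
             path)
  expect_warning(rec <- parse_annotation(path), "without a 5S/16S/23S")
  expect_equal(rec$gene_class[rec$gene_id == "r1"], "rRNA_unclassified")
})

test_that("oriC tables resolve centers, first-listed duplicates, and wrapping regions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\toric_start\toric_end",
               "acc1\t1000\t1200",
               "acc2\t500\t700",
               "acc2\t99000\t99200",     # duplicate: first listed wins
               "acc3\t99951\t50"), path) # wraps the coordinate origin
  oric <- parse_oric_table(path, genome_lengths = c(acc3 = 1e5))
  expect_equal(oric[["acc1"]], 1100)
  expect_equal(oric[["acc2"]], 600)
  d <- min(abs(oric[["acc3"]] - 1), 1e5 - abs(oric[["acc3"]] - 1))
  expect_lte(d, 0.5)
  expect_error(oric[["missing"]])
  # two parses are byte-identical (determinism of the duplicate rule)
  expect_identical(oric, parse_oric_table(path, genome_lengths = c(acc3 = 1e5)))
  expect_error(parse_oric_table(path), "genome_lengths")
})

test_that("class position means pool rRNA subtypes and flag absent classes", {
  genes <- data.frame(
    gene_id = c("r1", "r2", "t1"),
    gene_class = c("rRNA_16S", "rRNA_5S", "tRNA"),
    start = c(1, 1, 1), end = c(2, 2, 2), strand = "+",
    midpoint = c(1.1e6, 1.3e6, 1.7e6), stringsAsFactors = FALSE)
  g <- genome_record("sp", genes, genome_length = 4e6, oric = 1e6,
                     tau_min = 0.8)
  mc <- mean_class_positions(g)
  expect_equal(mc$position_rRNA, mean(c(0.05, 0.15)))
  expect_equal(mc$position_tRNA, 0.35)
  expect_equal(g$mu_max, log(2) / 0.8)
  expect_equal(g$growth_class, "fast")
  # single-class genome: absent class is NA, not zero
  g2 <- genome_record("sp2", genes[genes$gene_class == "tRNA", ],
                      genome_length = 4e6, oric = 1e6)
  mc2 <- mean_class_positions(g2)
  expect_true(is.na(mc2$position_rRNA))
  expect_equal(mc2$n_rRNA, 0)
})
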