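# oriC-relative gene positions on a circular chromosome.
#
# Conventions: 1-based inclusive coordinates (GenBank; GFF3 is identical).
# Midpoints keep half-integer values. A gene annotated across the origin
# (start > end) gets the circular midpoint.

#' Midpoint of a gene on a circular chromosome
#'
#' `(start + end)/2` for ordinary genes; for features wrapping the origin
#' (`start > end`) the midpoint is taken along the circular span and mapped
#' back into `(0, L]`. Half-integer midpoints are kept unrounded.
#'
#' @param start,end 1-based inclusive coordinates (bp).
#' @param genome_length chromosome length (bp).
#' @return midpoint coordinate (bp, possibly half-integer).
#' @export
gene_midpoint <- function(start, end, genome_length) {
  if (any(start < 1 | start > genome_length) ||
      any(end < 1 | end > genome_length))
    stop("coordinates must lie in [1, genome_length]", call. = FALSE)
  wrap <- start > end
  mid <- (start + end) / 2
  if (any(wrap)) {
    m <- start[wrap] + (end[wrap] + genome_length - start[wrap]) / 2
    mid[wrap] <- ifelse(m > genome_length, m - genome_length, m)
  }
  mid
}

#' Relative distance of a coordinate to oriC
#'
#' The shortest circular distance between `midpoint` and `oric`, divided by
#' half the chromosome length: 0 at oriC, 1 at the replication terminus,
#' 0.5 a quarter-genome to either side of oriC.
#'
#' @param midpoint gene midpoint (bp).
#' @param oric oriC center coordinate (bp).
#' @inheritParams gene_midpoint
#' @return relative position in `[0, 1]`.
#' @export
relative_position <- function(midpoint, oric, genome_length) {
  if (any(midpoint <= 0 | midpoint > genome_length) ||
      any(oric <= 0 | oric > genome_length))
    stop("coordinates must lie in (0, genome_length]", call. = FALSE)
  d <- abs(midpoint - oric)
  d <- pmin(d, genome_length - d)
  d / (genome_length / 2)
}

#' Fast/slow growth classification
#'
#' Species with minimal doubling time <= 1 h (mu_max >= ln 2 = 0.69 h^-1)
#' are classified as fast-growing; these are the species expected to run
#' overlapping replication rounds and hence strong gene-dosage effects.
#'
#' @param tau_min minimal doubling time (h), vectorised.
#' @return character vector, `"fast"` or `"slow"`.
#' @export
classify_growth <- function(tau_min) {
  if (any(tau_min <= 0)) stop("'tau_min' must be > 0", call. = FALSE)
  ifelse(tau_min <= 1, "fast", "slow")
}

.RRNA_CLASSES <- c("rRNA_5S", "rRNA_16S", "rRNA_23S")

.classify_rrna <- function(text) {
  # case-insensitive match on 5S/16S/23S in product or gene name
  lc <- tolower(text)
  ifelse(grepl("16s", lc), "rRNA_16S",
         ifelse(grepl("23s", lc), "rRNA_23S",
                ifelse(grepl("\\b5s|(^|[^0-9])5s", lc), "rRNA_5S",
                       "rRNA_unclassified")))
}

#' Parse tRNA/rRNA features from a genome annotation
#'
#' Reads a GFF3 file (via rtracklayer) or a GenBank flat file (feature
#' table) and returns one record per tRNA or rRNA feature. rRNA subtypes
#' (5S/16S/23S) are inferred case-insensitively from the product or gene
#' name; rRNA features that match none are kept with class
#' `"rRNA_unclassified"` (still pooled as rRNA in position means) and
#' flagged via a warning. Pseudo-genes are excluded.
#'
#' @param file path to a `.gff`/`.gff3` or GenBank (`.gb`/`.gbk`/`.gbff`)
#'   annotation.
#' @param genome_length chromosome length (bp); taken from the file when it
#'   declares it (GFF3 `##sequence-region`, GenBank LOCUS line) and required
#'   otherwise.
#' @return data.frame with columns `gene_id`, `gene_class`, `start`, `end`,
#'   `strand`, `midpoint` (relative `position` is added once an oriC is
#'   known; see [genome_record()]).
#' @export
parse_annotation <- function(file, genome_length = NULL) {
  if (!file.exists(file)) stop("annotation file not found: ", file, call. = FALSE)
  first <- readLines(file, n = 1L, warn = FALSE)
  is_genbank <- grepl("^LOCUS", first)
  feats <- if (is_genbank) .parse_genbank(file) else .parse_gff3(file)
  if (is.null(genome_length)) genome_length <- attr(feats, "genome_length")
  if (is.null(genome_length) || is.na(genome_length))
    stop("genome length not declared in file; pass 'genome_length'", call. = FALSE)
  if (nrow(feats) == 0L)
    stop("no tRNA/rRNA features found in ", file, call. = FALSE)
  # circular-genome convention: features crossing the origin carry
  # end > genome length (GFF3) -- normalize to the wrapped start > end form
  over <- feats$end > genome_length
  feats$end[over] <- feats$end[over] - genome_length
  n_pseudo <- sum(feats$pseudo)
  feats <- feats[!feats$pseudo, , drop = FALSE]
  if (nrow(feats) == 0L)
    stop("all tRNA/rRNA features are pseudo-genes in ", file, call. = FALSE)
  gene_class <- ifelse(feats$type == "tRNA", "tRNA", .classify_rrna(feats$label))
  if (any(gene_class == "rRNA_unclassified"))
    warning(sum(gene_class == "rRNA_unclassified"),
            " rRNA feature(s) without a 5S/16S/23S label; pooled as rRNA",
            call. = FALSE)
  out <- data.frame(
    gene_id = feats$gene_id,
    gene_class = gene_class,
    start = feats$start,
    end = feats$end,
    strand = feats$strand,
    midpoint = gene_midpoint(feats$start, feats$end, genome_length),
    stringsAsFactors = FALSE)
  attr(out, "genome_length") <- genome_length
  attr(out, "n_pseudo_excluded") <- n_pseudo
  out
}

.parse_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  L <- NA_real_
  # sequence-region pragma, if present
  hdr <- grep("^##sequence-region", readLines(file, warn = FALSE), value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
    if (length(parts) >= 4) L <- as.numeric(parts[4])
  }
  type <- as.character(gr$type)
  keep <- type %in% c("tRNA", "rRNA")
  gr <- gr[keep]
  type <- type[keep]
  md <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (nm %in% names(md)) as.character(md[[nm]]) else rep(NA_character_, length(gr))
  }
  product <- getcol("product")
  gene <- getcol("gene")
  id <- getcol("ID")
  pseudo <- getcol("pseudo")
  pseudo <- !is.na(pseudo) & tolower(pseudo) %in% c("true", "1", "yes")
  label <- ifelse(is.na(product), ifelse(is.na(gene), "", gene), product)
  ids <- ifelse(is.na(id), ifelse(is.na(gene), paste0(type, "_", seq_along(gr)), gene), id)
  out <- data.frame(
    gene_id = ids, type = type,
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    label = label, pseudo = pseudo, stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  attr(out, "genome_length") <- L
  out
}

# Minimal GenBank flat-file feature-table reader covering what annotation
# dumps contain for tRNA/rRNA: LOCUS length, feature keys at column 6,
# locations `a..b`, `complement(a..b)` and origin-wrapping
# `join(a..L,1..b)`, and /product /gene /pseudo qualifiers.
.parse_genbank <- function(file) {
  lines <- readLines(file, warn = FALSE)
  L <- NA_real_
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus)) {
    m <- regmatches(locus[1], regexec("([0-9]+)\\s+bp", locus[1]))[[1]]
    if (length(m) == 2) L <- as.numeric(m[2])
  }
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("no FEATURES section in ", file, call. = FALSE)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]

  is_key <- grepl("^ {5}\\S", flines)
  key_idx <- which(is_key)
  recs <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    j <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(flines)
    key <- sub("^\\s*(\\S+).*$", "\\1", flines[i])
    if (!key %in% c("tRNA", "rRNA")) next
    block <- flines[i:j]
    loc <- sub("^\\s*\\S+\\s+", "", block[1])
    # location may continue onto lines that are not qualifiers
    extra <- block[-1]
    qual_start <- grep("^\\s+/", extra)
    if (length(qual_start) && qual_start[1] > 1)
      loc <- paste0(loc, paste(trimws(extra[seq_len(qual_start[1] - 1)]), collapse = ""))
    quals <- grep("^\\s+/", extra, value = TRUE)
    getq <- function(name) {
      hit <- grep(paste0("^\\s+/", name, "="), quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub("\"", "", sub(paste0("^\\s+/", name, "="), "", hit[1]))
    }
    pseudo <- any(grepl("^\\s+/pseudo(\\s*$|=)", quals))
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2) next
    if (grepl("join", loc) && length(nums) >= 4) {
      start <- nums[1]; end <- nums[length(nums)]   # origin-wrapping join
    } else {
      start <- min(nums[1:2]); end <- max(nums[1:2])
    }
    product <- getq("product"); gene <- getq("gene"); ltag <- getq("locus_tag")
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = if (!is.na(ltag)) ltag else if (!is.na(gene)) gene else
        paste0(key, "_", length(recs) + 1L),
      type = key, start = start, end = end, strand = strand,
      label = if (!is.na(product)) product else if (!is.na(gene)) gene else "",
      pseudo = pseudo, stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene_id = character(), type = character(), start = numeric(),
               end = numeric(), strand = character(), label = character(),
               pseudo = logical(), stringsAsFactors = FALSE)
  attr(out, "genome_length") <- L
  out
}

#' Parse a DoriC-style oriC table
#'
#' TSV with columns `accession`, `oric_start`, `oric_end` (1-based
#' inclusive). Returns the center of the oriC region per accession; for
#' regions wrapping the coordinate origin the circular center is used. When
#' several oriCs are listed for one accession the first listed is taken
#' (deterministic; annotated oriCs of one chromosome lie within a fraction
#' of a percent of the genome length of each other, so the choice is
#' immaterial).
#'
#' @param file TSV path.
#' @param genome_lengths named numeric vector (names = accessions) needed to
#'   resolve wrapping oriC regions; optional otherwise.
#' @return named numeric vector of oriC center coordinates (bp).
#' @export
parse_oric_table <- function(file, genome_lengths = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("accession", "oric_start", "oric_end")
  if (!all(need %in% names(tab)))
    stop("oriC table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- tab[!duplicated(tab$accession), , drop = FALSE]  # first listed wins
  centers <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- tab$oric_start[i]; e <- tab$oric_end[i]
    if (s <= e) {
      centers[i] <- (s + e) / 2
    } else {
      L <- genome_lengths[[tab$accession[i]]]
      if (is.null(L) || is.na(L))
        stop("wrapping oriC for ", tab$accession[i],
             " requires genome_lengths", call. = FALSE)
      centers[i] <- gene_midpoint(s, e, L)
    }
  }
  stats::setNames(centers, tab$accession)
}

#' Assemble a genome record with oriC-relative gene positions
#'
#' Combines parsed annotation features, the chromosome length and the oriC
#' center into a single per-species record; computes each gene's relative
#' position and, when a minimal doubling time is given, the maximal growth
#' rate `mu_max = ln 2 / tau_min` and the fast/slow class.
#'
#' @param species species or accession label.
#' @param genes data.frame as returned by [parse_annotation()].
#' @param genome_length chromosome length (bp).
#' @param oric oriC center coordinate (bp).
#' @param tau_min optional minimal doubling time (h).
#' @return object of class `"genome_record"`.
#' @export
genome_record <- function(species, genes, genome_length, oric,
                          tau_min = NA_real_) {
  genes$position <- relative_position(genes$midpoint, oric, genome_length)
  mu_max <- if (is.na(tau_min)) NA_real_ else log(2) / tau_min
  growth_class <- if (is.na(tau_min)) NA_character_ else classify_growth(tau_min)
  structure(list(species = species, genome_length = genome_length,
                 oric_position = oric, genes = genes,
                 tau_min = tau_min, mu_max = mu_max,
                 growth_class = growth_class),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, oriC at %s bp, %d tRNA + %d rRNA genes",
              x$species, round(x$genome_length), format(x$oric_position),
              sum(x$genes$gene_class == "tRNA"),
              sum(x$genes$gene_class != "tRNA")))
  if (!is.na(x$mu_max))
    cat(sprintf(", mu_max %.2f h^-1 (%s)", x$mu_max, x$growth_class))
  cat("\n")
  invisible(x)
}

#' Mean oriC-relative position per gene class
#'
#' Unweighted arithmetic means of the relative positions of tRNA genes and
#' of rRNA genes (5S/16S/23S pooled). A missing class is reported as `NA`
#' (absent), never as zero.
#'
#' @param genome a [genome_record()].
#' @return named list with `position_tRNA`, `position_rRNA`, and gene counts
#'   `n_tRNA`, `n_rRNA`.
#' @export
mean_class_positions <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  is_t <- g$gene_class == "tRNA"
  is_r <- startsWith(g$gene_class, "rRNA")
  list(
    position_tRNA = if (any(is_t)) mean(g$position[is_t]) else NA_real_,
    position_rRNA = if (any(is_r)) mean(g$position[is_r]) else NA_real_,
    n_tRNA = sum(is_t),
    n_rRNA = sum(is_r))
}
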