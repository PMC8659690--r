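# Phylogenetically independent contrasts and the nonparametric tests used
# in the cross-species survey.

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm on a rooted, fully binary tree with
#' branch lengths: in postorder, each internal node contributes the
#' standardized contrast `(x1 - x2)/sqrt(v1 + v2)` of its two daughters,
#' the ancestral value is the precision-weighted average
#' `(x1/v1 + x2/v2)/(1/v1 + 1/v2)`, and the node's parent branch is
#' extended by `v1 v2/(v1 + v2)`.
#'
#' Implemented here directly (rather than delegating) because downstream
#' correlation tests on contrasts are the package's inference layer; tests
#' verify the output against generalized-least-squares whitening under the
#' Brownian-motion covariance.
#'
#' @param tree an [ape::phylo] object, rooted and binary, with branch
#'   lengths. Zero-length branches are inflated to `1e-8` with a warning.
#' @param trait named numeric vector; names must match `tree$tip.label`.
#' @return object of class `"contrast_set"`: numeric vector of `n_tips - 1`
#'   standardized contrasts named by internal node number (ape numbering,
#'   root first), in deterministic node order.
#' @export
pic_contrasts <- function(tree, trait) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree))
    stop("tree must be fully binary; resolve polytomies first (see resolve_polytomies)",
         call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    stop("trait must be named by the tree's tip labels", call. = FALSE)
  if (any(tree$edge.length == 0)) {
    warning("zero-length branches inflated to 1e-8 for contrast standardization",
            call. = FALSE)
    tree$edge.length[tree$edge.length == 0] <- 1e-8
  }

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  x <- c(trait[tree$tip.label], rep(NA_real_, n_node))
  v <- numeric(n_tip + n_node)  # extra variance accumulated at each node
  blen <- numeric(n_tip + n_node)
  blen[tree$edge[, 2]] <- tree$edge.length

  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge
  contrasts <- stats::setNames(rep(NA_real_, n_node),
                               as.character((n_tip + 1):(n_tip + n_node)))
  # postorder edges come in daughter pairs per internal node
  for (i in seq(1, nrow(edge), by = 2)) {
    node <- edge[i, 1]
    c1 <- edge[i, 2]; c2 <- edge[i + 1, 2]
    v1 <- blen[c1] + v[c1]
    v2 <- blen[c2] + v[c2]
    contrasts[as.character(node)] <- (x[c1] - x[c2]) / sqrt(v1 + v2)
    x[node] <- (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    v[node] <- v1 * v2 / (v1 + v2)
  }
  # report in increasing node number (root first), as is conventional
  out <- contrasts[order(as.integer(names(contrasts)))]
  structure(out, class = c("contrast_set", "numeric"))
}

#' Resolve polytomies deterministically
#'
#' Orders tips by name, then resolves multifurcations into a binary tree
#' with zero-length internal branches (ape's `multi2di` with `random =
#' FALSE`). Zero branches are later inflated by [pic_contrasts()].
#'
#' @inheritParams pic_contrasts
#' @export
resolve_polytomies <- function(tree) {
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::multi2di(tree, random = FALSE)
}

#' Correlation test on independent contrasts
#'
#' Contrasts have arbitrary sign, so association is measured through the
#' origin: `r = sum(xy)/sqrt(sum(x^2) sum(y^2))`, with a two-sided t test on
#' `n - 1` degrees of freedom (regression through the origin on `n`
#' contrast pairs). A rank-based variant (Spearman on the contrast pairs)
#' is exposed as a robustness check.
#'
#' @param contrasts_x,contrasts_y numeric vectors of equal length >= 2
#'   (e.g. from [pic_contrasts()]).
#' @param method `"pearson_origin"` (default, standard contrast practice)
#'   or `"spearman"`.
#' @return list with `estimate` (correlation), `p_value`, `n`, `method`.
#' @export
pic_correlation_test <- function(contrasts_x, contrasts_y,
                                 method = c("pearson_origin", "spearman")) {
  method <- match.arg(method)
  n <- length(contrasts_x)
  if (n != length(contrasts_y)) stop("length mismatch", call. = FALSE)
  if (n < 2L) stop("need at least 2 contrasts", call. = FALSE)
  if (method == "spearman") {
    ct <- suppressWarnings(
      stats::cor.test(contrasts_x, contrasts_y, method = "spearman"))
    return(list(estimate = unname(ct$estimate), p_value = ct$p.value,
                n = n, method = method))
  }
  sxx <- sum(contrasts_x^2); syy <- sum(contrasts_y^2)
  if (sxx == 0 || syy == 0)
    stop("all-zero contrasts; correlation undefined", call. = FALSE)
  r <- sum(contrasts_x * contrasts_y) / sqrt(sxx * syy)
  df <- n - 1L
  r <- max(min(r, 1), -1)
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  list(estimate = r, p_value = p, n = n, method = method)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of symmetry about `null_location`; values
#' exactly equal to the null are dropped, and at least 5 must remain.
#'
#' @param values numeric vector.
#' @param null_location hypothesized center.
#' @return two-sided p-value.
#' @export
one_sample_wilcoxon <- function(values, null_location) {
  kept <- values[values != null_location]
  if (length(kept) < 5L)
    stop("fewer than 5 values differ from the null location", call. = FALSE)
  suppressWarnings(
    stats::wilcox.test(kept, mu = null_location, alternative = "two.sided")$p.value)
}

#' F test for equality of variances
#'
#' Two-sided variance-ratio test of two independent samples.
#'
#' @param sample1,sample2 numeric vectors, each of length >= 2.
#' @return two-sided p-value.
#' @export
variance_f_test <- function(sample1, sample2) {
  if (length(sample1) < 2L || length(sample2) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::var(sample1) == 0 && stats::var(sample2) == 0)
    stop("both samples have zero variance", call. = FALSE)
  stats::var.test(sample1, sample2, alternative = "two.sided")$p.value
}
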