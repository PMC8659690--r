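test_that("two-tip and constant-trait contrasts follow the closed form", {
  tr <- ape::read.tree(text = "(A:1.5,B:2.5);")
  expect_equal(as.numeric(pic_contrasts(tr, c(A = 3, B = 1))),
               (3 - 1) / sqrt(1.5 + 2.5))
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(as.numeric(pic_contrasts(tr3, c(A = 7, B = 7, C = 7))),
               c(0, 0))
})

test_that("the 3-taxon hand recursion is reproduced up to sign", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  got <- sort(abs(as.numeric(pic_contrasts(tr, c(A = 1, B = 3, C = 6)))))
  # (1-3)/sqrt(2) and (2-6)/sqrt(1.5+2): ancestral value 2, branch 1+0.5
  expect_equal(got, sort(abs(c(-2 / sqrt(2), -4 / sqrt(3.5)))),
               tolerance = 1e-12)
})

test_that("contrasts match ape::pic across random trees", {
  for (s in 1:5) {
    tt <- generate_tree_with_traits(10, seed = 100 + s)
    mine <- as.numeric(pic_contrasts(tt$tree, tt$traits[, 1]))
    ref <- as.numeric(ape::pic(tt$traits[tt$tree$tip.label, 1], tt$tree))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("contrasts whiten the Brownian-motion covariance on trees up to 6 tips", {
  for (n in 3:6) {
    tt <- generate_tree_with_traits(n, seed = 200 + n)
    D <- contrast_matrix(tt$tree)
    V <- ape::vcv(tt$tree)
    W <- D %*% V %*% t(D)
    expect_lt(max(abs(W - diag(n - 1))), 1e-8)
  }
})

test_that("invalid trees and traits are rejected; zero branches are inflated with a warning", {
  tt <- generate_tree_with_traits(6, seed = 9)
  unrooted <- ape::unroot(tt$tree)
  expect_error(pic_contrasts(unrooted, tt$traits[, 1]), "rooted")
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  expect_error(pic_contrasts(poly, c(A = 1, B = 2, C = 3, D = 4)), "binary")
  resolved <- resolve_polytomies(poly)
  expect_true(ape::is.binary(resolved))
  expect_warning(pic_contrasts(resolved, c(A = 1, B = 2, C = 3, D = 4)),
                 "zero-length")
  bad <- tt$traits[, 1]; names(bad)[1] <- "nope"
  expect_error(pic_contrasts(tt$tree, bad), "tip labels")
  noblen <- tt$tree; noblen$edge.length <- NULL
  expect_error(pic_contrasts(noblen, tt$traits[, 1]), "branch lengths")
})

test_that("flipping child order flips at most contrast signs, not p-values", {
  tt <- generate_tree_with_traits(12, seed = 77, n_traits = 2)
  rot <- ape::rotate(tt$tree, node = length(tt$tree$tip.label) + 1)
  a1 <- pic_contrasts(tt$tree, tt$traits[, 1])
  a2 <- pic_contrasts(rot, tt$traits[, 1])
  b1 <- pic_contrasts(tt$tree, tt$traits[, 2])
  b2 <- pic_contrasts(rot, tt$traits[, 2])
  expect_equal(sort(abs(as.numeric(a1))), sort(abs(as.numeric(a2))),
               tolerance = 1e-12)
  p1 <- pic_correlation_test(a1, b1)$p_value
  p2 <- pic_correlation_test(a2, b2)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("through-origin correlation of contrasts behaves at the extremes", {
  tt <- generate_tree_with_traits(20, seed = 13)
  cx <- as.numeric(pic_contrasts(tt$tree, tt$traits[, 1]))
  res <- pic_correlation_test(cx, 3 * cx)
  expect_equal(res$estimate, 1)
  expect_lt(res$p_value, 1e-12)
  # orthogonal-by-construction: project out cx
  cy <- rnorm(length(cx))
  cy <- cy - cx * sum(cx * cy) / sum(cx^2)
  expect_equal(pic_correlation_test(cx, cy)$estimate, 0, tolerance = 1e-12)
  expect_error(pic_correlation_test(cx, cy[-1]), "mismatch")
  # rank-based variant runs and agrees in sign on a strong signal
  expect_gt(pic_correlation_test(cx, 3 * cx, method = "spearman")$estimate,
            0.99)
})

test_that("one-sample Wilcoxon p-values match the exact signed-rank distribution", {
  # symmetric sample about the null: p close to 1
  sym <- c(-4, -3, -2, -1, 1, 2, 3, 4) + 0.5
  expect_gt(one_sample_wilcoxon(sym, 0.5), 0.9)
  # all 20 values strictly below the null: two-sided p = 2/2^20 < 1e-4
  below <- seq(0.1, 0.48, length.out = 20)
  p <- one_sample_wilcoxon(below, 0.5)
  expect_lt(p, 1e-4)
  expect_equal(p, 2 / 2^20, tolerance = 1e-10)
  expect_error(one_sample_wilcoxon(c(0.5, 0.5, 0.4, 0.3, 0.2, 0.1), 0.5),
               "fewer than 5")
})

test_that("variance F test is two-sided, symmetric, and sharp at extreme ratios", {
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(variance_f_test(c(x, x), c(x, x)), 1)
  expect_equal(variance_f_test(x, y), variance_f_test(y, x))
  set.seed(4)
  a <- rnorm(50, sd = 1); b <- rnorm(50, sd = 10)  # variance ratio ~100
  expect_lt(variance_f_test(a, b), 1e-15)
  expect_error(variance_f_test(rep(1, 5), rep(2, 5)), "zero variance")
})
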