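test_that("correlation matrix has unit diagonal and honors rank reversal", {
  m <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(6, 5, 4, 3, 2, 1),
             c = c(2, 4, 5, 7, 8, 12))
  cc <- correlation_matrix(m, method = "spearman")
  expect_equal(unname(diag(cc)), c(1, 1, 1))
  expect_equal(cc["a", "b"], -1)
  expect_equal(cc["a", "c"], 1)
  expect_equal(cc, t(cc))
})

test_that("spearman equals rank-then-pearson with average ranks for ties", {
  x <- c(3.1, 0.2, 0.2, 5.5, 4.0, 2.2)
  y <- c(10, 2, 4, 30, 30, 7)
  # hand oracle: average ranks, then the Pearson product-moment formula
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  want <- pearson(rk(x), rk(y))
  got <- correlation_matrix(cbind(x = x, y = y), method = "spearman")["x", "y"]
  expect_equal(got, want)
  # invariance under a strictly monotone transform
  got2 <- correlation_matrix(cbind(x = exp(x), y = y),
                             method = "spearman")["x", "y"]
  expect_equal(got2, want)
})

test_that("pairs with too few complete rows become NA with a warning", {
  m <- cbind(a = c(1, 2, NA, NA, 5), b = c(2, 1, 3, 4, NA))
  expect_warning(cc <- correlation_matrix(m), "fewer than")
  expect_true(is.na(cc["a", "b"]))
  expect_equal(cc["a", "a"], 1)
})

test_that("complete-linkage clustering merges identical columns first", {
  m <- cbind(a = c(1, 2, 3, 9), b = c(1, 2, 3, 9), c = c(9, 5, 1, 0),
             d = c(8, 5, 2, 1))
  cc <- correlation_matrix(m, method = "pearson")
  hc <- hcluster(cc)
  expect_equal(hc$height[1], 0)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("a", "b"))
  # planted two-block structure is recovered at k = 2
  blocks <- cutree(hc, k = 2)
  expect_equal(blocks[["a"]], blocks[["b"]])
  expect_equal(blocks[["c"]], blocks[["d"]])
  expect_false(blocks[["a"]] == blocks[["c"]])
  # missing cells are refused with advice
  cc_na <- cc; cc_na[1, 2] <- NA
  expect_error(hcluster(cc_na), "pairwise-complete")
  # newick export carries the leaf labels
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  for (lab in colnames(m)) expect_match(nwk, lab)
})

test_that("PCA centers variables and reports variance fractions", {
  set.seed(11)
  base <- matrix(rnorm(40), 20, 2)
  m <- cbind(base[, 1], base[, 1], base[, 2], base[, 2] + 0.01)
  colnames(m) <- c("c1", "c1dup", "c2", "c2eps")
  p <- profile_pca(m)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_equal(p$scores["c1", ], p$scores["c1dup", ])
  # planted one-factor structure: PC1 separates the duplicated groups
  grp <- c(1, 1, 2, 2)
  pc1 <- p$scores[, 1]
  expect_true(max(pc1[grp == 1]) < min(pc1[grp == 2]) ||
                min(pc1[grp == 1]) > max(pc1[grp == 2]))
  # complete-case handling drops rows with NA
  m_na <- m; m_na[1, 1] <- NA
  expect_equal(profile_pca(m_na)$n_features, 19)
})

test_that("Jensen-Shannon distance matches closed-form values", {
  expect_equal(jsd(c(1, 0), c(1, 0)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)  # disjoint supports, log base 2
  # jsd((1,0),(.5,.5)) = H(0.75, 0.25) - 0.5
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), h - 0.5)
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), 0.31128, tolerance = 1e-5)
  m <- cbind(p = c(1, 0), q = c(0.5, 0.5))
  d <- jsd_matrix(m)
  expect_equal(d["p", "q"], 0.55792, tolerance = 1e-5)
  expect_equal(diag(d), c(p = 0, q = 0))
  expect_error(jsd_matrix(cbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("sqrt-JSD satisfies the triangle inequality on random triples", {
  set.seed(33)
  for (i in 1:25) {
    m <- matrix(stats::rexp(30), 10, 3)
    d <- jsd_matrix(m)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("label dominance scores nearest-neighbor label agreement", {
  # block-diagonal correlation by species
  cc <- rbind(c(1, .9, .1, .1), c(.9, 1, .1, .1),
              c(.1, .1, 1, .8), c(.1, .1, .8, 1))
  colnames(cc) <- rownames(cc) <- paste0("c", 1:4)
  expect_equal(label_dominance(cc, c("s1", "s1", "s2", "s2")), 1)
  expect_equal(label_dominance(cc, c("s1", "s2", "s1", "s2")), 0)
  # random symmetric matrices: dominance fluctuates around the
  # label-share baseline (1/5 here: 1 of 5 partners shares the label)
  set.seed(7)
  doms <- replicate(300, {
    a <- matrix(stats::runif(36), 6)
    cc <- (a + t(a)) / 2; diag(cc) <- 1
    label_dominance(cc, rep(c("x", "y", "z"), each = 2))
  })
  expect_equal(mean(doms), 1 / 5, tolerance = 0.05)
})
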