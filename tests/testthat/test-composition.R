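test_that("Bray-Curtis matches the hand formula and its metric properties", {
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2, 3), c(3, 2, 1)))), 1 / 3)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 4)))), 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "a")
  # formula oracle on random matrices
  set.seed(1)
  m <- matrix(rpois(5 * 8, 4), 5, 8)
  d <- as.matrix(bray_curtis(m))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j], sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("PCA axes order variance and reconstruct the data", {
  # two perfectly correlated variables: one axis carries 100%
  x <- rnorm(20)
  p1 <- ordinate_pca(cbind(a = x, b = 2 * x + 1), scale = TRUE)
  expect_equal(p1$percent[1], 100)
  set.seed(2)
  tab <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, letters[1:5]))
  p <- ordinate_pca(tab, scale = FALSE)
  expect_true(all(diff(p$percent) <= 1e-12))
  expect_equal(sum(p$percent), 100)
  # full reconstruction of the centered table
  centered <- scale(tab, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(centered),
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues agree with an independent eigen-decomposition
  expect_equal(p$eigenvalues, eigen(cov(tab))$values, tolerance = 1e-10)
  expect_warning(ordinate_pca(cbind(tab, k = rep(1, 30))), "constant")
  expect_error(suppressWarnings(
    ordinate_pca(cbind(k1 = rep(1, 30), k2 = rep(2, 30)))), "non-constant")
})

test_that("DCA keeps CA axis 1 and suppresses the arch on a gradient", {
  grad <- seq(0, 100, length.out = 20)
  mu <- seq(0, 100, length.out = 30)
  m <- sapply(mu, function(o) gaussian_niche(grad, o, 12, 10))
  rownames(m) <- paste0("s", 1:20)
  d <- ordinate_dca(m)
  # axis-1 ranks recover the gradient exactly (up to reversal)
  expect_equal(abs(cor(d$scores[, 1], grad, method = "spearman")), 1)
  # arch suppressed: detrended axis-2 variance well below axis 1
  expect_lt(var(d$scores[, 2]), 0.25 * var(d$scores[, 1]))
  # axis 1 agrees in rank with vegan's implementation
  dec <- vegan::decorana(m)
  expect_equal(abs(cor(d$scores[, 1], vegan::scores(dec)[, 1],
                       method = "spearman")), 1)
  # identical samples get identical scores
  m2 <- rbind(m, m[3, , drop = FALSE])
  rownames(m2) <- c(rownames(m), "dup")
  d2 <- ordinate_dca(m2)
  expect_equal(d2$scores["dup", ], d2$scores["s3", ], ignore_attr = TRUE)
  expect_error(ordinate_dca(m, n_segments = 1), "n_segments")
  expect_warning(ordinate_dca(rbind(m, 0)), "zero-sum")
})

# independent pseudo-F oracle, written from the sums-of-squares definition
oracle_pseudo_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  g <- length(unique(groups))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (k in unique(groups)) {
    idx <- which(groups == k)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

test_that("PERMANOVA pseudo-F and exact p agree with enumeration and vegan", {
  set.seed(3)
  m <- matrix(runif(6 * 5), 6, 5, dimnames = list(letters[1:6], NULL))
  d <- bray_curtis(m)
  groups <- rep(c("g1", "g2"), each = 3)
  pv <- permanova(d, groups, n_perm = 999)
  expect_true(pv$exhaustive)
  expect_equal(pv$ss_total, pv$ss_within + pv$ss_between, tolerance = 1e-9)
  expect_equal(pv$pseudo_f, oracle_pseudo_f(d, groups))
  # exhaustive p from brute-force enumeration of all 20 assignments
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    lab <- rep("g2", 6); lab[idx] <- "g1"
    oracle_pseudo_f(d, lab)
  })
  expect_equal(pv$p, mean(fs >= pv$pseudo_f))
  # one-way pseudo-F matches vegan::adonis2 on a larger random set
  set.seed(4)
  m2 <- matrix(rpois(24 * 10, 6), 24, 10)
  gr2 <- rep(c("a", "b", "c"), each = 8)
  d2 <- bray_curtis(m2)
  pv2 <- permanova(d2, gr2, n_perm = 199, seed = 1)
  ad <- vegan::adonis2(d2 ~ gr2, permutations = 99)
  expect_equal(pv2$pseudo_f, ad$F[1], tolerance = 1e-8)
  expect_gt(pv2$p, 0)
  expect_lte(pv2$p, 1)
})

test_that("PERMANOVA is invariant to consistent relabeling and validates input", {
  set.seed(5)
  m <- matrix(runif(12 * 4), 12, 4)
  d <- bray_curtis(m)
  gr <- rep(c("x", "y"), each = 6)
  p1 <- permanova(d, gr, n_perm = 199, seed = 7)
  p2 <- permanova(d, ifelse(gr == "x", "B", "A"), n_perm = 199, seed = 7)
  expect_equal(p1$pseudo_f, p2$pseudo_f)
  # permuting samples together with labels leaves F unchanged
  perm <- sample(12)
  p3 <- permanova(as.matrix(d)[perm, perm], gr[perm], n_perm = 199, seed = 7)
  expect_equal(p1$pseudo_f, p3$pseudo_f)
  expect_error(permanova(d, c(rep("x", 11), "y"), n_perm = 99), "size 1")
  expect_error(permanova(d, gr, n_perm = 50), "99")
})
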