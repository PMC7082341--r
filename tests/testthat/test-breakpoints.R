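test_that("broken-stick fit recovers noiseless breakpoints exactly", {
  x <- rep(seq(700, 3760, length.out = 18), each = 4)
  y <- 1 + 0.002 * x + 0.003 * pmax(x - 2400, 0)
  f <- piecewise_fit(x, y, band = c(1800, 3000), n_null = 0)
  expect_equal(f$psi, 2400)
  expect_lt(f$sse, 1e-18)
  expect_equal(f$beta1, 0.002, tolerance = 1e-9)
  expect_equal(f$beta2, 0.003, tolerance = 1e-9)
  expect_error(piecewise_fit(x, y, band = c(4000, 5000)), "band")
  expect_error(piecewise_fit(x[1:4], y[1:4], band = c(1800, 3000)), ">= 6")
})

test_that("grid search equals an independently coded brute-force minimizer", {
  x <- rep(seq(700, 3760, length.out = 18), each = 3)
  set.seed(11)
  for (rep_ in 1:10) {
    y <- rnorm(length(x)) + 0.001 * x
    f <- piecewise_fit(x, y, band = c(1800, 3000), n_null = 0)
    psi_grid <- seq(1800, 3000, by = 1)
    sses <- vapply(psi_grid, function(p)
      sum(lm.fit(cbind(1, x, pmax(x - p, 0)), y)$residuals^2), numeric(1))
    j <- which.min(sses)
    expect_equal(f$psi, psi_grid[j])
    expect_equal(f$sse, sses[j], tolerance = 1e-9)
    # nesting: the broken stick never fits worse than the single line
    expect_lte(f$sse, f$sse_linear + 1e-12)
  }
})

test_that("bootstrap CI collapses without noise and is seed-stable", {
  x <- rep(seq(700, 3760, length.out = 18), each = 3)
  y <- 2 - 0.001 * x + 0.004 * pmax(x - 2400, 0)
  f <- breakpoint_bootstrap(x, y, band = c(1800, 3000), n_boot = 99,
                            seed = 5)
  expect_equal(c(f$ci_low, f$ci_high), c(2400, 2400))
  expect_false(f$ci_edge_limited)
  f2 <- breakpoint_bootstrap(x, y, band = c(1800, 3000), n_boot = 99,
                             seed = 5)
  expect_identical(f$psi_boot, f2$psi_boot)
})

test_that("bootstrap CI widens with noise", {
  x <- rep(seq(700, 3760, length.out = 18), each = 5)
  base <- 0.001 * x + 0.004 * pmax(x - 2400, 0)
  widths <- vapply(1:15, function(s) {
    set.seed(s)
    lo <- breakpoint_bootstrap(x, base + rnorm(length(x), 0, 0.2),
                               band = c(1800, 3000), n_boot = 99, seed = s)
    hi <- breakpoint_bootstrap(x, base + rnorm(length(x), 0, 2),
                               band = c(1800, 3000), n_boot = 99, seed = s)
    (hi$ci_high - hi$ci_low) - (lo$ci_high - lo$ci_low)
  }, numeric(1))
  expect_gt(mean(widths), 0)
  expect_gt(mean(widths > 0), 0.7)
})

test_that("adjacent turnover selects the pair straddling the planted fault", {
  b <- default_bundle(seed = 7)
  tv <- adjacent_turnover(b$otu_matrix, b$samples$site_id, site_elev_of(b),
                          band = c(1800, 3000), n_perm = 99, seed = 1)
  expect_s3_class(tv, "turnover_profile")
  sel <- tv$profile[tv$selected, ]
  expect_lt(sel$elev_lo, 2400)
  expect_gt(sel$elev_hi, 2400)
  expect_within_one_spacing(tv$breakpoint, 2400)
  expect_true(all(tv$profile$pseudo_f >= 0))
  expect_true(all(tv$profile$midpoint[tv$selected] >= 1800))
  # when one pair maximizes both statistics, rank-sum selection is argmax
  in_band <- tv$profile$midpoint >= 1800 & tv$profile$midpoint <= 3000
  both_max <- which(tv$profile$pseudo_f == max(tv$profile$pseudo_f[in_band]) &
                      tv$profile$dissimilarity ==
                        max(tv$profile$dissimilarity[in_band]))
  if (length(both_max) == 1) expect_equal(tv$selected, both_max)
  expect_error(
    adjacent_turnover(b$otu_matrix, b$samples$site_id, site_elev_of(b),
                      band = c(2420, 2450), n_perm = 99),
    "band")
})

test_that("split density peaks where a step taxon changes", {
  set.seed(8)
  elev <- rep(seq(700, 3760, length.out = 18), each = 10)
  m <- cbind(step = ifelse(elev > 2400, 40, 2) + rpois(length(elev), 2),
             flat = rep(5, length(elev)))
  sd_ <- split_density(m, elev)
  expect_within_one_spacing(sd_$peak, 2400)
  # first split of the step taxon dominates
  top <- sd_$splits[which.max(sd_$splits$weight), ]
  expect_equal(top$taxon, "step")
  expect_within_one_spacing(top$threshold, 2400)
  # constant matrix: no splits, flat zero density
  expect_message(
    sd0 <- split_density(matrix(3, 60, 2, dimnames = NULL),
                         elev[1:60]), "flat")
  expect_true(all(sd0$raw == 0))
  expect_true(is.na(sd0$peak))
  # scale equivariance of variance-reduction splits
  sd2 <- split_density(2 * m, elev)
  expect_equal(sd_$splits$threshold, sd2$splits$threshold)
  expect_equal(sd_$peak, sd2$peak)
})

test_that("cross-mountain comparison flags flat profiles and validates input", {
  m <- matrix(rpois(40, 6), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
  elev <- c(1000, 1000, 2000, 2000)
  cm <- cross_mountain(m, m, elev, elev, pairing_tol = 50)
  expect_true(cm$flat)
  expect_true(all(cm$pairs$similarity == 1))
  expect_true(is.na(cm$min_elevation))
  expect_error(cross_mountain(m, m, elev, elev + 500, pairing_tol = 50),
               "tolerance")
})

test_that("consensus summaries aggregate per facet", {
  mk <- function(psi, p = 0.01) structure(
    list(psi = psi, p_improvement = p), class = "breakpoint_fit")
  one <- consensus_breakpoints(list(mk(2400)), "funs")
  expect_equal(one$mean, 2400)
  expect_equal(one$n, 1)
  same <- consensus_breakpoints(list(mk(2400), mk(2400), mk(2400)),
                                rep("funs", 3))
  expect_equal(same$q3 - same$q1, 0)
  mixed <- consensus_breakpoints(
    list(mk(2000), mk(2200), mk(2600, p = 0.5), mk(2800)),
    c("a", "a", "b", "b"))
  expect_equal(nrow(mixed), 2)
  expect_equal(sum(mixed$mean * mixed$n) / sum(mixed$n),
               mean(c(2000, 2200, 2600, 2800)))
  expect_equal(mixed$n_significant, c(2, 1))
})
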