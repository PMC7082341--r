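test_that("geochemical indices follow the molar formulas", {
  g <- geochem_indices(data.frame(Al2O3 = 50, CaO_star = 20, Na2O = 15,
                                  K2O = 15, Ti = 1, Fe = 2, Al = 4, Mg = 1,
                                  Ca = 2))
  expect_equal(g$CIA, 50)
  expect_equal(g$Ca_Al, 0.5)
  expect_equal(g$Ti_Fe, 0.5)
  g2 <- geochem_indices(data.frame(Al2O3 = 7, CaO_star = 7, Na2O = 7,
                                   K2O = 7, Ti = 1, Fe = 1, Al = 1, Mg = 1,
                                   Ca = 1))
  expect_equal(g2$CIA, 25)
  expect_warning(
    g3 <- geochem_indices(data.frame(Al2O3 = 1, CaO_star = 1, Na2O = 1,
                                     K2O = 1, Ti = 1, Fe = 0, Al = 1,
                                     Mg = 1, Ca = 1)), "Ti/Fe")
  expect_true(is.na(g3$Ti_Fe))
  expect_error(geochem_indices(data.frame(Al2O3 = 1)), "missing columns")
})

test_that("dereplication keeps the response-stronger member of each pair", {
  set.seed(10)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, 0, 1e-8)   # duplicate of x
  z <- rnorm(50)
  resp <- x + z + rnorm(50, 0, 0.5)
  der <- dereplicate_predictors(data.frame(x = x, y = y, z = z), resp)
  expect_equal(ncol(der$retained), 2)
  expect_true("z" %in% colnames(der$retained))
  expect_equal(nrow(der$log), 1)
  # strict threshold: a pair exactly at the threshold is untouched
  r_exact <- cor(x, resp)
  der2 <- dereplicate_predictors(data.frame(x = x, resp = resp),
                                 response = z, r_threshold = abs(r_exact))
  expect_equal(ncol(der2$retained), 2)
  # orthogonal predictors pass through unchanged
  der3 <- dereplicate_predictors(data.frame(x = x, z = z), resp)
  expect_identical(colnames(der3$retained), c("x", "z"))
  # keep-first rule
  der4 <- dereplicate_predictors(data.frame(x = x, y = y), keep = "first")
  expect_identical(colnames(der4$retained), "x")
})

test_that("model averaging weights and conditional betas behave", {
  set.seed(11)
  n <- 80
  x1 <- rnorm(n)
  y <- 0.8 * x1 + rnorm(n, 0, 0.5)
  single <- all_subsets_average(y, data.frame(x1 = x1))
  ols <- unname(coef(lm(scale(y) ~ scale(x1)))[2])
  expect_equal(single$table$beta, ols, tolerance = 1e-9)
  expect_equal(sum(single$models$weight), 1, tolerance = 1e-9)
  expect_true(all(single$table$importance >= 0 &
                    single$table$importance <= 1))
  # orthonormal predictors: averaged beta close to the full-model beta
  q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  yq <- q %*% c(1, -0.8, 0.6) + rnorm(n, 0, 0.3)
  avg <- all_subsets_average(drop(yq), as.data.frame(q))
  full <- coef(lm(scale(drop(yq)) ~ apply(q, 2, scale)))[-1]
  expect_equal(avg$table$beta, unname(full), tolerance = 0.01)
  # dropping the worst model and renormalizing keeps the |beta| ranking
  w_orig <- numeric(length(avg$coefficients))
  w_orig[as.integer(rownames(avg$models))] <- avg$models$weight
  worst <- which.max(avg$models$delta)
  drop_idx <- as.integer(rownames(avg$models))[worst]
  cond_beta <- function(var, weights) {
    has <- vapply(avg$coefficients, function(cf) var %in% names(cf),
                  logical(1))
    sum(weights[has] * vapply(avg$coefficients[has], `[[`, numeric(1),
                              var)) / sum(weights[has])
  }
  vars <- avg$table$predictor
  w2 <- w_orig; w2[drop_idx] <- 0; w2 <- w2 / sum(w2)
  b_before <- vapply(vars, cond_beta, numeric(1), weights = w_orig)
  b_after <- vapply(vars, cond_beta, numeric(1), weights = w2)
  expect_identical(order(abs(b_before)), order(abs(b_after)))
  expect_error(all_subsets_average(y, as.data.frame(matrix(rnorm(n * 16), n))),
               "dereplicate")
})

test_that("geological increments detect planted effects and ignore clones", {
  set.seed(12)
  n <- 120
  contemp <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  geo <- data.frame(g1 = rnorm(n), g2 = rnorm(n))
  y <- 0.7 * contemp$c1 + 0.6 * geo$g1 + rnorm(n)
  gi <- geo_increment(y, contemp, geo)
  expect_gt(gi$percent_increase, 0)
  expect_lt(gi$anova_p, 0.05)
  expect_gte(gi$fraction_significant, 0.5)
  expect_gte(gi$r2_full, gi$r2_contemporary)
  # a geological block duplicating contemporary columns adds nothing
  gi0 <- geo_increment(y, contemp,
                       data.frame(g1 = contemp$c1, g2 = contemp$c2))
  expect_equal(gi0$absolute_increase, 0, tolerance = 1e-12)
  expect_error(geo_increment(y, contemp, contemp), "disjoint")
})

test_that("variation partitioning satisfies its identity and planted cases", {
  set.seed(13)
  n <- 200
  a1 <- rnorm(n); a2 <- rnorm(n); b1 <- rnorm(n)
  y <- a1 - 0.5 * a2 + rnorm(n, 0, 0.7)
  vp <- variation_partition(y, data.frame(a1, a2), data.frame(b1))
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-9)
  expect_lt(abs(vp$b), 0.02)             # B is pure noise
  expect_equal(vp$a, vp$adj_r2_ab - vp$adj_r2_b, tolerance = 1e-12)
  # identity holds on arbitrary random inputs
  for (i in 1:5) {
    yy <- rnorm(50)
    vv <- variation_partition(yy, data.frame(p = rnorm(50)),
                              data.frame(q = rnorm(50), r = rnorm(50)))
    expect_equal(vv$a + vv$b + vv$c + vv$d, 1, tolerance = 1e-9)
  }
  expect_error(variation_partition(y, data.frame(a1), data.frame(a1)),
               "disjoint")
})

test_that("composite scores reduce to z-scores and balance equal effects", {
  set.seed(14)
  x <- rnorm(60)
  y <- 2 * x + rnorm(60)
  cs <- composite_score(data.frame(x = x), y)
  expect_equal(abs(cs$composite), abs((x - mean(x)) / sd(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sd(cs$composite), 1, tolerance = 1e-12)
  # two independent indicators with equal true effects get equal weight
  i1 <- rnorm(500); i2 <- rnorm(500)
  y2 <- i1 + i2 + rnorm(500, 0, 0.3)
  cs2 <- composite_score(data.frame(i1, i2), y2)
  expect_equal(unname(abs(cs2$weights[1])), unname(abs(cs2$weights[2])),
               tolerance = 0.1)
})

test_that("path analysis decomposes effects and reproduces saturated fits", {
  # deterministic chain: x -> m -> y with y = m = x
  x <- rnorm(30)
  dat <- data.frame(x = x, m = x, y = x)
  pm <- suppressWarnings(
    path_fit(dat, data.frame(from = c("x", "m"), to = c("m", "y")), "y"))
  ex <- pm$effects[pm$effects$node == "x", ]
  expect_equal(ex$direct, 0)
  expect_equal(ex$indirect, 1, tolerance = 1e-9)
  expect_equal(ex$total, 1, tolerance = 1e-9)
  # saturated recursive model: implied = observed, SRMR = 0
  set.seed(15)
  d3 <- data.frame(a = rnorm(100))
  d3$b <- 0.5 * d3$a + rnorm(100)
  d3$c <- 0.3 * d3$a - 0.4 * d3$b + rnorm(100)
  sat <- path_fit(d3, data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c")), "c")
  expect_lt(sat$srmr, 1e-10)
  expect_equal(sat$effects$total, sat$effects$direct + sat$effects$indirect,
               tolerance = 1e-12)
  # total effect equals the simple standardized slope (path-tracing oracle)
  set.seed(16)
  n <- 10000
  xx <- rnorm(n)
  mm <- 0.6 * xx + rnorm(n, 0, 0.8)
  yy <- 0.5 * mm + 0.3 * xx + rnorm(n)
  big <- path_fit(data.frame(x = xx, m = mm, y = yy),
                  data.frame(from = c("x", "m", "x"), to = c("m", "y", "y")),
                  "y")
  simple <- unname(coef(lm(scale(yy) ~ scale(xx)))[2])
  expect_equal(big$effects$total[big$effects$node == "x"], simple,
               tolerance = 0.02)
  expect_error(path_fit(d3, data.frame(from = c("a", "b"), to = c("b", "a")),
                        "b"), "cycle")
  expect_error(path_fit(d3, data.frame(from = "a", to = "b"), "z"),
               "outcome")
})

test_that("permutation slope test matches exhaustive enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 1.9, 3.4, 2.8, 4.0)
  pl <- permutation_lm(x, y)
  expect_true(pl$exhaustive)
  expect_equal(pl$n_perm, 120)
  # brute-force oracle over all 120 orderings
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  xc <- x - mean(x)
  slopes <- apply(perms, 1, function(r) sum(xc * y[unlist(r)]) / sum(xc^2))
  expect_equal(pl$slope, unname(coef(lm(y ~ x))[2]))
  expect_equal(pl$p, mean(abs(slopes) >= abs(pl$slope)))
  # constant response: slope 0, p 1
  pc <- permutation_lm(x, rep(2, 5))
  expect_equal(pc$slope, 0)
  expect_equal(pc$p, 1)
  expect_error(permutation_lm(rep(1, 5), y), "constant x")
  # strong signal at the add-one resolution floor
  set.seed(17)
  xs <- seq_len(30); ys <- xs + rnorm(30, 0, 0.1)
  ps <- permutation_lm(xs, ys, n_perm = 999, seed = 2)
  expect_equal(ps$p, 1 / 1000)
})
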