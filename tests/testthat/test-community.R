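test_that("rarefaction subsamples without replacement to exact depth", {
  m <- matrix(c(60, 40, 0, 5, 3, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  r <- rarefy_counts(m, depth = 10, seed = 1)
  expect_true(all(rowSums(r) == 10))
  expect_true(all(r <= m))  # without replacement
  # a row already at depth is unchanged
  expect_identical(rarefy_counts(m, depth = 10, seed = 2)["b", ], m["b", ])
  # depth 1 leaves exactly one count of 1
  r1 <- rarefy_counts(m, depth = 1, seed = 3)
  expect_true(all(apply(r1, 1, function(x) sum(x == 1) == 1 && sum(x) == 1)))
  # shallow samples dropped with a warning
  expect_warning(r2 <- rarefy_counts(m, depth = 50, seed = 1), "dropped")
  expect_equal(rownames(r2), "a")
  expect_error(rarefy_counts(m, depth = 0), "positive")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # 100 + 100 counts rarefied to 100: first entry is hypergeometric with
  # mean 50 and variance 100*.5*.5*(100/199)
  m <- matrix(c(100, 100), 1, 2, dimnames = list("s", c("t1", "t2")))
  draws <- vapply(1:2000, function(s)
    rarefy_counts(m, depth = 100, seed = s)[1, 1], numeric(1))
  se <- sqrt(100 * 0.25 * (100 / 199) / 2000)
  expect_lt(abs(mean(draws) - 50), 3 * se)
})

test_that("richness and chao1 follow the classical formulas", {
  row <- c(5, 3, 1, 1, 1, 2)
  expect_identical(richness(row), 6L)
  expect_equal(chao1(row), 10.5)                  # 6 + 9/2
  expect_equal(chao1(c(5, 3, 2, 2)), 4)           # no singletons: S_obs
  expect_equal(chao1(c(1, 1, 0)), 2 + 2 * 1 / 2)  # F2=0 bias-corrected form
  expect_identical(richness(numeric(3)), 0L)
  expect_equal(chao1(numeric(3)), 0)
  expect_error(richness(c(-1, 2)), "negative")
  # chao1 >= richness, equality iff no singletons
  set.seed(42)
  for (i in 1:25) {
    r <- rpois(30, 1.5)
    expect_gte(chao1(r), richness(r))
    if (sum(r == 1) == 0) expect_equal(chao1(r), richness(r))
  }
})

test_that("taxon aggregation conserves totals and splits Proteobacteria", {
  m <- matrix(c(3, 4, 2, 1,
                0, 5, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), c("o1", "o2", "o3", "o4")))
  tax <- data.frame(
    taxon_id = c("o1", "o2", "o3", "o4"),
    phylum = c("Acidobacteria", "Acidobacteria", "Proteobacteria",
               "Cyanobacteria"),
    class = c(NA, NA, "Gammaproteobacteria", NA))
  agg <- aggregate_taxa(m, tax)
  expect_equal(agg[, "Acidobacteria"], c(a = 7, b = 5))
  expect_true("Gammaproteobacteria" %in% colnames(agg))
  expect_false("Proteobacteria" %in% colnames(agg))
  expect_equal(rowSums(agg), rowSums(m))
  # missing taxonomy handling
  tax2 <- tax[1:3, ]
  expect_error(aggregate_taxa(m, tax2), "o4")
  expect_warning(agg2 <- aggregate_taxa(m, tax2, policy = "drop"), "dropped")
  expect_equal(rowSums(agg2), rowSums(m[, 1:3]))
})

test_that("prevalence filter is boundary-inclusive", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("x", "y", "z")))
  m[, "x"] <- 1            # occupancy 1.0
  m[1:8, "y"] <- 1         # occupancy 0.8
  m[1:2, "z"] <- 1         # occupancy 0.2
  expect_identical(colnames(prevalence_filter(m, 0, 0.95)), c("y", "z"))
  expect_true("y" %in% colnames(prevalence_filter(m, 0.8, 1)))  # inclusive
  expect_identical(prevalence_filter(m, 0, 1), m)
  expect_warning(prevalence_filter(m, 0.99, 0.995), "every taxon")
  expect_error(prevalence_filter(m, 0.5, 0.2), "min_frac")
})

test_that("multidiversity averages standardized components", {
  rt <- data.frame(a = c(1, 2, 3, 4), b = c(10, 30, 20, 40))
  md <- multidiversity(rt)
  expect_equal(mean(md$md), 0, tolerance = 1e-12)
  expect_equal(multidiversity(rt[, "a", drop = FALSE])$md,
               (rt$a - mean(rt$a)) / sd(rt$a))
  # components that are exact negatives cancel
  neg <- data.frame(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(unname(multidiversity(neg)$md), c(0, 0, 0))
  expect_warning(md2 <- multidiversity(cbind(rt, k = 5)), "constant")
  expect_identical(md2$components, c("a", "b"))
  expect_error(multidiversity(data.frame(k = c(5, 5, 5))), "constant")
  # max-scaling mode keeps values in (0, 1]
  ms <- multidiversity(rt, mode = "maxscale")
  expect_true(all(ms$md > 0 & ms$md <= 1))
})

test_that("importance values average the three relative attributes", {
  expect_equal(importance_value(3, 0.5, 12), 1)        # single species
  expect_equal(importance_value(c(2, 2), c(0.3, 0.3), c(5, 5)),
               c(0.5, 0.5))                            # symmetry
  # relative density .5, coverage .3, height .1 -> IV 0.3
  iv <- importance_value(c(5, 5), c(3, 7), c(1, 9))
  expect_equal(iv[1], (0.5 + 0.3 + 0.1) / 3)
  expect_equal(sum(iv), 1)
  # zero plot total for one attribute: divisor stays 3
  iv0 <- importance_value(c(1, 1), c(0, 0), c(2, 2))
  expect_equal(iv0, c(1 / 3, 1 / 3))
  set.seed(7)
  for (i in 1:10) {
    iv <- importance_value(runif(5), runif(5), runif(5))
    expect_equal(sum(iv), 1)
  }
})

test_that("allometric biomass equations reproduce the printed forms", {
  expect_equal(plant_biomass("fir", 10, 0.5), 2.79599)
  expect_equal(plant_biomass("hardwood", 10, 0.5),
               0.6573 * 500^1.0502 / 100, tolerance = 1e-12)
  expect_equal(plant_biomass("softwood", 10, 0.5),
               2.1529 * 500^0.6085 / 100, tolerance = 1e-12)
  expect_equal(plant_biomass("shrub", 2, 0.4),
               (0.0398 * 200 - 0.3326) * 0.4 / 25, tolerance = 1e-12)
  # herb equation goes negative for tiny plants and is clipped
  expect_warning(b <- plant_biomass("herb", 0.02, 1), "clipped")
  expect_equal(b, 0)
  expect_error(plant_biomass("cactus", 1, 0.5), "unknown")
  expect_error(plant_biomass("fir", -1, 0.5), "non-negative")
  # monotone nondecreasing in V for the tree equations
  v_grid <- seq(0.5, 30, length.out = 40)
  for (ty in c("fir", "hardwood", "softwood")) {
    b <- plant_biomass(rep(ty, 40), v_grid, 0.5)
    expect_true(all(diff(b) >= 0))
  }
})
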