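# Contemporary vs. geological driver attribution: geochemical indices,
# predictor dereplication, AICc model averaging, geological-increment
# regressions, variation partitioning, composite variables, and recursive
# path analysis with effect decomposition.

#' Geochemical weathering indices
#'
#' Chemical index of alteration CIA = 100 * Al2O3 / (Al2O3 + CaO* + Na2O +
#' K2O) on molar oxide proportions (CaO* is the silicate-fraction CaO,
#' corrected upstream), plus the elemental Ti/Fe, Ti/Al, Mg/Al and Ca/Al
#' ratios. Higher CIA indicates stronger chemical weathering.
#'
#' @param element_table data.frame/matrix with columns `Al2O3`, `CaO_star`
#'   (or `CaO*`), `Na2O`, `K2O` and elemental `Ti`, `Fe`, `Al`, `Mg`, `Ca`.
#' @return data.frame with columns `CIA`, `Ti_Fe`, `Ti_Al`, `Mg_Al`, `Ca_Al`;
#'   zero denominators yield NA with a warning.
#' @export
#' @examples
#' geochem_indices(data.frame(Al2O3 = 50, CaO_star = 20, Na2O = 15, K2O = 15,
#'                            Ti = 1, Fe = 2, Al = 4, Mg = 1, Ca = 2))
geochem_indices <- function(element_table) {
  t_ <- as.data.frame(element_table)
  if ("CaO*" %in% names(t_)) names(t_)[names(t_) == "CaO*"] <- "CaO_star"
  need <- c("Al2O3", "CaO_star", "Na2O", "K2O", "Ti", "Fe", "Al", "Mg", "Ca")
  miss <- setdiff(need, names(t_))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad, na.rm = TRUE)) {
      warning("zero denominator in ", what, ": NA returned")
      den[bad] <- NA
    }
    num / den
  }
  oxsum <- t_$Al2O3 + t_$CaO_star + t_$Na2O + t_$K2O
  data.frame(
    CIA = 100 * safe_div(t_$Al2O3, oxsum, "CIA"),
    Ti_Fe = safe_div(t_$Ti, t_$Fe, "Ti/Fe"),
    Ti_Al = safe_div(t_$Ti, t_$Al, "Ti/Al"),
    Mg_Al = safe_div(t_$Mg, t_$Al, "Mg/Al"),
    Ca_Al = safe_div(t_$Ca, t_$Al, "Ca/Al"))
}

#' Dereplicate collinear predictors
#'
#' Greedy elimination over predictor pairs whose absolute Pearson correlation
#' exceeds `r_threshold` (strictly): from each conflicting pair, the variable
#' with the larger absolute correlation with the response is retained
#' (`keep = "stronger"`, default) or simply the earlier column
#' (`keep = "first"`). Pairs at exactly the threshold are both retained.
#'
#' @param predictor_table samples x predictors numeric table.
#' @param response response vector (required for `keep = "stronger"`).
#' @param r_threshold correlation threshold (default 0.7).
#' @param keep conflict-resolution rule.
#' @return list with `retained` (filtered table), `dropped` (names) and
#'   `log` (data.frame of decisions).
#' @export
dereplicate_predictors <- function(predictor_table, response = NULL,
                                   r_threshold = 0.7,
                                   keep = c("stronger", "first")) {
  keep <- match.arg(keep)
  m <- as.matrix(predictor_table)
  if (ncol(m) < 2) stop("need >= 2 predictors")
  if (keep == "stronger" && is.null(response))
    stop("keep = \"stronger\" needs the response")
  alive <- colnames(m)
  log <- list()
  ry <- if (!is.null(response))
    abs(apply(m, 2, function(v) stats::cor(v, response))) else NULL
  repeat {
    r <- abs(stats::cor(m[, alive, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= r_threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    a <- alive[ij[1]]; b <- alive[ij[2]]
    drop_ <- if (keep == "first") {
      if (match(a, colnames(m)) < match(b, colnames(m))) b else a
    } else {
      if (ry[a] >= ry[b]) b else a
    }
    log[[length(log) + 1L]] <- data.frame(
      var_a = a, var_b = b, r = max(r), dropped = drop_)
    alive <- setdiff(alive, drop_)
    if (length(alive) < 2) break
  }
  list(retained = predictor_table[, alive, drop = FALSE],
       dropped = setdiff(colnames(m), alive),
       log = if (length(log)) do.call(rbind, log)
             else data.frame(var_a = character(), var_b = character(),
                             r = numeric(), dropped = character()))
}

# Gaussian AICc of a least-squares fit.
aicc_ls <- function(rss, n, n_coef) {
  k <- n_coef + 1  # + sigma
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets AICc model averaging with conditional coefficients
#'
#' Z-scores the response and predictors, fits every least-squares subset
#' model (including the intercept-only model), weights models by Akaike
#' weights w_i = exp(-Delta_i / 2) / sum, and reports for each predictor the
#' conditional model-averaged standardized coefficient (weighted over the
#' models containing it) and its relative importance (sum of the weights of
#' those models).
#'
#' @param response numeric response.
#' @param predictors samples x predictors table (dereplicate first).
#' @param max_predictors refuse larger predictor sets (default 15).
#' @return object of class `model_average`: list with `table` (per-predictor
#'   beta and importance), `models` (per-model AICc, delta, weight), and `n`.
#' @export
all_subsets_average <- function(response, predictors, max_predictors = 15) {
  x <- as.matrix(predictors)
  p <- ncol(x)
  if (p > max_predictors)
    stop("more than ", max_predictors,
         " predictors: dereplicate or group them first")
  n <- length(response)
  if (n <= p + 2) stop("need n > #predictors + 2")
  y <- zscore(response)
  xz <- apply(x, 2, zscore)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  nm <- colnames(x)
  fits <- lapply(seq_len(nrow(subsets)), function(i) {
    sel <- unlist(subsets[i, ])
    X <- cbind(`(Intercept)` = 1, xz[, sel, drop = FALSE])
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    list(sel = sel, coef = f$coefficients[-1],
         aicc = aicc_ls(rss, n, ncol(X)))
  })
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  table <- do.call(rbind, lapply(seq_len(p), function(j) {
    has <- vapply(fits, function(f) f$sel[j], logical(1))
    bj <- vapply(fits[has], function(f) unname(f$coef[nm[j]]), numeric(1))
    wj <- w[has]
    data.frame(predictor = nm[j],
               beta = sum(wj * bj) / sum(wj),
               importance = sum(wj))
  }))
  models <- data.frame(
    terms = vapply(fits, function(f)
      paste(nm[f$sel], collapse = "+"), character(1)),
    aicc = aicc, delta = delta, weight = w)
  structure(list(table = table, models = models[order(models$delta), ],
                 coefficients = lapply(fits, `[[`, "coef"), n = n),
            class = "model_average")
}

# Stepwise (forward + backward) AIC selection of lm terms, quietly.
# The fits are created with `data = dat`, and stats::step re-evaluates the
# model call in this function's frame, so the data must be bound here as
# `dat`.
step_quiet <- function(object, scope, dat) {
  stats::step(object, scope = scope, direction = "both", trace = 0)
}

#' Explained-variance gain from geological predictors
#'
#' Selects a contemporary-environment model by stepwise AIC (forward +
#' backward from the intercept-only model), then augments it by stepwise AIC
#' over the geological block with the contemporary terms locked in, and
#' reports the percent increase in R^2. Significance of the geological
#' contribution is assessed by the nested-model F test comparing the selected
#' contemporary model with the same model plus the full geological block
#' (selection-free on the geological side, so the test keeps its nominal
#' level). Additionally, every subset of the contemporary block (including
#' the intercept-only model) is augmented by the full geological block and
#' the fraction of significant F tests at `alpha` is reported.
#'
#' @param response numeric response.
#' @param contemporary,geological disjoint predictor tables.
#' @param alpha significance level for the subset census (default 0.05).
#' @return object of class `geo_increment`: list with `r2_contemporary`,
#'   `r2_full` (stepwise-augmented), `percent_increase`, `anova_f`,
#'   `anova_p`, `fraction_significant`, and the selected term sets.
#' @export
geo_increment <- function(response, contemporary, geological, alpha = 0.05) {
  cdf <- as.data.frame(contemporary)
  gdf <- as.data.frame(geological)
  if (length(intersect(names(cdf), names(gdf))))
    stop("contemporary and geological blocks must be disjoint")
  dat <- data.frame(.y = as.numeric(response), cdf, gdf,
                    check.names = FALSE)
  cvars <- names(cdf); gvars <- names(gdf)
  null_fit <- stats::lm(.y ~ 1, data = dat)
  up_c <- stats::reformulate(cvars, response = ".y")
  sel_c <- step_quiet(null_fit, scope = list(lower = ~1, upper = up_c), dat)
  terms_c <- attr(stats::terms(sel_c), "term.labels")
  r2_c <- summary(sel_c)$r.squared
  low_f <- if (length(terms_c)) stats::reformulate(terms_c, response = ".y")
           else .y ~ 1
  up_cg <- stats::reformulate(c(terms_c, gvars), response = ".y")
  sel_cg <- step_quiet(sel_c, scope = list(lower = low_f, upper = up_cg), dat)
  r2_cg <- summary(sel_cg)$r.squared
  inc <- if (r2_c > 0) 100 * (r2_cg - r2_c) / r2_c else NA_real_
  # selection-free significance: contemporary-selected vs + full geo block
  full_geo <- stats::lm(stats::reformulate(c(terms_c, gvars),
                                           response = ".y"), data = dat)
  an <- stats::anova(sel_c, full_geo)
  f_ <- an$F[2]; p_ <- an$`Pr(>F)`[2]
  # census over all contemporary subsets
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(cvars)))
  sig <- vapply(seq_len(nrow(subsets)), function(i) {
    terms <- cvars[unlist(subsets[i, ])]
    base <- stats::lm(if (length(terms))
      stats::reformulate(terms, response = ".y") else .y ~ 1, data = dat)
    aug <- stats::lm(stats::reformulate(c(terms, gvars), response = ".y"),
                     data = dat)
    a <- stats::anova(base, aug)
    isTRUE(a$`Pr(>F)`[2] < alpha)
  }, logical(1))
  structure(list(r2_contemporary = r2_c, r2_full = r2_cg,
                 absolute_increase = r2_cg - r2_c, percent_increase = inc,
                 anova_f = f_, anova_p = p_,
                 fraction_significant = mean(sig),
                 terms_contemporary = terms_c,
                 terms_full = attr(stats::terms(sel_cg), "term.labels")),
            class = "geo_increment")
}

#' Variation partitioning between two predictor blocks
#'
#' Adjusted-R^2 partition of a response between blocks A and B:
#' a = adjR2(A+B) - adjR2(B) (unique to A), b = adjR2(A+B) - adjR2(A)
#' (unique to B), c = adjR2(A) + adjR2(B) - adjR2(A+B) (shared; may be
#' negative), d = 1 - adjR2(A+B) (residual). a + b + c + d = 1 exactly.
#'
#' @param response numeric response.
#' @param blockA,blockB disjoint non-empty predictor tables.
#' @return list with fractions `a`, `b`, `c`, `d` and the three adjusted R^2.
#' @export
variation_partition <- function(response, blockA, blockB) {
  adf <- as.data.frame(blockA); bdf <- as.data.frame(blockB)
  if (!ncol(adf) || !ncol(bdf)) stop("blocks must be non-empty")
  if (length(intersect(names(adf), names(bdf))))
    stop("blocks must be disjoint")
  adj <- function(df) {
    f <- stats::lm(y ~ ., data = data.frame(y = response, df,
                                            check.names = FALSE))
    s <- summary(f)
    if (any(is.na(stats::coef(f)))) stop("singular fit in variation_partition")
    s$adj.r.squared
  }
  ra <- adj(adf); rb <- adj(bdf); rab <- adj(cbind(adf, bdf))
  list(a = rab - rb, b = rab - ra, c = ra + rb - rab, d = 1 - rab,
       adj_r2_a = ra, adj_r2_b = rb, adj_r2_ab = rab)
}

#' Composite variable from indicator regression weights
#'
#' Builds a block-level composite as the linear combination of z-scored
#' indicators weighted by their multiple-regression coefficients against the
#' z-scored response, then re-standardizes the composite to SD 1.
#'
#' @param indicators samples x indicators table (>= 1 column, dereplicated).
#' @param response numeric response.
#' @return list with `composite` (z-scored scores) and `weights`.
#' @export
composite_score <- function(indicators, response) {
  x <- as.matrix(indicators)
  if (!ncol(x)) stop("need >= 1 indicator")
  xz <- apply(x, 2, zscore)
  if (is.null(colnames(xz))) colnames(xz) <- paste0("i", seq_len(ncol(xz)))
  y <- zscore(response)
  f <- stats::lm.fit(cbind(1, xz), y)
  w <- f$coefficients[-1]
  if (any(is.na(w)))
    stop("collinear indicators; dereplicate before building the composite")
  comp <- drop(xz %*% w)
  list(composite = zscore(comp), weights = w)
}

# Topological order of a DAG given an edge list; errors on cycles.
topo_order <- function(nodes, edges) {
  order_ <- character()
  remaining <- nodes
  while (length(remaining)) {
    active <- edges$from %in% remaining & edges$to %in% remaining
    free <- setdiff(remaining, unique(edges$to[active]))
    if (!length(free))
      stop("cycle detected among: ", paste(remaining, collapse = ", "))
    order_ <- c(order_, free)
    remaining <- setdiff(remaining, free)
  }
  order_
}

#' Recursive path analysis with effect decomposition
#'
#' Fits each endogenous node of an acyclic path diagram by least squares on
#' its parents (all variables z-scored), yielding standardized path
#' coefficients. Effects on the outcome are decomposed by path tracing:
#' the direct effect is the edge coefficient into the outcome, the indirect
#' effect is the sum over all other directed paths of the products of
#' coefficients, and total = direct + indirect. Model fit is summarized by
#' the SRMR between observed and model-implied correlations (residual
#' variances 1 - R^2; exogenous correlations taken from the data) and by the
#' summed per-equation AIC for comparing alternative diagrams.
#'
#' @param data data.frame holding every node's observed values.
#' @param edges data.frame with columns `from`, `to` (a DAG).
#' @param outcome name of the outcome node.
#' @return object of class `path_model`: list with `coefficients` (edge
#'   table with estimate, se, p), `r2` (per endogenous node), `effects`
#'   (direct/indirect/total on the outcome), `srmr`, `aic`, and `order`.
#' @export
path_fit <- function(data, edges, outcome) {
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges needs columns from, to")
  nodes <- unique(c(edges$from, edges$to))
  miss <- setdiff(nodes, names(data))
  if (length(miss)) stop("nodes absent from data: ",
                         paste(miss, collapse = ", "))
  if (!outcome %in% nodes) stop("outcome must appear in the edge list")
  ord <- topo_order(nodes, edges)
  z <- as.data.frame(lapply(data[nodes], zscore))
  n <- nrow(z)
  endo <- unique(edges$to)
  B <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))  # B[to, from]
  r2 <- stats::setNames(numeric(length(endo)), endo)
  coefs <- list()
  aic_total <- 0
  for (v in endo) {
    parents <- edges$from[edges$to == v]
    f <- stats::lm(stats::reformulate(parents, response = v), data = z)
    s <- summary(f)
    B[v, parents] <- stats::coef(f)[parents]
    r2[v] <- s$r.squared
    aic_total <- aic_total + stats::AIC(f)
    cf <- s$coefficients[parents, , drop = FALSE]
    coefs[[v]] <- data.frame(from = parents, to = v,
                             estimate = cf[, 1], se = cf[, 2], p = cf[, 4],
                             row.names = NULL)
  }
  coefs <- do.call(rbind, coefs)
  inv <- solve(diag(length(nodes)) - B)
  total <- inv - diag(length(nodes))
  direct <- B[outcome, ]
  tot_out <- total[outcome, ]
  effects <- data.frame(node = nodes, direct = unname(direct),
                        indirect = unname(tot_out - direct),
                        total = unname(tot_out))
  effects <- effects[effects$node != outcome, ]
  # implied correlations: Sigma = (I - B)^-1 Psi (I - B)^-T
  exo <- setdiff(nodes, endo)
  psi <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (length(exo)) psi[exo, exo] <- stats::cor(z[exo])
  diag(psi)[endo] <- 1 - r2[endo]
  implied <- inv %*% psi %*% t(inv)
  obs <- stats::cor(z[nodes])
  dimnames(implied) <- dimnames(obs)
  dimplied <- sqrt(diag(implied))
  implied_cor <- implied / outer(dimplied, dimplied)
  off <- upper.tri(obs)
  srmr <- sqrt(mean((obs[off] - implied_cor[off])^2))
  structure(list(coefficients = coefs, r2 = r2, effects = effects,
                 srmr = srmr, aic = aic_total, order = ord, b_matrix = B,
                 outcome = outcome, n = n),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Recursive path model, outcome:", x$outcome,
      sprintf("(n = %d, SRMR = %.4f, summed AIC = %.1f)\n", x$n, x$srmr,
              x$aic))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

# All permutations of 1..n (small n only), as a list.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' Permutation test of a simple linear-regression slope
#'
#' OLS slope of y on x with a two-sided permutation p-value obtained by
#' permuting the response: p = (1 + #\{|slope_perm| >= |slope_obs|\}) /
#' (1 + n_perm), or the exact enumeration over all n! response orderings
#' when that is cheaper.
#'
#' @param x predictor (non-constant).
#' @param y response.
#' @param n_perm permutations (default 4999).
#' @param seed RNG seed.
#' @return list with `slope`, `p`, `n_perm`, `exhaustive`.
#' @export
permutation_lm <- function(x, y, n_perm = 4999, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 points")
  if (stats::sd(x) == 0) stop("constant x")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope_of <- function(yy) sum(xc * yy) / sxx
  obs <- slope_of(y)
  exhaustive <- length(x) <= 7 && factorial(length(x)) <= n_perm
  if (exhaustive) {
    perms <- all_perms(length(y))
    sl <- vapply(perms, function(p) slope_of(y[p]), numeric(1))
    p <- mean(abs(sl) >= abs(obs) - 1e-12)
    n_used <- length(perms)
  } else {
    sl <- with_seed(seed,
                    replicate(n_perm, slope_of(sample(y))))
    p <- (1 + sum(abs(sl) >= abs(obs) - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(slope = obs, p = p, n_perm = n_used, exhaustive = exhaustive)
}
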