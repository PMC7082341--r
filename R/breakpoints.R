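# Elevational breakpoint detection: continuous two-segment regression with
# bootstrap CIs and a permutation test of the slope change, compositional
# turnover between adjacent elevations, regression-tree split-density
# profiling, cross-mountain similarity, and consensus summaries.

# Candidate grid inside the band with >= 2 distinct x strictly on each side.
pw_candidates <- function(x, band, step) {
  ux <- sort(unique(x))
  if (length(ux) < 4) stop("need >= 4 distinct x values")
  lo <- max(band[1], ux[2])
  hi <- min(band[2], ux[length(ux) - 1])
  if (lo > hi) stop("band leaves no admissible breakpoint candidates")
  psi <- seq(ceiling(lo / step) * step, hi, by = step)
  keep <- vapply(psi, function(p)
    sum(ux < p) >= 2 && sum(ux > p) >= 2, logical(1))
  psi <- psi[keep]
  if (!length(psi)) stop("no admissible breakpoint candidates in band")
  psi
}

# Vectorized SSE profile of the continuous broken-stick model
# y = b0 + b1 x + b2 (x - psi)_+ over all candidate psi.
# Works on x sorted ascending; elevations are scaled to km for conditioning.
pw_sse_profile <- function(xs, ys, psi) {
  n <- length(xs)
  sx <- sum(xs); sxx <- sum(xs^2)
  sy <- sum(ys); sxy <- sum(xs * ys); syy <- sum(ys^2)
  # suffix sums over points with x > psi
  csx <- rev(cumsum(rev(xs)))
  csxx <- rev(cumsum(rev(xs^2)))
  csy <- rev(cumsum(rev(ys)))
  csxy <- rev(cumsum(rev(xs * ys)))
  k <- findInterval(psi, xs)          # points with x <= psi
  m <- n - k
  sfx <- c(csx, 0)[k + 1]
  sfxx <- c(csxx, 0)[k + 1]
  sfy <- c(csy, 0)[k + 1]
  sfxy <- c(csxy, 0)[k + 1]
  sh <- sfx - psi * m
  shh <- sfxx - 2 * psi * sfx + psi^2 * m
  sxh <- sfxx - psi * sfx
  shy <- sfxy - psi * sfy
  # solve the 3x3 normal equations by cofactor expansion, vectorized over psi
  a11 <- n; a12 <- sx; a13 <- sh
  a22 <- sxx; a23 <- sxh; a33 <- shh
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  i11 <- a22 * a33 - a23^2
  i12 <- a13 * a23 - a12 * a33
  i13 <- a12 * a23 - a13 * a22
  i22 <- a11 * a33 - a13^2
  i23 <- a13 * a12 - a11 * a23
  i33 <- a11 * a22 - a12^2
  b0 <- (i11 * sy + i12 * sxy + i13 * shy) / det
  b1 <- (i12 * sy + i22 * sxy + i23 * shy) / det
  b2 <- (i13 * sy + i23 * sxy + i33 * shy) / det
  sse <- syy - (b0 * sy + b1 * sxy + b2 * shy)
  bad <- !is.finite(sse) | abs(det) < 1e-12
  sse[bad] <- Inf
  list(sse = sse, b0 = b0, b1 = b1, b2 = b2)
}

# Minimal grid search: returns psi-hat and its SSE (fast path used by the
# bootstrap and the permutation null).
pw_min <- function(x_ord_km, y_ord, psi_km) {
  prof <- pw_sse_profile(x_ord_km, y_ord, psi_km)
  i <- which.min(prof$sse)
  c(psi = psi_km[i], sse = prof$sse[i])
}

#' Continuous two-segment (broken-stick) regression with breakpoint search
#'
#' Fits y = b0 + b1 x + b2 (x - psi)_+ by ordinary least squares at every
#' candidate breakpoint psi on a grid inside `band` and keeps the
#' SSE-minimizing psi. The improvement over a single straight line is
#' summarized by an F-type statistic charging two extra parameters (the slope
#' change and the breakpoint); because the breakpoint is estimated, the naive
#' F reference distribution is not exact (the Davies problem), so the
#' reported `p_improvement` comes from a permutation test: residuals of the
#' single-line fit are permuted, added back to its fitted values, and the
#' full grid search is re-run on each permuted response.
#'
#' @param x predictor (elevation, m).
#' @param y response.
#' @param band numeric length-2 search interval for the breakpoint (m).
#' @param grid_step candidate spacing in m (default 1).
#' @param n_null permutations for the improvement test (default 199).
#' @param seed RNG seed for the permutation test.
#' @return object of class `breakpoint_fit`: list with `psi`, `beta0`,
#'   `beta1` (lower-segment slope), `beta2` (slope change above psi), `sse`,
#'   `r2`, `sse_linear`, `f_improvement`, `p_improvement`, `band`,
#'   `grid_step`, `n`, plus `ci_low`/`ci_high` once
#'   [breakpoint_bootstrap()] has been run.
#' @export
piecewise_fit <- function(x, y, band, grid_step = 1, n_null = 199,
                          seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6) stop("need >= 6 points")
  if (length(band) != 2 || band[1] >= band[2]) stop("band must be (lo, hi)")
  if (band[1] > max(x) || band[2] < min(x))
    stop("band lies outside the data range")
  psi <- pw_candidates(x, band, grid_step)
  ord <- order(x)
  xs <- x[ord] / 1000
  ys <- y[ord]
  psik <- psi / 1000
  prof <- pw_sse_profile(xs, ys, psik)
  i <- which.min(prof$sse)
  psi_hat <- psi[i]
  # clean refit at the selected breakpoint
  h <- pmax(x - psi_hat, 0)
  fit <- stats::lm.fit(cbind(1, x, h), y)
  sse <- sum(fit$residuals^2)
  lin <- stats::lm.fit(cbind(1, x), y)
  sse_lin <- sum(lin$residuals^2)
  sst <- sum((y - mean(y))^2)
  f_obs <- ((sse_lin - sse) / 2) / (sse / (n - 4))
  # permutation null: linear-model residuals reshuffled, grid search re-run
  p_imp <- NA_real_
  if (n_null > 0) {
    res <- lin$residuals
    fitted_lin <- lin$fitted.values[ord]
    res_ord <- res[ord]  # permuted anyway; keep aligned with sorted x
    f_null <- with_seed(seed, vapply(seq_len(n_null), function(b) {
      yb <- fitted_lin + sample(res_ord)
      mb <- pw_min(xs, yb, psik)
      lb <- stats::lm.fit(cbind(1, xs), yb)
      sseb_lin <- sum(lb$residuals^2)
      ((sseb_lin - mb["sse"]) / 2) / (mb["sse"] / (n - 4))
    }, numeric(1)))
    p_imp <- (1 + sum(f_null >= f_obs - 1e-12)) / (1 + n_null)
  }
  structure(list(
    psi = psi_hat, beta0 = unname(fit$coefficients[1]),
    beta1 = unname(fit$coefficients[2]), beta2 = unname(fit$coefficients[3]),
    sse = sse, r2 = 1 - sse / sst, sse_linear = sse_lin,
    f_improvement = f_obs, p_improvement = p_imp,
    ci_low = NA_real_, ci_high = NA_real_, ci_edge_limited = NA,
    band = band, grid_step = grid_step, n = n, n_null = n_null, seed = seed),
    class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "Broken-stick fit: psi = %.0f m [band %.0f-%.0f], slopes %.4g / %.4g, R2 = %.3f\n",
    x$psi, x$band[1], x$band[2], x$beta1, x$beta1 + x$beta2, x$r2))
  if (!is.na(x$p_improvement))
    cat(sprintf("  improvement over line: F = %.3g, permutation p = %.4g\n",
                x$f_improvement, x$p_improvement))
  if (!is.na(x$ci_low))
    cat(sprintf("  bootstrap 95%% CI: %.0f-%.0f m%s\n", x$ci_low, x$ci_high,
                if (isTRUE(x$ci_edge_limited)) " (edge-limited)" else ""))
  invisible(x)
}

#' Case-resampling bootstrap CI for the breakpoint
#'
#' Resamples (x, y) pairs with replacement, re-runs the breakpoint grid
#' search, and reports the percentile 95% interval of the breakpoint
#' estimates. If more than 20% of resample fits land on the edge of the
#' search band the interval is flagged edge-limited.
#'
#' @inheritParams piecewise_fit
#' @param n_boot bootstrap replicates (default 999).
#' @param fit optional `breakpoint_fit` to annotate with the interval.
#' @return the `fit` (or a fresh one) with `ci_low`, `ci_high`,
#'   `ci_edge_limited` and `psi_boot` filled in.
#' @export
breakpoint_bootstrap <- function(x, y, band, n_boot = 999, seed = NULL,
                                 grid_step = 1, fit = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(fit))
    fit <- piecewise_fit(x, y, band, grid_step = grid_step, n_null = 0)
  psi <- pw_candidates(x, band, grid_step)
  psik <- psi / 1000
  n <- length(x)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]
      if (sum(unique(xb) < max(psi)) >= 2 && sum(unique(xb) > min(psi)) >= 2)
        break
    }
    ord <- order(xb)
    keep <- psik[vapply(psi, function(p) {
      ux <- unique(xb)
      sum(ux < p) >= 2 && sum(ux > p) >= 2
    }, logical(1))]
    if (!length(keep)) return(NA_real_)
    pw_min(xb[ord] / 1000, y[idx][ord], keep)[["psi"]] * 1000
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  edge <- mean(boots <= min(psi) + grid_step | boots >= max(psi) - grid_step)
  fit$ci_low <- ci[1]
  fit$ci_high <- ci[2]
  fit$ci_edge_limited <- edge > 0.2
  fit$psi_boot <- boots
  fit$n_boot <- n_boot
  fit
}

#' Compositional turnover between adjacent elevations
#'
#' For every pair of elevation-adjacent sites, computes the mean between-site
#' Bray-Curtis dissimilarity and a two-group PERMANOVA pseudo-F, then selects
#' as the compositional breakpoint the pair (with midpoint inside `band`)
#' maximizing the within-band rank sum of pseudo-F and dissimilarity,
#' breaking ties by the higher pseudo-F.
#'
#' @param matrix samples x taxa abundance matrix.
#' @param site_of_sample site id per sample (row).
#' @param site_elevations named vector: elevation (m) per site id.
#' @param band search band (m) for the breakpoint midpoint.
#' @param n_perm PERMANOVA permutations per pair.
#' @param seed RNG seed; per-pair seeds are derived deterministically.
#' @return object of class `turnover_profile`: list with `profile`
#'   (data.frame of pairs), `selected` (row index), `breakpoint` (midpoint
#'   elevation, m) and `band`.
#' @export
adjacent_turnover <- function(matrix, site_of_sample, site_elevations, band,
                              n_perm = 999, seed = NULL) {
  m <- as_count_matrix(matrix)
  site_of_sample <- as.character(site_of_sample)
  if (length(site_of_sample) != nrow(m))
    stop("site_of_sample must have one entry per sample")
  sites <- names(site_elevations)
  if (is.null(sites)) stop("site_elevations must be named by site id")
  if (!all(site_of_sample %in% sites)) stop("samples reference unknown sites")
  if (any(table(site_of_sample) < 2)) stop("every site needs >= 2 samples")
  ord <- order(site_elevations)
  sites <- sites[ord]
  elev <- unname(site_elevations[ord])
  d <- as.matrix(bray_curtis(m))
  np <- length(sites) - 1
  prof <- data.frame(site_lo = sites[-length(sites)], site_hi = sites[-1],
                     elev_lo = elev[-length(elev)], elev_hi = elev[-1],
                     midpoint = (elev[-length(elev)] + elev[-1]) / 2,
                     dissimilarity = NA_real_, pseudo_f = NA_real_,
                     p = NA_real_)
  for (i in seq_len(np)) {
    lo <- site_of_sample == sites[i]
    hi <- site_of_sample == sites[i + 1]
    prof$dissimilarity[i] <- mean(d[lo, hi])
    idx <- lo | hi
    pv <- permanova(d[idx, idx], groups = site_of_sample[idx],
                    n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    prof$pseudo_f[i] <- pv$pseudo_f
    prof$p[i] <- pv$p
  }
  in_band <- prof$midpoint >= band[1] & prof$midpoint <= band[2]
  if (!any(in_band)) stop("no adjacent pair has its midpoint inside the band")
  score <- rank(prof$pseudo_f[in_band]) + rank(prof$dissimilarity[in_band])
  cand <- which(in_band)[score == max(score)]
  sel <- cand[which.max(prof$pseudo_f[cand])]
  structure(list(profile = prof, selected = sel,
                 breakpoint = prof$midpoint[sel], band = band),
            class = "turnover_profile")
}

#' @export
print.turnover_profile <- function(x, ...) {
  s <- x$profile[x$selected, ]
  cat(sprintf(
    "Adjacent-elevation turnover: breakpoint pair %s-%s (midpoint %.0f m), BC = %.3f, pseudo-F = %.3g, p = %.4g\n",
    s$site_lo, s$site_hi, s$midpoint, s$dissimilarity, s$pseudo_f, s$p))
  invisible(x)
}

# Split thresholds and impurity (SS) decreases of a depth-limited regression
# tree of one response on elevation.
tree_splits <- function(y, elevation, max_depth, min_leaf) {
  if (stats::sd(y) == 0) return(NULL)
  ctl <- rpart::rpart.control(maxdepth = max_depth, minbucket = min_leaf,
                              minsplit = 2 * min_leaf, cp = 0, xval = 0,
                              maxcompete = 0, maxsurrogate = 0)
  fit <- rpart::rpart(y ~ elevation, data = data.frame(y = y,
                      elevation = elevation), method = "anova", control = ctl)
  if (is.null(fit$splits) || nrow(fit$frame) < 3) return(NULL)
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  internal <- which(frame$var != "<leaf>")
  dev <- frame$dev
  dec <- vapply(internal, function(i) {
    kid_l <- match(nodes[i] * 2L, nodes)
    kid_r <- match(nodes[i] * 2L + 1L, nodes)
    dev[i] - dev[kid_l] - dev[kid_r]
  }, numeric(1))
  data.frame(threshold = unname(fit$splits[, "index"]),
             decrease = pmax(dec, 0))
}

#' Split-density profile of compositional change along elevation
#'
#' Fits, per taxon, a depth-limited binary regression tree of abundance on
#' elevation (variance-reduction splitting), weights each split threshold by
#' its impurity decrease (normalized within taxon so every informative taxon
#' contributes equally), aggregates thresholds with a weighted Gaussian
#' kernel density, and standardizes by the kernel density of the observed
#' elevations. The standardized profile peaks where many taxa change
#' abruptly relative to sampling effort.
#'
#' @param matrix samples x taxa abundance matrix.
#' @param elevation elevation (m) per sample.
#' @param max_depth tree depth limit (default 3).
#' @param min_leaf minimum samples per leaf (default 5).
#' @param bandwidth kernel bandwidth in m; default Silverman ("nrd0").
#' @param n_grid evaluation grid size (default 512).
#' @return object of class `split_density`: list with `grid`, `raw`
#'   (split-importance density), `data_density`, `standardized`, `peak`
#'   (elevation of the standardized maximum), and `splits` (per-taxon table).
#' @export
split_density <- function(matrix, elevation, max_depth = 3, min_leaf = 5,
                          bandwidth = NULL, n_grid = 512) {
  m <- as_count_matrix(matrix)
  if (length(elevation) != nrow(m))
    stop("elevation must have one entry per sample")
  if (nrow(m) < 2 * min_leaf) stop("too few samples for the leaf size")
  splits <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- tree_splits(m[, j], elevation, max_depth, min_leaf)
    if (!is.null(s) && nrow(s) && sum(s$decrease) > 0) {
      s$weight <- s$decrease / sum(s$decrease)
      s$taxon <- colnames(m)[j]
      splits[[j]] <- s
    }
  }
  splits <- do.call(rbind, splits)
  rng <- range(elevation)
  bw_data <- bandwidth %||% stats::bw.nrd0(elevation)
  dd <- stats::density(elevation, bw = bw_data,
                       from = rng[1], to = rng[2], n = n_grid)
  grid <- dd$x
  if (is.null(splits) || !nrow(splits)) {
    message("no informative splits: flat (zero) split density")
    raw <- rep(0, n_grid)
  } else {
    w <- splits$weight / sum(splits$weight)
    bw_spl <- bandwidth %||%
      (if (length(unique(splits$threshold)) > 1)
         stats::bw.nrd0(splits$threshold) else bw_data)
    if (!is.finite(bw_spl) || bw_spl <= 0) bw_spl <- bw_data
    sd_ <- stats::density(splits$threshold, weights = w, bw = bw_spl,
                          from = rng[1], to = rng[2], n = n_grid)
    raw <- sd_$y
  }
  standardized <- ifelse(dd$y > 1e-12, raw / dd$y, 0)
  peak <- if (all(raw == 0)) NA_real_ else grid[which.max(standardized)]
  structure(list(grid = grid, raw = raw, data_density = dd$y,
                 standardized = standardized, peak = peak,
                 splits = splits %||%
                   data.frame(threshold = numeric(), decrease = numeric(),
                              weight = numeric(), taxon = character())),
            class = "split_density")
}

#' Cross-mountain community similarity
#'
#' Compares two mountains' communities after harmonizing taxa (outer join
#' with zero fill): (i) matches sites of mountain B to the nearest-elevation
#' site of mountain A within `pairing_tol` and profiles the matched-pair
#' Bray-Curtis similarity (1 - dissimilarity of mean site profiles), whose
#' minimum marks the shared transition; (ii) for each site of mountain B,
#' regresses its similarities to all mountain-A sites on the A-side of
#' `breakpoint` (below or above) on elevation, with a permutation test of
#' the slope.
#'
#' @param matrixA,matrixB samples x taxa matrices for the two mountains.
#' @param elevA,elevB elevation (m) per sample.
#' @param pairing_tol maximum elevation difference (m) for a matched pair.
#' @param breakpoint elevation (m) splitting mountain-A sites into the
#'   below/above set used for the slope regressions.
#' @param direction "below" (default) or "above": which A-side to regress.
#' @param n_perm permutations for the slope tests.
#' @param seed RNG seed.
#' @return object of class `cross_mountain`: list with `pairs` (matched
#'   profile, similarity in `[0,1]`), `min_elevation` (B elevation of minimum
#'   similarity; NA with `flat = TRUE` when the profile is constant), and
#'   `slopes` (per-focal-B-site slope, p).
#' @export
cross_mountain <- function(matrixA, matrixB, elevA, elevB, pairing_tol = 100,
                           breakpoint = NULL, direction = c("below", "above"),
                           n_perm = 999, seed = NULL) {
  direction <- match.arg(direction)
  ma <- as_count_matrix(matrixA, "matrixA")
  mb <- as_count_matrix(matrixB, "matrixB")
  taxa <- union(colnames(ma), colnames(mb))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(taxa),
                  dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  ma <- pad(ma); mb <- pad(mb)
  site_profile <- function(m, elev) {
    u <- sort(unique(elev))
    prof <- t(vapply(u, function(e)
      colMeans(m[elev == e, , drop = FALSE]), numeric(ncol(m))))
    rownames(prof) <- as.character(u)
    list(elev = u, profile = prof)
  }
  a <- site_profile(ma, elevA)
  b <- site_profile(mb, elevB)
  # greedy nearest-elevation matching, each A site used once
  cand <- expand.grid(i = seq_along(b$elev), j = seq_along(a$elev))
  cand$gap <- abs(b$elev[cand$i] - a$elev[cand$j])
  cand <- cand[cand$gap <= pairing_tol, ]
  cand <- cand[order(cand$gap), ]
  used_a <- used_b <- integer()
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    if (cand$i[r] %in% used_b || cand$j[r] %in% used_a) next
    used_b <- c(used_b, cand$i[r]); used_a <- c(used_a, cand$j[r])
    pairs[[length(pairs) + 1L]] <- cand[r, ]
  }
  if (!length(pairs)) stop("no matched elevation pairs within tolerance")
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(b$elev[pairs$i]), ]
  sim <- vapply(seq_len(nrow(pairs)), function(r) {
    1 - as.numeric(bray_curtis(rbind(a$profile[pairs$j[r], ],
                                     b$profile[pairs$i[r], ])))
  }, numeric(1))
  prof <- data.frame(elev_b = b$elev[pairs$i], elev_a = a$elev[pairs$j],
                     similarity = sim)
  flat <- diff(range(sim)) < 1e-12
  min_elev <- if (flat) NA_real_ else prof$elev_b[which.min(prof$similarity)]
  slopes <- NULL
  if (!is.null(breakpoint)) {
    side <- if (direction == "below") a$elev < breakpoint
            else a$elev > breakpoint
    if (sum(side) >= 3) {
      slopes <- do.call(rbind, lapply(seq_along(b$elev), function(i) {
        s <- vapply(which(side), function(j)
          1 - as.numeric(bray_curtis(rbind(a$profile[j, ], b$profile[i, ]))),
          numeric(1))
        pl <- permutation_lm(a$elev[side], s, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, i))
        data.frame(elev_b = b$elev[i], slope = pl$slope, p = pl$p)
      }))
    }
  }
  structure(list(pairs = prof, min_elevation = min_elev, flat = flat,
                 slopes = slopes, pairing_tol = pairing_tol,
                 breakpoint = breakpoint, direction = direction),
            class = "cross_mountain")
}

#' Summarize breakpoint fits by facet
#'
#' @param fits list of `breakpoint_fit` objects.
#' @param facets character tag per fit (e.g. "plants", "bacteria",
#'   "functions").
#' @param alpha significance level for the improvement test count.
#' @return data.frame with one row per facet: n, mean, median, q1, q3 of the
#'   breakpoint elevations and the number significant at `alpha`.
#' @export
consensus_breakpoints <- function(fits, facets, alpha = 0.05) {
  if (length(fits) != length(facets)) stop("one facet tag per fit")
  psi <- vapply(fits, function(f) f$psi, numeric(1))
  p <- vapply(fits, function(f) f$p_improvement %||% NA_real_, numeric(1))
  out <- do.call(rbind, lapply(split(seq_along(psi), facets), function(idx) {
    q <- stats::quantile(psi[idx], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(facet = facets[idx[1]], n = length(idx), mean = mean(psi[idx]),
               q1 = q[1], median = q[2], q3 = q[3],
               n_significant = sum(p[idx] < alpha, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
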