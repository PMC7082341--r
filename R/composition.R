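# Distances, ordinations, and permutation tests on multivariate
# community / function tables.

#' Bray-Curtis dissimilarity matrix
#'
#' d_ij = sum|x_i - x_j| / sum(x_i + x_j) between non-negative abundance rows;
#' bounded in `[0, 1]`, zero on the diagonal. Computed with
#' \code{vegan::vegdist}. Zero-sum rows are rejected by name because their
#' dissimilarity is undefined.
#'
#' @param matrix samples x taxa non-negative matrix.
#' @return object of class `dist` with sample labels.
#' @export
#' @examples
#' bray_curtis(rbind(a = c(1, 2, 3), b = c(3, 2, 1)))  # 4/12 = 1/3
bray_curtis <- function(matrix) {
  m <- as_count_matrix(matrix)
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("zero-sum sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Principal component analysis of an environmental or geological table
#'
#' Centered (and optionally unit-variance scaled) eigendecomposition via
#' \code{stats::prcomp}. Constant columns are dropped with a warning. Axis
#' signs follow the convention that the largest-magnitude loading on each
#' axis is positive, so results are reproducible across platforms.
#'
#' @param table samples x variables numeric table.
#' @param scale logical; use the correlation matrix (default TRUE, suitable
#'   when variables have different units).
#' @return list with `scores`, `loadings`, `eigenvalues`,
#'   `percent` (variance explained per axis) and `method = "PCA"`.
#' @export
ordinate_pca <- function(table, scale = TRUE) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("table must be numeric")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 samples and >= 2 variables")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 non-constant columns")
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation, eigenvalues = ev,
       percent = 100 * ev / sum(ev), method = "PCA")
}

# Correspondence analysis via SVD of the standardized residual matrix.
ca_core <- function(m) {
  p <- m / sum(m)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  dec <- svd(s)
  keep <- dec$d > 1e-10
  keep[1] <- TRUE
  d <- dec$d[keep]
  # principal row coordinates
  scores <- sweep(dec$u[, keep, drop = FALSE], 1, sqrt(r), "/")
  scores <- sweep(scores, 2, d, "*")
  rownames(scores) <- rownames(m)
  list(scores = scores, eigenvalues = d^2)
}

#' Detrended correspondence analysis (detrending by segments)
#'
#' Correspondence analysis (reciprocal averaging, computed by SVD) with the
#' second axis detrended against the first: the axis-1 range is divided into
#' `n_segments` equal segments and axis-2 sample scores are centered within
#' each segment, suppressing the arch artifact. Axis 1 is identical to the CA
#' solution. Hill's nonlinear rescaling is not applied, so axis lengths are
#' in raw score units rather than SD units.
#'
#' @param matrix samples x taxa non-negative matrix; zero-sum rows/columns
#'   are dropped with a warning.
#' @param n_segments number of detrending segments (default 26).
#' @return list with `scores` (axes 1-2), `eigenvalues` (CA eigenvalues),
#'   `percent`, `method = "DCA"` and `n_segments`.
#' @export
ordinate_dca <- function(matrix, n_segments = 26) {
  if (!is.numeric(n_segments) || n_segments < 2)
    stop("n_segments must be >= 2")
  m <- as_count_matrix(matrix)
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr)) {
    warning("dropping zero-sum sample(s): ",
            paste(rownames(m)[zr], collapse = ", "))
    m <- m[!zr, , drop = FALSE]
  }
  if (any(zc)) {
    warning("dropping empty taxa: ", sum(zc))
    m <- m[, !zc, drop = FALSE]
  }
  if (nrow(m) < 3) stop("need >= 3 non-empty samples")
  ca <- ca_core(m)
  ax1 <- ca$scores[, 1]
  ax2 <- if (ncol(ca$scores) >= 2) ca$scores[, 2] else rep(0, nrow(m))
  # deterministic orientation
  if (ax1[which.max(abs(ax1))] < 0) ax1 <- -ax1
  rng <- range(ax1)
  if (diff(rng) > 0) {
    seg <- cut(ax1, breaks = seq(rng[1], rng[2], length.out = n_segments + 1),
               include.lowest = TRUE)
    ax2 <- ax2 - stats::ave(ax2, seg, FUN = mean)
  }
  scores <- cbind(DCA1 = ax1, DCA2 = ax2)
  rownames(scores) <- rownames(m)
  ev <- ca$eigenvalues
  list(scores = scores, eigenvalues = ev, percent = 100 * ev / sum(ev),
       method = "DCA", n_segments = n_segments)
}

# Within-group sum of squared distances from a squared-distance matrix.
ss_within_groups <- function(d2, idx_by_group) {
  tot <- 0
  for (idx in idx_by_group) {
    sub <- d2[idx, idx]
    tot <- tot + sum(sub[upper.tri(sub)]) / length(idx)
  }
  tot
}

#' One-way PERMANOVA with pseudo-F statistic
#'
#' Partitions the total sum of squared inter-sample distances into between-
#' and within-group components and tests group separation by permuting group
#' labels. SS_total = (1/n) sum_{i<j} d_ij^2; pseudo-F =
#' (SS_between/(g-1)) / (SS_within/(n-g)). The p-value uses the add-one rule
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm) with a `>=` tie comparison;
#' when the number of distinct label assignments for a two-group design is
#' small enough, all assignments are enumerated and the p-value is exact.
#'
#' @param dist `dist` object or square symmetric distance matrix.
#' @param groups group labels, one per sample; every group needs >= 2 members.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return object of class `permanova`: list with `pseudo_f`, `p`, `ss_total`,
#'   `ss_within`, `ss_between`, `df`, `n_perm`, `exhaustive`, `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (n_perm < 99) stop("n_perm must be >= 99")
  g <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  split_idx <- split(seq_len(n), groups)
  ss_w <- ss_within_groups(d2, split_idx)
  ss_b <- ss_total - ss_w
  f_obs <- (ss_b / (g - 1)) / (ss_w / (n - g))
  f_stat <- function(lab) {
    sw <- ss_within_groups(d2, split(seq_len(n), lab))
    ((ss_total - sw) / (g - 1)) / (sw / (n - g))
  }
  exhaustive <- g == 2 && choose(n, sizes[1]) <= n_perm + 1
  if (exhaustive) {
    combos <- utils::combn(n, sizes[1])
    fs <- apply(combos, 2, function(i) {
      lab <- rep(levels(groups)[2], n)
      lab[i] <- levels(groups)[1]
      f_stat(factor(lab))
    })
    p <- sum(fs >= f_obs - 1e-12) / length(fs)
    n_used <- ncol(combos)
  } else {
    fs <- with_seed(seed, replicate(n_perm, f_stat(sample(groups))))
    p <- (1 + sum(fs >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_f = unname(f_obs), p = unname(p),
                 ss_total = ss_total, ss_within = ss_w, ss_between = ss_b,
                 df = c(between = g - 1, within = n - g),
                 n_perm = n_used, exhaustive = exhaustive, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (one-way): pseudo-F =", format(x$pseudo_f, digits = 4),
      "df =", x$df[1], "/", x$df[2],
      if (x$exhaustive) "(exhaustive)" else sprintf("(%d perms)", x$n_perm),
      "p =", format(x$p, digits = 4), "\n")
  invisible(x)
}
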