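# Averaging-based ecosystem multifunctionality: z-score standardization,
# overall and per-group EMF, and subset-permutation robustness curves.

#' Column-wise z-scores of an ecosystem-function table
#'
#' Standardizes each function to mean 0, SD 1 across samples using the sample
#' SD (n - 1 denominator). Constant columns cannot be standardized and are
#' reported by name.
#'
#' @param function_table samples x functions numeric table (NAs allowed).
#' @return z-score matrix with the input dimnames.
#' @export
zscore_table <- function(function_table) {
  m <- as.matrix(function_table)
  if (!is.numeric(m)) stop("function table must be numeric")
  if (nrow(m) < 2) stop("need >= 2 samples")
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    stop("constant column(s): ", paste(colnames(m)[bad], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  sweep(sweep(m, 2, mu), 2, sds, "/")
}

#' Ecosystem multifunctionality (EMF) of a z-score matrix
#'
#' Row mean of the z-scores over a function subset. Missing entries are
#' excluded pairwise; a sample whose subset coverage falls below
#' `min_coverage` gets a missing EMF.
#'
#' @param z z-score matrix from [zscore_table()].
#' @param subset function names or column indices (default: all).
#' @param min_coverage minimum fraction of non-missing subset functions per
#'   sample (default 0.5).
#' @return numeric per-sample EMF.
#' @export
emf <- function(z, subset = NULL, min_coverage = 0.5) {
  z <- as.matrix(z)
  if (is.null(subset)) subset <- colnames(z) %||% seq_len(ncol(z))
  if (!length(subset)) stop("empty function subset")
  if (is.character(subset) && !all(subset %in% colnames(z)))
    stop("subset names absent from z: ",
         paste(setdiff(subset, colnames(z)), collapse = ", "))
  zz <- z[, subset, drop = FALSE]
  used <- rowSums(!is.na(zz))
  out <- rowMeans(zz, na.rm = TRUE)
  out[used < min_coverage * ncol(zz)] <- NA_real_
  out[used == 0] <- NA_real_
  out
}

#' Overall and per-group multifunctionality table
#'
#' @param function_table samples x functions table.
#' @param groups named character vector or data.frame (`fn`, `group`) mapping
#'   each function to its functional group (e.g. plant biomass, microbial
#'   biomass, enzyme activity, photosynthetic bacteria, soil nutrients).
#' @return list with `z` (z-score matrix), `emf` (overall per-sample EMF),
#'   `group_emf` (samples x groups), and `groups` (the map used).
#' @export
multifunctionality <- function(function_table, groups = NULL) {
  z <- zscore_table(function_table)
  overall <- emf(z)
  group_emf <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups))
      groups <- stats::setNames(as.character(groups$group),
                                as.character(groups$fn))
    miss <- setdiff(colnames(z), names(groups))
    if (length(miss))
      stop("functions without a group: ", paste(miss, collapse = ", "))
    gl <- split(colnames(z), groups[colnames(z)])
    group_emf <- vapply(gl, function(fns) emf(z, fns),
                        numeric(nrow(z)))
  }
  list(z = z, emf = overall, group_emf = group_emf, groups = groups)
}

# All k-subsets of cols if cheap, else n random distinct-column subsets.
draw_subsets <- function(cols, k, n_perm) {
  total <- choose(length(cols), k)
  if (total <= n_perm) {
    asplit(utils::combn(cols, k), 2)
  } else {
    lapply(seq_len(n_perm), function(i) sample(cols, k))
  }
}

#' Robustness of EMF to the number of functions considered
#'
#' For each subset size k from `k_min` to `k_max`, draws `n_perm` random
#' k-subsets of functions (all subsets exhaustively when there are fewer than
#' `n_perm`), computes the subset EMF per sample, and records its Pearson
#' correlation with the full-set EMF. Because EMF is a mean, the expectation
#' of the subset EMF over uniformly drawn subsets equals the full EMF; the
#' curve quantifies how quickly individual subsets concentrate around it.
#'
#' @param z z-score matrix.
#' @param k_min,k_max subset size range (defaults 10 and `ncol(z)`).
#' @param n_perm subsets per k (default 1000).
#' @param seed RNG seed.
#' @return object of class `subset_curve`: data.frame `curve` with per-k mean
#'   and SD of subset EMF correlations with the full EMF, the mean subset EMF
#'   per k, and `exhaustive` flags; plus `full_emf` and `seed`.
#' @export
emf_subset_curve <- function(z, k_min = 10, k_max = NULL, n_perm = 1000,
                             seed = NULL) {
  z <- as.matrix(z)
  k_max <- k_max %||% ncol(z)
  if (k_min < 1) stop("k_min must be >= 1")
  if (k_max > ncol(z)) stop("k_max exceeds the number of functions")
  full <- emf(z)
  cols <- colnames(z) %||% seq_len(ncol(z))
  rows <- with_seed(seed, lapply(seq(k_min, k_max), function(k) {
    subs <- draw_subsets(cols, k, n_perm)
    emfs <- vapply(subs, function(s) emf(z, s), numeric(nrow(z)))
    cors <- apply(emfs, 2, function(e)
      if (stats::sd(e) == 0) NA_real_ else stats::cor(e, full))
    data.frame(k = k, n_subsets = length(subs),
               exhaustive = choose(length(cols), k) <= n_perm,
               mean_cor = mean(cors, na.rm = TRUE),
               sd_cor = stats::sd(cors),
               mean_emf_sd = mean(apply(emfs, 1, stats::sd)))
  }))
  structure(list(curve = do.call(rbind, rows), full_emf = full,
                 n_perm = n_perm, seed = seed),
            class = "subset_curve")
}
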