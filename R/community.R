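# Per-sample diversity, taxonomic aggregation, multidiversity, and
# vegetation-survey derived quantities (importance values, allometric biomass).

#' Rarefy a count matrix to even sequencing depth
#'
#' Subsamples each sample (row) without replacement to exactly `depth` reads.
#' Samples whose total count is below `depth` are dropped with a warning;
#' totals are never scaled up. Rarefaction keeps richness comparisons
#' unbiased by uneven sampling effort.
#'
#' @param matrix samples x taxa count matrix (rows are samples).
#' @param depth target depth (reads per sample), a positive integer.
#' @param seed integer seed for the subsampling.
#' @return a count matrix whose rows all sum to exactly `depth`.
#' @export
#' @examples
#' m <- matrix(c(60, 40, 3, 2), 2, 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("t1", "t2")))
#' rarefy_counts(m, depth = 5, seed = 1)
rarefy_counts <- function(matrix, depth, seed = NULL) {
  m <- as_count_matrix(matrix)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  if (any(m != round(m))) stop("rarefaction requires integer counts")
  tot <- rowSums(m)
  low <- tot < depth
  if (any(low)) {
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[low], collapse = ", "))
    m <- m[!low, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no samples at or above the rarefaction depth")
  with_seed(seed, {
    out <- m
    for (i in seq_len(nrow(m))) {
      if (sum(m[i, ]) == depth) next  # already at depth: unchanged
      pool <- rep.int(seq_len(ncol(m)), m[i, ])
      take <- sample(pool, depth, replace = FALSE)
      out[i, ] <- tabulate(take, nbins = ncol(m))
    }
    out
  })
}

#' Observed richness of a count row
#'
#' @param row non-negative abundance vector.
#' @return integer number of taxa with positive abundance.
#' @export
richness <- function(row) {
  if (any(row < 0)) stop("negative abundances")
  sum(row > 0)
}

#' Chao1 richness estimator
#'
#' Classical form S_obs + F1^2 / (2 F2) where F1 and F2 are the numbers of
#' singletons and doubletons; when F2 = 0 the bias-corrected form
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) is used. An all-zero row returns 0.
#'
#' @param row non-negative integer count vector.
#' @return Chao1 estimate (>= observed richness).
#' @export
#' @examples
#' chao1(c(5, 3, 1, 1, 1, 2))  # 6 + 9/2 = 10.5
chao1 <- function(row) {
  if (any(row < 0)) stop("negative abundances")
  s <- sum(row > 0)
  if (s == 0L) return(0)
  f1 <- sum(row == 1)
  f2 <- sum(row == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Aggregate a community matrix to a higher taxonomic level
#'
#' Sums taxon columns within taxonomy groups. At `level = "phylum"`,
#' Proteobacteria are reported at class rank (classes treated as phyla
#' thereafter), reflecting the high abundance and ecological heterogeneity
#' of proteobacterial classes.
#'
#' @param matrix samples x taxa matrix.
#' @param taxonomy data.frame with columns `taxon_id`, `phylum` and, for
#'   Proteobacteria, `class`.
#' @param level aggregation level; only "phylum" is meaningful here.
#' @param policy what to do with taxa missing from the taxonomy:
#'   "error" (default) or "drop".
#' @return aggregated samples x groups matrix; per-sample totals conserved
#'   (exactly, unless taxa are dropped).
#' @export
aggregate_taxa <- function(matrix, taxonomy, level = "phylum",
                           policy = c("error", "drop")) {
  policy <- match.arg(policy)
  m <- as_count_matrix(matrix)
  if (!all(c("taxon_id", "phylum") %in% names(taxonomy)))
    stop("taxonomy needs columns taxon_id and phylum")
  if (level != "phylum") stop("unsupported aggregation level: ", level)
  idx <- match(colnames(m), taxonomy$taxon_id)
  missing <- colnames(m)[is.na(idx)]
  if (length(missing)) {
    if (policy == "error")
      fail_all(missing, "taxa without taxonomy entries")
    warning(length(missing), " taxa without taxonomy dropped")
    m <- m[, !is.na(idx), drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  grp <- taxonomy$phylum[idx]
  if ("class" %in% names(taxonomy)) {
    pro <- grp == "Proteobacteria" & !is.na(taxonomy$class[idx]) &
      nzchar(taxonomy$class[idx])
    grp[pro] <- taxonomy$class[idx][pro]
  }
  t(rowsum(t(m), group = grp))
}

#' Filter taxa by occupancy (prevalence)
#'
#' Keeps taxa whose fraction of occupied samples lies in
#' `[min_frac, max_frac]`, boundaries inclusive.
#'
#' @param matrix samples x taxa matrix.
#' @param min_frac,max_frac occupancy bounds in `[0, 1]`.
#' @return the filtered matrix (possibly with zero columns, with a warning).
#' @export
prevalence_filter <- function(matrix, min_frac = 0, max_frac = 1) {
  m <- as_count_matrix(matrix)
  if (min_frac < 0 || max_frac > 1 || min_frac > max_frac)
    stop("require 0 <= min_frac <= max_frac <= 1")
  occ <- colMeans(m > 0)
  keep <- occ >= min_frac & occ <= max_frac
  if (!any(keep)) warning("prevalence filter removed every taxon")
  m[, keep, drop = FALSE]
}

#' Multidiversity: mean of standardized richness components
#'
#' Collapses several richness components (e.g. plant richness, whole-community
#' bacterial richness, per-phylum richness) into a single per-sample index by
#' averaging standardized values. Under z-score standardization the index has
#' dataset mean zero by construction.
#'
#' @param richness_table samples x components numeric table.
#' @param mode "zscore" (default, sample SD) or "maxscale" (divide by column
#'   maximum).
#' @return list with `md` (per-sample index), `components` (names used),
#'   `dropped` (zero-variance components removed), and `mode`.
#' @export
multidiversity <- function(richness_table, mode = c("zscore", "maxscale")) {
  mode <- match.arg(mode)
  m <- as.matrix(richness_table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  keep <- apply(m, 2, function(x) stats::sd(x) > 0 && max(abs(x)) > 0)
  if (!any(keep)) stop("all multidiversity components are constant")
  if (any(!keep))
    warning("dropping constant components: ",
            paste(colnames(m)[!keep], collapse = ", "))
  m <- m[, keep, drop = FALSE]
  std <- if (mode == "zscore") apply(m, 2, zscore)
         else sweep(m, 2, apply(m, 2, max), "/")
  list(md = rowMeans(std), components = colnames(m),
       dropped = colnames(richness_table)[!keep] %||% character(), mode = mode)
}

#' Plant importance values within a plot
#'
#' IV of a species is the mean of its relative density, relative coverage and
#' relative height within the plot, so importance values sum to one per plot.
#' If a plot total for one attribute is zero, that attribute contributes zero
#' for every species and the averaging divisor stays three.
#'
#' @param density,coverage,height per-species attribute vectors for one plot.
#' @return numeric vector of importance values.
#' @export
importance_value <- function(density, coverage, height) {
  n <- length(density)
  if (length(coverage) != n || length(height) != n)
    stop("attribute vectors must have equal length")
  if (any(c(density, coverage, height) < 0)) stop("negative attributes")
  rel <- function(x) {
    tot <- sum(x)
    if (tot > 0) x / tot else rep(0, length(x))
  }
  (rel(density) + rel(coverage) + rel(height)) / 3
}

#' Allometric plant biomass from height and coverage
#'
#' Applies the per-type allometric equations used in Tibetan elevational
#' surveys, with stand volume V = 100 * height * coverage:
#' fir (0.4642 V + 47.4990)/100; hardwood 0.6573 V^1.0502 / 100;
#' softwood 2.1529 V^0.6085 / 100; shrub (0.0398 * height * 100 - 0.3326) *
#' coverage / 25; herb (0.0175 * height * 100 - 0.2888) * coverage.
#' The shrub and herb equations can go negative for very small plants;
#' negative outputs are clipped to zero with a warning.
#'
#' @param type one of "fir", "hardwood", "softwood", "shrub", "herb"
#'   (vectorized, recycled against height/coverage).
#' @param height plant height in metres (>= 0).
#' @param coverage cover fraction in `[0, 1]` (>= 0 enforced).
#' @return biomass estimate(s), non-negative.
#' @export
#' @examples
#' plant_biomass("fir", height = 10, coverage = 0.5)  # V = 500 -> 2.79599
plant_biomass <- function(type, height, coverage) {
  n <- max(length(type), length(height), length(coverage))
  type <- rep_len(as.character(type), n)
  height <- rep_len(height, n)
  coverage <- rep_len(coverage, n)
  if (any(height < 0) || any(coverage < 0))
    stop("height and coverage must be non-negative")
  known <- c("fir", "hardwood", "softwood", "shrub", "herb")
  if (!all(type %in% known))
    stop("unknown plant type(s): ",
         paste(unique(setdiff(type, known)), collapse = ", "))
  v <- 100 * height * coverage
  b <- numeric(n)
  b[type == "fir"] <- (0.4642 * v[type == "fir"] + 47.4990) / 100
  b[type == "hardwood"] <- 0.6573 * v[type == "hardwood"]^1.0502 / 100
  b[type == "softwood"] <- 2.1529 * v[type == "softwood"]^0.6085 / 100
  b[type == "shrub"] <-
    (0.0398 * height[type == "shrub"] * 100 - 0.3326) *
    coverage[type == "shrub"] / 25
  b[type == "herb"] <-
    (0.0175 * height[type == "herb"] * 100 - 0.2888) * coverage[type == "herb"]
  if (any(b < 0)) {
    warning(sum(b < 0), " negative biomass value(s) clipped to 0")
    b[b < 0] <- 0
  }
  b
}
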