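# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`
#' so that package functions never disturb the global RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one user-facing seed per bundle or run,
# sub-streams per table/stage. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 48271 + 11 * as.numeric(offset) + 7) %%
               2147483629)
}

# Column-wise z-score with sample SD (n - 1 denominator).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# Stop with a single message listing all accumulated problems.
fail_all <- function(problems, context) {
  if (length(problems))
    stop(context, ":\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric matrix coercion preserving dimnames, with validation.
as_count_matrix <- function(x, what = "community matrix") {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop(what, " must be numeric")
  if (any(m < 0)) stop(what, " contains negative entries")
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}
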