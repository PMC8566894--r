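# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed if one is given, restoring the caller's RNG state afterwards,
#' so that stochastic operations are bit-reproducible without disturbing the
#' surrounding stream. A `NULL` seed means "use the current stream".
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  code
}

#' Derive a per-stage seed from a global seed
#'
#' Fans a single pipeline seed out into independent, reproducible sub-seeds so
#' stages can be re-run in isolation. Kept below 2^31 - 1 (R integers).
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 2147483647
  as.integer((abs(seed) %% 65536 * 48271 + h * 7919 + 1) %% 2147483647)
}

# Validate a samples x taxa count matrix; returns it invisibly.
check_community <- function(m, integer_counts = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("community matrix must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix must have sample and taxon names")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate taxon ids")
  if (anyNA(m)) stop("community matrix contains missing values")
  if (any(m < 0)) stop("community matrix contains negative counts")
  if (integer_counts && any(abs(m - round(m)) > 1e-8))
    stop("community matrix contains non-integer counts")
  invisible(m)
}

# Long-format (i, j) indices of the lower triangle of an n x n matrix,
# matching the ordering of stats::dist.
pair_index <- function(labels) {
  n <- length(labels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(sample_i = labels[idx[, 2]], sample_j = labels[idx[, 1]],
             stringsAsFactors = FALSE)
}

# Build a stats::dist object from a vector of lower-triangle values.
as_dist_obj <- function(values, labels, method = "user") {
  attr(values, "Size") <- length(labels)
  attr(values, "Labels") <- labels
  attr(values, "Diag") <- FALSE
  attr(values, "Upper") <- FALSE
  attr(values, "method") <- method
  class(values) <- "dist"
  values
}
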