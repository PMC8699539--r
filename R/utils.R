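#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so that simulation functions are reproducible without
#' clobbering global randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# single positive whole number
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %s is outside its allowed range", name, format(x)),
         call. = FALSE)
  }
  x
}

#' Validate a count matrix
#'
#' Checks the invariants of the gene-by-sample count container used across the
#' package: unique gene and sample identifiers, non-negative integer counts,
#' and at least two samples.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   both dimnames set.
#' @return `counts`, invisibly, with gene symbols uppercased.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  }
  rownames(counts) <- toupper(rownames(counts))
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g)) {
    stop("duplicated gene identifiers: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}

# align a design table with a count matrix; errors on mismatch
check_design <- function(design, counts) {
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(design$sample_id, colnames(counts)) ||
      anyDuplicated(design$sample_id)) {
    stop("design sample_id must match the matrix samples exactly once each",
         call. = FALSE)
  }
  design[match(colnames(counts), design$sample_id), , drop = FALSE]
}
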