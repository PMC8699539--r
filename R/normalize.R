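#' Analysis thresholds and options
#'
#' Central container for the tunable parameters of the pipeline: the
#' fold-change and significance thresholds used for differential-expression
#' filtering and signature derivation, the pseudo-count for log-CPM, the
#' number of pattern clusters, and the modified-Z-score settings used for
#' survival scoring.
#'
#' @param fc_threshold fold-change cutoff (> 1); genes must exceed it
#'   strictly (default 2).
#' @param alpha significance level (default 0.05).
#' @param use_fdr if TRUE the BH-adjusted value is compared to `alpha`
#'   instead of the raw p-value.
#' @param prior_count pseudo-count added before log-CPM (default 0.5).
#' @param k_clusters number of K-means pattern clusters (default 4).
#' @param sd_multiplier multiplier of the score SD in the survival
#'   stratification threshold (default 2).
#' @param mz_method `"median_mad"` (canonical modified Z-score) or
#'   `"mean_ad"` (mean-absolute-deviation variant).
#' @param seed integer seed for seeded steps (K-means restarts,
#'   permutations).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(fc_threshold = 2, alpha = 0.05, use_fdr = FALSE,
                            prior_count = 0.5, k_clusters = 4,
                            sd_multiplier = 2,
                            mz_method = c("median_mad", "mean_ad"),
                            seed = 1) {
  check_scalar(fc_threshold, "fc_threshold", lower = 1, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(prior_count, "prior_count", lower = 0)
  k_clusters <- check_count(k_clusters, "k_clusters")
  check_scalar(sd_multiplier, "sd_multiplier", lower = 0)
  structure(
    list(fc_threshold = fc_threshold, alpha = alpha, use_fdr = isTRUE(use_fdr),
         prior_count = prior_count, k_clusters = k_clusters,
         sd_multiplier = sd_multiplier, mz_method = match.arg(mz_method),
         seed = seed),
    class = "analysis_config"
  )
}

# one sample against the reference: weighted, doubly-trimmed mean of
# gene-wise log expression ratios
tmm_pair <- function(obs, ref, trim_m, trim_a) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # inverse of the asymptotic variance of M (delta method, binomial sampling)
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  n <- length(log_r)
  if (n == 0L) {
    warning("no genes survive zero filtering; TMM factor set to 1")
    return(1)
  }
  if (max(abs(log_r)) < 1e-6) return(1)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(log_r) >= lo_m & rank(log_r) <= hi_m &
    rank(abs_e) >= lo_a & rank(abs_e) <= hi_a
  if (!any(keep)) {
    warning("no genes survive trimming; TMM factor set to 1")
    return(1)
  }
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM procedure: against a
#' reference sample, genes with a zero count in either sample are excluded;
#' the gene-wise log2 expression-ratio values (M) are doubly trimmed (30
#' percent on M, 5 percent on average log intensity A, both tails) and
#' averaged with inverse-asymptotic-variance weights; factors are rescaled
#' to have geometric mean one.  The reference defaults to the sample whose
#' upper-quartile count fraction is closest to the mean upper quartile.
#'
#' @param counts validated count matrix (genes x samples).
#' @param ref reference sample id, or NULL for the upper-quartile rule.
#' @param trim_m,trim_a two-tail trim fractions on M and A.
#' @return Named numeric vector of factors (geometric mean 1) with the
#'   reference sample id in attribute `"ref"`.
#' @export
tmm_factors <- function(counts, ref = NULL, trim_m = 0.3, trim_a = 0.05) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(ref)) {
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  } else if (!ref %in% colnames(counts)) {
    stop("reference sample not found: ", ref, call. = FALSE)
  }
  f <- vapply(colnames(counts), function(s) {
    tmm_pair(counts[, s], counts[, ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  attr(f, "ref") <- ref
  f
}

#' Log2 counts-per-million with a pseudo-count
#'
#' `log2((count + prior_count) / (effective library size in millions))`,
#' where the effective size is the column total times its normalization
#' factor.
#'
#' @param counts validated count matrix.
#' @param factors per-sample normalization factors aligned to columns
#'   (default 1 for all samples).
#' @param prior_count pseudo-count (> 0 keeps every value finite).
#' @return Numeric matrix of log2 CPM values, same shape as `counts`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  validate_counts(counts)
  check_scalar(prior_count, "prior_count", lower = 0)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (!is.null(names(factors))) {
    if (!all(colnames(counts) %in% names(factors))) {
      stop("factors missing for some samples", call. = FALSE)
    }
    factors <- factors[colnames(counts)]
  }
  if (length(factors) != ncol(counts)) {
    stop("need one factor per sample", call. = FALSE)
  }
  eff <- colSums(counts) * factors
  if (any(eff <= 0)) stop("non-positive effective library size", call. = FALSE)
  out <- log2(sweep(counts + prior_count, 2, eff / 1e6, "/"))
  if (!all(is.finite(out))) stop("non-finite log-CPM values", call. = FALSE)
  out
}
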