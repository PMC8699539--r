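#' Modified Z-score normalization of an expression matrix
#'
#' Robust per-gene standardization across patients.  The canonical form
#' (`median_mad`) is `0.6745 * (x - median) / MAD` with
#' `MAD = median(|x - median|)`; the mean-absolute-deviation variant
#' (`mean_ad`) is `(x - mean) / (1.2533 * meanAD)`.  The constants make
#' each estimator consistent for the SD under normality.  Genes whose MAD
#' is zero but that are not constant fall back to the mean-AD scale;
#' constant genes are set to zero with a warning.
#'
#' @param x numeric matrix, patients in rows, genes in columns.
#' @param method `"median_mad"` (default) or `"mean_ad"`.
#' @return Matrix of modified Z-scores, same shape as `x`.
#' @export
modified_z <- function(x, method = c("median_mad", "mean_ad")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x))
  if (nrow(x) < 3L) stop("need at least 3 patients", call. = FALSE)
  z <- x
  warned <- FALSE
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (method == "median_mad") {
      med <- stats::median(v)
      mad_raw <- stats::median(abs(v - med))
      if (mad_raw > 0) {
        z[, j] <- 0.6745 * (v - med) / mad_raw
        next
      }
      mean_ad <- mean(abs(v - med))
      if (mean_ad > 0) {
        z[, j] <- (v - med) / (1.2533 * mean_ad)
        next
      }
      z[, j] <- 0
      warned <- TRUE
    } else {
      mu <- mean(v)
      mean_ad <- mean(abs(v - mu))
      if (mean_ad > 0) {
        z[, j] <- (v - mu) / (1.2533 * mean_ad)
      } else {
        z[, j] <- 0
        warned <- TRUE
      }
    }
  }
  if (warned) warning("constant gene(s) set to zero modified Z")
  z
}

#' Average modified Z-score over a signature
#'
#' The per-patient signature score: the mean of modified Z-scores over the
#' measured signature genes.
#'
#' @param z matrix from [modified_z()] (patients x genes).
#' @param signature a `signature_definition` or character vector of
#'   symbols.
#' @return Named numeric vector of per-patient scores; unmeasured
#'   signature genes are reported in the `"missing"` attribute.
#' @export
avemz <- function(z, signature) {
  genes <- if (inherits(signature, "signature_definition")) {
    signature$gene_ids
  } else {
    toupper(signature)
  }
  measured <- intersect(genes, colnames(z))
  if (!length(measured)) {
    stop("no signature genes measured in the matrix", call. = FALSE)
  }
  missing <- setdiff(genes, measured)
  if (length(missing)) {
    warning("signature genes not measured: ", paste(missing, collapse = ", "))
  }
  out <- rowMeans(z[, measured, drop = FALSE])
  attr(out, "missing") <- missing
  out
}

#' Stratify patients by signature score
#'
#' Patients are called signature-high ("altered") when their score strictly
#' exceeds `mean + sd_multiplier * SD` of the score vector (population SD,
#' n denominator: the threshold describes this cohort, it is not an
#' inferential estimate).
#'
#' @param scores named numeric vector of per-patient scores (e.g. from
#'   [avemz()]).
#' @param sd_multiplier number of SDs above the mean (default 2).
#' @return data.frame: patient_id, score, stratum ("high"/"low"), with the
#'   threshold in the `"threshold"` attribute.
#' @export
stratify <- function(scores, sd_multiplier = 2) {
  check_scalar(sd_multiplier, "sd_multiplier", lower = 0)
  if (length(scores) < 2L) stop("need at least 2 patients", call. = FALSE)
  sd_pop <- sqrt(mean((scores - mean(scores))^2))
  if (sd_pop == 0) {
    warning("zero score variance; all patients called unaltered")
  }
  thr <- mean(scores) + sd_multiplier * sd_pop
  out <- data.frame(
    patient_id = if (is.null(names(scores))) {
      sprintf("PT%04d", seq_along(scores))
    } else {
      names(scores)
    },
    score = as.numeric(scores),
    stratum = ifelse(scores > thr, "high", "low"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per stratum; censored times reduce the risk set
#' without introducing steps.
#'
#' @param cohort data.frame with `time` (months, > 0), `event` (0/1), and
#'   optionally `stratum`.
#' @param stratum optional stratum label to restrict to.
#' @return data.frame: stratum, time, n_risk, n_event, n_censor, survival.
#' @export
km_estimate <- function(cohort, stratum = NULL) {
  if (!is.null(stratum)) {
    cohort <- cohort[cohort$stratum == stratum, , drop = FALSE]
  }
  if (!nrow(cohort)) stop("empty cohort/stratum", call. = FALSE)
  if (any(cohort$time <= 0)) stop("times must be positive", call. = FALSE)
  has_strata <- "stratum" %in% names(cohort) &&
    length(unique(cohort$stratum)) > 1L
  fit <- if (has_strata) {
    survival::survfit(survival::Surv(time, event) ~ stratum, data = cohort)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  }
  s <- summary(fit, censored = TRUE)
  data.frame(
    stratum = if (has_strata) {
      sub("^stratum=", "", as.character(s$strata))
    } else {
      rep(if (!is.null(stratum)) stratum else "all", length(s$time))
    },
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    survival = s$surv,
    stringsAsFactors = FALSE
  )
}

#' Two-group logrank test
#'
#' Standard logrank comparison of the high and low strata: at each distinct
#' event time the observed number of group events is compared with its
#' hypergeometric expectation; the chi-square statistic (1 df) aggregates
#' observed minus expected over event times with the standard tie-aware
#' variance.
#'
#' @param cohort data.frame with `time`, `event`, and a two-level
#'   `stratum` column.
#' @return A list of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (named by stratum), `n`.
#' @export
logrank_test <- function(cohort) {
  if (!all(c("time", "event", "stratum") %in% names(cohort))) {
    stop("cohort needs time, event, stratum columns", call. = FALSE)
  }
  grp <- unique(cohort$stratum)
  if (length(grp) != 2L || any(table(cohort$stratum) == 0)) {
    stop("need exactly two nonempty strata", call. = FALSE)
  }
  if (sum(cohort$event) == 0) {
    stop("no events observed; logrank undefined", call. = FALSE)
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                               data = cohort)
  labels <- sub("^stratum=", "", names(sd_fit$n))
  p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  structure(
    list(chi_square = unname(sd_fit$chisq), df = 1L, p_value = p,
         observed = stats::setNames(as.numeric(sd_fit$obs), labels),
         expected = stats::setNames(as.numeric(sd_fit$exp), labels),
         n = stats::setNames(as.numeric(sd_fit$n), labels)),
    class = "logrank_result"
  )
}

# normalize heterogeneous receptor-status codes to "+"/"-"
normalize_status <- function(x, column) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("+", "pos", "positive", "1")] <- "+"
  out[x0 %in% c("-", "neg", "negative", "0")] <- "-"
  bad <- unique(x0[is.na(out)])
  if (length(bad)) {
    stop(sprintf("unknown %s status code(s): %s", column,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Filter a clinical table by receptor-status subtype
#'
#' @param clinical data.frame with `er_status` and `her2_status` columns
#'   (and `pr_status` for the TNBC rule); codes may be `+`/`-`,
#'   `pos`/`neg`, `positive`/`negative`, or 1/0.
#' @param rule `"ER+/HER2-"` (hormone-receptor positive, HER2 negative) or
#'   `"TNBC"` (triple negative: ER-, PR-, HER2-).
#' @return The matching rows; the number kept is reported in the
#'   `"n_kept"` attribute, and an empty result warns.
#' @export
subtype_filter <- function(clinical, rule = c("ER+/HER2-", "TNBC")) {
  rule <- match.arg(rule)
  need <- c("er_status", "her2_status", if (rule == "TNBC") "pr_status")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  er <- normalize_status(clinical$er_status, "ER")
  her2 <- normalize_status(clinical$her2_status, "HER2")
  keep <- if (rule == "ER+/HER2-") {
    er == "+" & her2 == "-"
  } else {
    pr <- normalize_status(clinical$pr_status, "PR")
    er == "-" & pr == "-" & her2 == "-"
  }
  out <- clinical[keep, , drop = FALSE]
  if (!nrow(out)) warning("no patients match the ", rule, " rule")
  attr(out, "n_kept") <- nrow(out)
  out
}
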