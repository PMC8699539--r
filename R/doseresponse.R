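#' Four-parameter logistic curve
#'
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)`.  With `hill > 0`
#' the curve falls from `top` toward `bottom` as dose increases (the usual
#' shape for viability against an inhibitor); `ic50` is the midpoint dose
#' regardless of direction.
#'
#' @param dose positive dose(s).
#' @param top,bottom asymptotes.
#' @param ic50 midpoint dose.
#' @param hill slope.
#' @return Numeric vector of responses.
#' @export
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Least-squares four-parameter logistic fit
#'
#' Fits viability-versus-dose data by nonlinear least squares
#' (Levenberg-Marquardt) with a multi-start grid of IC50 initial values at
#' the observed dose quantiles, keeping the best fit by residual sum of
#' squares.  Degenerate (flat) data and failed optimizations are reported
#' with `converged = FALSE` rather than a spurious fit; fitted IC50s
#' outside the tested dose range are flagged (`in_range = FALSE`), since
#' those are bounds, not estimates.
#'
#' @param doses positive doses (micromolar), at least 4 distinct values.
#' @param viability numeric vector (one value per dose), matrix, or
#'   data.frame of replicate measurements with rows matching `doses`; a
#'   `dose_um` column, if present, is used as the doses.
#' @return An object of class `dose_response_fit`: `top`, `bottom`,
#'   `ic50`, `hill`, `rss`, `converged`, `in_range`, `n_points`.
#' @export
fit_4pl <- function(doses, viability) {
  if (is.data.frame(viability) && "dose_um" %in% names(viability)) {
    doses <- viability$dose_um
    viability <- viability[setdiff(names(viability), "dose_um")]
  }
  viability <- as.matrix(viability)
  if (length(doses) != nrow(viability)) {
    stop("viability rows must match doses", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(unique(doses)) < 4L) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  d <- rep(doses, times = ncol(viability))
  v <- as.numeric(viability)
  ok <- is.finite(v)
  d <- d[ok]; v <- v[ok]

  unconverged <- structure(
    list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_, hill = NA_real_,
         rss = NA_real_, converged = FALSE, in_range = NA, n_points = length(v)),
    class = "dose_response_fit"
  )
  dose_means <- tapply(v, d, mean)
  if (diff(range(dose_means)) < 1e-8 * max(1, mean(abs(v)))) {
    return(unconverged)  # flat response: ic50 unidentifiable
  }

  hill0 <- if (utils::tail(dose_means, 1) < dose_means[1]) 1 else -1
  ic50_starts <- stats::quantile(unique(doses), c(0.1, 0.25, 0.5, 0.75, 0.9))
  dat <- data.frame(d = d, v = v)
  best <- NULL
  for (ic0 in ic50_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (d / ic50)^hill),
        data = dat,
        start = list(top = max(dose_means), bottom = min(dose_means),
                     ic50 = as.numeric(ic0), hill = hill0),
        lower = c(top = -Inf, bottom = -Inf, ic50 = min(doses) * 1e-4,
                  hill = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) return(unconverged)
  cf <- as.list(best$coef)
  # (top, bottom, hill) -> (bottom, top, -hill) leaves the curve unchanged;
  # normalize so top >= bottom
  if (cf$top < cf$bottom) {
    tmp <- cf$top; cf$top <- cf$bottom; cf$bottom <- tmp
    cf$hill <- -cf$hill
  }
  structure(
    list(top = cf$top, bottom = cf$bottom, ic50 = cf$ic50, hill = cf$hill,
         rss = best$rss, converged = TRUE,
         in_range = cf$ic50 >= min(doses) && cf$ic50 <= max(doses),
         n_points = length(v)),
    class = "dose_response_fit"
  )
}

#' IC50 sensitivity ratio between two fits
#'
#' `ic50_a / ic50_b`: values above 1 mean condition b responds at lower
#' doses (is more sensitive) than condition a.
#'
#' @param fit_a,fit_b converged [fit_4pl()] results.
#' @return Positive scalar fold change.
#' @export
sensitivity_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both fits must have converged", call. = FALSE)
  }
  fit_a$ic50 / fit_b$ic50
}
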