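#' A 16-gene FOXM1-associated target panel
#'
#' Cell-cycle and checkpoint genes regulated by the FOXM1 transcription
#' factor (including FOXM1 itself), useful as a profiling panel across the
#' parental/treated/resistant conditions with [gene_profile_table()].
#'
#' @return Character vector of 16 gene symbols.
#' @export
foxm1_target_panel <- function() {
  c("FOXM1", "CENPA", "CDC25B", "CCNB2", "CCNE1", "RB1", "CDC25A", "E2F1",
    "CDKN2C", "MCM2", "CDK2", "RRM2", "PCNA", "CDKN1A", "CCND1", "CCNE2")
}

# Welch two-sample t on one gene; degenerate zero-variance data carry no
# evidence and get p = 1
welch_p <- function(a, b) {
  out <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  if (is.na(out)) out <- 1
  out
}

#' Differential expression between two conditions
#'
#' Per-gene two-sided Welch t-test on (normalized) log-CPM values, with
#' log2 fold change computed as the difference of group means
#' (first-named condition minus second) and Benjamini-Hochberg adjustment
#' across all genes in the contrast.
#'
#' @param expr log-CPM matrix (genes x samples).
#' @param design design table with `sample_id` and `condition` columns
#'   covering the matrix samples.
#' @param contrast length-2 character, e.g. `c("R", "P")` for R vs P.
#' @return data.frame with one row per gene: gene_id, contrast, log2FC,
#'   p_value, fdr, mean_a, mean_b.
#' @export
differential_expression <- function(expr, design, contrast = c("R", "P")) {
  stopifnot(is.matrix(expr), length(contrast) == 2L)
  design <- check_design(design, expr)
  unknown <- setdiff(contrast, unique(design$condition))
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ia <- which(design$condition == contrast[1])
  ib <- which(design$condition == contrast[2])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each side of the contrast needs >= 2 replicates", call. = FALSE)
  }
  a <- expr[, ia, drop = FALSE]
  b <- expr[, ib, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  p <- vapply(seq_len(nrow(expr)), function(i) welch_p(a[i, ], b[i, ]),
              numeric(1))
  data.frame(gene_id = rownames(expr),
             contrast = paste0(contrast[1], "_vs_", contrast[2]),
             log2FC = mean_a - mean_b,
             p_value = p,
             fdr = bh_adjust(p),
             mean_a = mean_a,
             mean_b = mean_b,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input vector.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter a differential-expression result into up/down gene lists
#'
#' Genes pass when `|log2FC| > log2(fc_threshold)` (strict) and the raw
#' p-value (or BH-adjusted value when `use_fdr`) is strictly below `alpha`.
#' Both lists are ordered by decreasing absolute fold change, ties broken
#' by symbol.
#'
#' @param results one-contrast data.frame from
#'   [differential_expression()].
#' @param config an [analysis_config()].
#' @return An object of class `deg_list`: list with `contrast`, `up`,
#'   `down`, and the thresholds used.
#' @export
filter_deg <- function(results, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (length(unique(results$contrast)) > 1L) {
    stop("results must come from a single contrast", call. = FALSE)
  }
  sig <- if (config$use_fdr) results$fdr else results$p_value
  lfc <- results$log2FC
  cut <- log2(config$fc_threshold)
  pick <- function(idx) {
    idx <- idx[order(-abs(lfc[idx]), results$gene_id[idx])]
    results$gene_id[idx]
  }
  structure(
    list(contrast = results$contrast[1],
         up = pick(which(lfc > cut & sig < config$alpha)),
         down = pick(which(lfc < -cut & sig < config$alpha)),
         fc_threshold = config$fc_threshold,
         alpha = config$alpha,
         use_fdr = config$use_fdr),
    class = "deg_list"
  )
}

#' Per-gene condition means for a gene panel
#'
#' Profiles a panel of genes across the parental/treated/resistant
#' conditions: mean expression per condition plus the T-P and R-P deltas,
#' the table behind bar-chart style panel figures.
#'
#' @param expr log-CPM matrix.
#' @param design design table with conditions P, T, R.
#' @param panel character vector of gene symbols; missing symbols are
#'   reported via a warning and the `"missing"` attribute.
#' @return data.frame: gene_id, P, T, R, delta_T (T-P), delta_R (R-P).
#' @export
gene_profile_table <- function(expr, design, panel) {
  if (!length(panel)) stop("empty gene panel", call. = FALSE)
  panel <- toupper(panel)
  design <- check_design(design, expr)
  missing <- setdiff(panel, rownames(expr))
  if (length(missing)) {
    warning("panel genes not in the matrix: ",
            paste(missing, collapse = ", "))
  }
  panel <- intersect(panel, rownames(expr))
  cond_mean <- function(cond) {
    rowMeans(expr[panel, design$sample_id[design$condition == cond],
                  drop = FALSE])
  }
  out <- data.frame(gene_id = panel,
                    P = cond_mean("P"), T = cond_mean("T"), R = cond_mean("R"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$delta_T <- out$T - out$P
  out$delta_R <- out$R - out$P
  attr(out, "missing") <- missing
  out
}
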