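#' Describe a planted expression program
#'
#' A program is a named set of genes sharing multiplicative fold effects in
#' short-term treated (T) and resistant (R) cells relative to parental (P).
#' The four archetype patterns seen in inhibitor-resistance experiments are
#' expressible as fold pairs, e.g. treatment-induced/reverting programs have
#' `fold_T_vs_P > 1, fold_R_vs_P ~ 1`, resistance-only programs have
#' `fold_T_vs_P ~ 1, fold_R_vs_P > 1`.
#'
#' @param name program label.
#' @param gene_ids character vector of gene symbols carrying the effect.
#' @param fold_T_vs_P,fold_R_vs_P positive multipliers applied to the
#'   baseline mean in the T and R conditions.
#' @return An object of class `planted_program`.
#' @export
planted_program <- function(name, gene_ids, fold_T_vs_P = 1, fold_R_vs_P = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  gene_ids <- toupper(as.character(gene_ids))
  if (!length(gene_ids) || anyDuplicated(gene_ids)) {
    stop("gene_ids must be a non-empty set of unique symbols", call. = FALSE)
  }
  check_scalar(fold_T_vs_P, "fold_T_vs_P", lower = 0, strict_lower = TRUE)
  check_scalar(fold_R_vs_P, "fold_R_vs_P", lower = 0, strict_lower = TRUE)
  structure(
    list(name = name, gene_ids = gene_ids,
         fold_T_vs_P = fold_T_vs_P, fold_R_vs_P = fold_R_vs_P),
    class = "planted_program"
  )
}

#' Configuration for the negative-binomial count simulator
#'
#' Counts are drawn per gene and sample from a negative binomial with
#' variance `mu + dispersion * mu^2` (the mean/dispersion convention used by
#' count-based differential-expression tools).  Baseline log2 mean
#' expressions are uniform over `baseline_mean_log2_range`; per-sample
#' library-size factors are drawn log-uniform in [0.5, 2] so that
#' between-sample normalization has real work to do.
#'
#' @param n_genes number of genes in the matrix.
#' @param replicates_per_condition replicates for each of P, T, R
#'   (default 3, the usual design for this kind of experiment).
#' @param baseline_mean_log2_range length-2 numeric, log2 of the baseline
#'   mean count.
#' @param dispersion negative-binomial dispersion phi (> 0).
#' @param programs list of [planted_program()] objects with disjoint gene
#'   sets.
#' @param seed integer seed; identical configurations and seeds give
#'   byte-identical output.
#' @return An object of class `count_truth_config`.
#' @export
count_truth_config <- function(n_genes,
                               replicates_per_condition = 3,
                               baseline_mean_log2_range = c(5, 10),
                               dispersion = 0.1,
                               programs = list(),
                               seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  replicates_per_condition <- check_count(replicates_per_condition,
                                          "replicates_per_condition", min = 2)
  stopifnot(length(baseline_mean_log2_range) == 2L,
            diff(baseline_mean_log2_range) >= 0)
  check_scalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  if (!all(vapply(programs, inherits, logical(1), "planted_program"))) {
    stop("programs must be a list of planted_program objects", call. = FALSE)
  }
  all_ids <- unlist(lapply(programs, `[[`, "gene_ids"))
  clash <- unique(all_ids[duplicated(all_ids)])
  if (length(clash)) {
    stop("program gene sets overlap: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  if (length(all_ids) > n_genes) {
    stop("programs reference more genes than n_genes", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes,
         replicates_per_condition = replicates_per_condition,
         baseline_mean_log2_range = as.numeric(baseline_mean_log2_range),
         dispersion = dispersion,
         programs = programs,
         seed = seed),
    class = "count_truth_config"
  )
}

#' Simulate a P/T/R count matrix with planted programs
#'
#' Draws a genes-by-samples matrix of negative-binomial counts for three
#' conditions (parental P, short-term treated T, resistant R) with
#' `replicates_per_condition` samples each.  Condition means equal the
#' baseline mean times the program fold multiplier; non-program genes are
#' null (fold 1 in both contrasts).  A truth table records every planted
#' effect for recovery testing.
#'
#' @param config a [count_truth_config()].
#' @return A list with elements `counts` (integer matrix), `design`
#'   (data.frame: sample_id, cell_line, condition, replicate),
#'   `truth` (data.frame: gene_id, program, fold_T_vs_P, fold_R_vs_P),
#'   and `size_factors` (the simulated library-size multipliers, useful when
#'   checking that normalization recovers them).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_truth_config"))
  prog_ids <- unlist(lapply(config$programs, `[[`, "gene_ids"))
  n_free <- config$n_genes - length(prog_ids)
  free_ids <- sprintf("GENE%05d", seq_len(n_free))
  gene_ids <- c(prog_ids, free_ids)
  if (anyDuplicated(gene_ids)) {
    stop("program symbols collide with generated background symbols",
         call. = FALSE)
  }

  fold_T <- stats::setNames(rep(1, config$n_genes), gene_ids)
  fold_R <- fold_T
  prog_of <- stats::setNames(rep("none", config$n_genes), gene_ids)
  for (pr in config$programs) {
    fold_T[pr$gene_ids] <- pr$fold_T_vs_P
    fold_R[pr$gene_ids] <- pr$fold_R_vs_P
    prog_of[pr$gene_ids] <- pr$name
  }

  nrep <- config$replicates_per_condition
  cond <- rep(c("P", "T", "R"), each = nrep)
  sample_ids <- paste0(cond, rep(seq_len(nrep), times = 3))
  design <- data.frame(sample_id = sample_ids,
                       cell_line = "SYN",
                       condition = cond,
                       replicate = rep(seq_len(nrep), times = 3),
                       stringsAsFactors = FALSE)

  counts <- with_seed(config$seed, {
    base_log2 <- stats::runif(config$n_genes,
                              config$baseline_mean_log2_range[1],
                              config$baseline_mean_log2_range[2])
    baseline <- 2^base_log2
    sf <- 2^stats::runif(length(sample_ids), -1, 1)  # log-uniform in [0.5, 2]
    cond_fold <- rbind(P = rep(1, config$n_genes), T = fold_T, R = fold_R)
    m <- matrix(0L, config$n_genes, length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      mu <- baseline * cond_fold[cond[j], ] * sf[j]
      m[, j] <- stats::rnbinom(config$n_genes, mu = mu,
                               size = 1 / config$dispersion)
    }
    attr(m, "size_factors") <- stats::setNames(sf, sample_ids)
    m
  })
  sf <- attr(counts, "size_factors")
  attr(counts, "size_factors") <- NULL
  validate_counts(counts)

  truth <- data.frame(gene_id = gene_ids,
                      program = unname(prog_of),
                      fold_T_vs_P = unname(fold_T),
                      fold_R_vs_P = unname(fold_R),
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth, size_factors = sf)
}

#' Synthetic dataset for interferon-signature derivation recovery
#'
#' Builds the planted-truth fixture that emulates the derivation of an
#' interferon-related resistance signature: a hallmark-style source set of
#' `n_source` interferon-response symbols, of which `n_up` are planted
#' strongly upregulated and `n_down` strongly downregulated in resistant vs
#' parental cells; the remaining source symbols are left out of the measured
#' universe so that recovery measures the normalization/testing chain rather
#' than threshold leakage of null genes.  Baselines are drawn from the
#' well-quantified range (2^7 to 2^10) so that strongly suppressed genes
#' remain measurable.
#'
#' @param seed integer seed.
#' @param n_genes size of the measured gene universe.
#' @param n_up,n_down planted up/downregulated source-set genes (defaults
#'   43 and 9, the published derivation outcome).
#' @param n_source total size of the interferon source set.
#' @param fold planted fold change (applied as `fold` up and `1/fold` down);
#'   default 16, a strong induction of the kind seen for interferon-response
#'   genes in resistant cells.
#' @param dispersion negative-binomial dispersion.
#' @return A list: `counts`, `design`, `truth`, `source_set` (all
#'   `n_source` symbols), `up_genes`, `down_genes`.
#' @export
simulate_signature_dataset <- function(seed = 1, n_genes = 2000,
                                       n_up = 43, n_down = 9,
                                       n_source = 224, fold = 16,
                                       dispersion = 0.1) {
  stopifnot(n_up + n_down <= n_source)
  source_set <- sprintf("IFNG%03d", seq_len(n_source))
  up_genes <- source_set[seq_len(n_up)]
  down_genes <- source_set[n_up + seq_len(n_down)]
  cfg <- count_truth_config(
    n_genes = n_genes,
    replicates_per_condition = 3,
    baseline_mean_log2_range = c(7, 10),
    dispersion = dispersion,
    programs = list(
      planted_program("ifn_up", up_genes, fold_T_vs_P = 1, fold_R_vs_P = fold),
      planted_program("ifn_down", down_genes, fold_T_vs_P = 1,
                      fold_R_vs_P = 1 / fold)
    ),
    seed = seed
  )
  sim <- simulate_counts(cfg)
  c(sim, list(source_set = source_set, up_genes = up_genes,
              down_genes = down_genes, config = cfg))
}

#' Configuration for synthetic survival cohorts
#'
#' Event times are exponential with hazard `baseline_hazard` for unaltered
#' patients and `baseline_hazard * hazard_ratio_high` for signature-high
#' patients.  Censoring combines an administrative horizon with independent
#' uniform early censoring applied to a `censoring_rate` fraction of
#' patients.
#'
#' @param n_patients cohort size.
#' @param baseline_hazard events per month in the reference group.
#' @param hazard_ratio_high multiplicative hazard for the high stratum.
#' @param censoring_rate fraction in [0, 1) receiving an early uniform
#'   censoring time.
#' @param follow_up_horizon administrative censoring time, months.
#' @param seed integer seed.
#' @return An object of class `survival_truth_config`.
#' @export
survival_truth_config <- function(n_patients,
                                  baseline_hazard = 0.01,
                                  hazard_ratio_high = 2,
                                  censoring_rate = 0.2,
                                  follow_up_horizon = 300,
                                  seed = 1) {
  n_patients <- check_count(n_patients, "n_patients")
  check_scalar(baseline_hazard, "baseline_hazard", lower = 0, strict_lower = TRUE)
  check_scalar(hazard_ratio_high, "hazard_ratio_high", lower = 0,
               strict_lower = TRUE)
  check_scalar(censoring_rate, "censoring_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_scalar(follow_up_horizon, "follow_up_horizon", lower = 0,
               strict_lower = TRUE)
  structure(
    list(n_patients = n_patients, baseline_hazard = baseline_hazard,
         hazard_ratio_high = hazard_ratio_high,
         censoring_rate = censoring_rate,
         follow_up_horizon = follow_up_horizon, seed = seed),
    class = "survival_truth_config"
  )
}

#' Simulate a survival cohort linked to stratum labels
#'
#' @param config a [survival_truth_config()].
#' @param labels per-patient stratum labels: a character vector with values
#'   `"high"`/`"low"` (or a logical vector, `TRUE` = high) of length
#'   `n_patients`.
#' @return data.frame: patient_id, time (months), event (0/1), stratum.
#' @export
simulate_survival_cohort <- function(config, labels) {
  stopifnot(inherits(config, "survival_truth_config"))
  if (is.logical(labels)) labels <- ifelse(labels, "high", "low")
  if (length(labels) != config$n_patients) {
    stop("need one label per patient", call. = FALSE)
  }
  if (!all(labels %in% c("high", "low"))) {
    stop('labels must be "high" or "low"', call. = FALSE)
  }
  n <- config$n_patients
  with_seed(config$seed, {
    rate <- config$baseline_hazard *
      ifelse(labels == "high", config$hazard_ratio_high, 1)
    t_event <- stats::rexp(n, rate = rate)
    cens <- rep(config$follow_up_horizon, n)
    early <- stats::runif(n) < config$censoring_rate
    cens[early] <- stats::runif(sum(early), 0, config$follow_up_horizon)
    time <- pmin(t_event, cens)
    data.frame(patient_id = sprintf("PT%04d", seq_len(n)),
               time = time,
               event = as.integer(t_event <= cens),
               stratum = labels,
               stringsAsFactors = FALSE)
  })
}

#' Ground truth for a simulated dose-response curve
#'
#' @param top,bottom upper/lower viability asymptotes (percent).
#' @param ic50 midpoint dose, micromolar.
#' @param hill slope of the four-parameter logistic.
#' @param doses strictly increasing positive dose ladder, micromolar.
#' @param noise_sd Gaussian noise SD added to viability (percent).
#' @param n_replicates replicate measurements per dose.
#' @param seed integer seed.
#' @return An object of class `dose_response_truth`.
#' @export
dose_response_truth <- function(top = 100, bottom = 0, ic50 = 1, hill = 1,
                                doses = 10^seq(-2, log10(20), length.out = 8),
                                noise_sd = 5, n_replicates = 3, seed = 1) {
  stopifnot(top > bottom, ic50 > 0, length(doses) >= 1)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  structure(
    list(top = top, bottom = bottom, ic50 = ic50, hill = hill,
         doses = as.numeric(doses), noise_sd = noise_sd,
         n_replicates = n_replicates, seed = seed),
    class = "dose_response_truth"
  )
}

#' Simulate replicate viability measurements from a 4PL truth
#'
#' @param truth a [dose_response_truth()].
#' @return data.frame with `dose_um` and one `repk` column per replicate.
#' @export
simulate_dose_response <- function(truth) {
  stopifnot(inherits(truth, "dose_response_truth"))
  mu <- four_pl(truth$doses, truth$top, truth$bottom, truth$ic50, truth$hill)
  reps <- with_seed(truth$seed, {
    vapply(seq_len(truth$n_replicates), function(i) {
      mu + stats::rnorm(length(mu), sd = truth$noise_sd)
    }, numeric(length(mu)))
  })
  reps <- matrix(reps, nrow = length(mu))
  colnames(reps) <- paste0("rep", seq_len(truth$n_replicates))
  cbind(data.frame(dose_um = truth$doses), as.data.frame(reps))
}

#' Construct a gene-set collection
#'
#' Builds a named list of gene sets from a specification mixing explicit
#' symbol vectors and requested sizes (sampled from `universe`, or generated
#' fresh when no universe is given).  The result is GMT-writable with
#' [write_gmt()] and deterministic under `seed`.
#'
#' @param sets named list; each element is either a character vector of
#'   symbols or a single number giving a requested set size.
#' @param universe optional pool of symbols for size-specified sets.
#' @param seed integer seed used when sampling from `universe`.
#' @return Named list of character vectors.
#' @export
make_gene_sets <- function(sets, universe = NULL, seed = 1) {
  if (length(sets) == 0) return(stats::setNames(list(), character(0)))
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(seq_along(sets), function(i) {
      s <- sets[[i]]
      if (is.character(s)) {
        s <- toupper(s)
        if (!is.null(universe) && !all(s %in% toupper(universe))) {
          stop("set '", nm[i], "' contains symbols outside the universe",
               call. = FALSE)
        }
        return(s)
      }
      size <- check_count(s, paste0("size of set '", nm[i], "'"))
      if (is.null(universe)) {
        sprintf("%s_G%04d", toupper(nm[i]), seq_len(size))
      } else {
        if (size > length(universe)) {
          stop("set '", nm[i], "' larger than the universe", call. = FALSE)
        }
        sample(toupper(universe), size)
      }
    })
    stats::setNames(out, nm)
  })
}
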