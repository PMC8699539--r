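#' Standardized P/T/R condition profiles
#'
#' For each gene, the three condition means (P, T, R) are standardized to
#' mean 0 and (population) SD 1 across the triple, giving shape-only
#' profiles suitable for pattern clustering.  Genes with zero variance
#' across conditions are excluded and reported.
#'
#' @param expr log-CPM matrix.
#' @param design design table; all three conditions must be present.
#' @param genes optional subset of genes (e.g. the union of
#'   differential-expression hits) to profile; default all.
#' @return Numeric matrix with columns zP, zT, zR and excluded genes in the
#'   `"excluded"` attribute.
#' @export
condition_profiles <- function(expr, design, genes = NULL) {
  design <- check_design(design, expr)
  if (!all(c("P", "T", "R") %in% design$condition)) {
    stop("all three conditions P, T, R are required", call. = FALSE)
  }
  if (is.null(genes)) genes <- rownames(expr)
  genes <- intersect(toupper(genes), rownames(expr))
  m <- vapply(c("P", "T", "R"), function(cond) {
    rowMeans(expr[genes, design$sample_id[design$condition == cond],
                  drop = FALSE])
  }, numeric(length(genes)))
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  keep <- sd_pop > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  colnames(z) <- c("zP", "zT", "zR")
  attr(z, "excluded") <- genes[!keep]
  z
}

#' K-means clustering of expression-pattern profiles
#'
#' Lloyd's algorithm with Euclidean distance, taking the best of `n_init`
#' seeded restarts by total within-cluster sum of squares; deterministic
#' given `seed`.
#'
#' @param profiles matrix from [condition_profiles()].
#' @param k number of clusters.
#' @param seed integer seed for the restarts.
#' @param n_init number of random restarts.
#' @return A list of class `pattern_clusters`: `cluster` (named integer
#'   assignment), `centers` (k x 3), `sizes`, `tot_withinss`,
#'   `archetype` (filled by [label_archetypes()], initially unassigned).
#' @export
kmeans_patterns <- function(profiles, k = 4, seed = 1, n_init = 10) {
  k <- check_count(k, "k")
  if (k > nrow(profiles)) stop("k exceeds the number of genes", call. = FALSE)
  km <- with_seed(seed, {
    stats::kmeans(profiles, centers = k, nstart = n_init,
                  algorithm = "Lloyd", iter.max = 200)
  })
  structure(
    list(cluster = stats::setNames(km$cluster, rownames(profiles)),
         centers = km$centers,
         sizes = km$size,
         tot_withinss = km$tot.withinss,
         archetype = rep("unassigned", k)),
    class = "pattern_clusters"
  )
}

# archetype from the sign pattern of centroid deltas (zT - zP, zR - zP)
archetype_of <- function(d_t, d_r, delta) {
  if (d_t > delta && abs(d_r) <= delta) return("A")   # up in T, reverts in R
  if (d_r < -delta) return("B")                       # down in R
  if (d_t < -delta && d_r >= -delta) return("C")      # down in T, restored
  if (abs(d_t) <= delta && d_r > delta) return("D")   # up only in R
  "unassigned"
}

#' Label pattern clusters with archetypes A-D
#'
#' Archetypes follow the qualitative patterns seen when comparing
#' parental, short-term treated, and resistant cells: A = induced by
#' treatment and back to parental levels in resistance; B = suppressed in
#' resistant cells; C = suppressed by treatment and restored in
#' resistance; D = induced only in the resistant state.  Assignment uses
#' the sign pattern of the centroid deltas with tolerance `delta`.
#'
#' @param clusters a `pattern_clusters` object.
#' @param delta tolerance in standardized units (default 0.3) below which a
#'   delta counts as "unchanged".
#' @return The input with `archetype` filled in.
#' @export
label_archetypes <- function(clusters, delta = 0.3) {
  stopifnot(inherits(clusters, "pattern_clusters"))
  check_scalar(delta, "delta", lower = 0)
  cen <- clusters$centers
  clusters$archetype <- vapply(seq_len(nrow(cen)), function(i) {
    archetype_of(cen[i, "zT"] - cen[i, "zP"], cen[i, "zR"] - cen[i, "zP"],
                 delta)
  }, character(1))
  clusters
}

#' Hypergeometric over-representation of gene sets in a gene list
#'
#' One-sided upper-tail hypergeometric test per set (probability of an
#' overlap at least as large as observed, given the list and set sizes
#' within the universe), BH-adjusted across sets.  Sets are intersected
#' with the universe first.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param sets named list of gene sets.
#' @param universe character vector of all measured genes.
#' @return data.frame: set, overlap, set_size, list_size, universe_size,
#'   p_value, adj_p.
#' @export
overrepresentation <- function(gene_list, sets, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_list <- unique(toupper(gene_list))
  if (!all(gene_list %in% universe)) {
    stop("gene_list contains symbols outside the universe", call. = FALSE)
  }
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(toupper(sets[[nm]])), universe)
    ov <- length(intersect(gene_list, s))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(gene_list), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               list_size = length(gene_list),
               universe_size = length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out
}

# weighted Kolmogorov-Smirnov running sum; scores must be sorted decreasing
running_es <- function(in_set, scores, weight) {
  n_hit <- sum(in_set)
  n_miss <- length(in_set) - n_hit
  w <- abs(scores)^weight
  hit_inc <- ifelse(in_set, w / sum(w[in_set]), 0)
  miss_dec <- ifelse(in_set, 0, 1 / n_miss)
  rs <- cumsum(hit_inc - miss_dec)
  unname(rs[which.max(abs(rs))])
}

#' Preranked gene-set enrichment (running-sum) score
#'
#' Orders genes by decreasing score and walks the list accumulating
#' `|score|^weight` (normalized) at set members and subtracting
#' `1/(N - n)` at non-members; the enrichment score ES is the signed
#' maximum deviation of the running sum.  Significance comes from
#' gene-label permutation (re-drawing which genes form the set) with the
#' add-one correction, one-sided in the direction of the observed ES.
#'
#' @param scores named numeric vector of ranking scores (e.g. log2 fold
#'   changes), any order; names are gene symbols.
#' @param set character vector of set members; must intersect the list and
#'   not swallow it whole.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @param weight exponent on `|score|` for hit increments (1 = classic
#'   weighted statistic; 0 = equal weights).
#' @return A list of class `ranked_enrichment`: `es`, `p_value`, `n_perm`,
#'   `n_hits`, `seed`.
#' @export
ranked_enrichment <- function(scores, set, n_perm = 1000, seed = 1,
                              weight = 1) {
  if (is.null(names(scores)) || !all(is.finite(scores))) {
    stop("scores must be a named vector of finite values", call. = FALSE)
  }
  names(scores) <- toupper(names(scores))
  set <- unique(toupper(set))
  scores <- sort(scores, decreasing = TRUE)
  in_set <- names(scores) %in% set
  n_hit <- sum(in_set)
  if (n_hit == 0L) stop("set is disjoint from the ranked list", call. = FALSE)
  if (n_hit == length(scores)) {
    warning("set covers the entire ranked list; ES undefined, returning 0")
    return(structure(list(es = 0, p_value = 1, n_perm = 0, n_hits = n_hit,
                          seed = seed),
                     class = "ranked_enrichment"))
  }
  es <- running_es(in_set, scores, weight)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- logical(length(scores))
      lab[sample.int(length(scores), n_hit)] <- TRUE
      running_es(lab, scores, weight)
    }, numeric(1))
  })
  hits <- if (es >= 0) sum(perm >= es) else sum(perm <= es)
  structure(
    list(es = es, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm,
         n_hits = n_hit, seed = seed),
    class = "ranked_enrichment"
  )
}
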