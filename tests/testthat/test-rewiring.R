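profile_fixture <- function(seed = 3) {
  progs <- list(
    planted_program("A", sprintf("ARCA%03d", 1:100), fold_T_vs_P = 4),
    planted_program("B", sprintf("ARCB%03d", 1:100), fold_R_vs_P = 0.25),
    planted_program("C", sprintf("ARCC%03d", 1:100), fold_T_vs_P = 0.25),
    planted_program("D", sprintf("ARCD%03d", 1:100), fold_R_vs_P = 4)
  )
  sim <- simulate_counts(count_truth_config(n_genes = 500, programs = progs,
                                            seed = seed))
  e <- log_cpm(sim$counts, tmm_factors(sim$counts))
  genes <- sim$truth$gene_id[sim$truth$program != "none"]
  list(profiles = condition_profiles(e, sim$design, genes = genes),
       truth = substr(genes, 4, 4))
}

test_that("condition profiles are standardized triples", {
  e <- matrix(c(1, 1, 2, 2, 3, 3,
                5, 5, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("RISING", "CONST"), sprintf("S%d", 1:6)))
  d <- toy_design(colnames(e), rep(c("P", "T", "R"), each = 2))
  z <- condition_profiles(e, d)
  # means (1, 2, 3) standardize to (-1.2247, 0, 1.2247) with population SD
  expect_equal(unname(z["RISING", ]), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  expect_false("CONST" %in% rownames(z))
  expect_identical(attr(z, "excluded"), "CONST")
  expect_error(condition_profiles(e[, 1:4], d[1:4, ]), "P, T, R")
})

test_that("k-means recovers planted archetypes and labels them A-D", {
  skip_if_not_installed("mclust")
  fx <- profile_fixture()
  cl <- label_archetypes(kmeans_patterns(fx$profiles, k = 4, seed = 17))
  expect_gte(mclust::adjustedRandIndex(cl$cluster, fx$truth), 0.95)
  # each planted archetype's majority cluster carries the matching label
  for (arch in c("A", "B", "C", "D")) {
    maj <- as.integer(names(which.max(table(cl$cluster[fx$truth == arch]))))
    expect_identical(cl$archetype[maj], arch)
  }
})

test_that("k-means is deterministic and degenerate cases behave", {
  fx <- profile_fixture()
  c1 <- kmeans_patterns(fx$profiles, k = 4, seed = 21)
  c2 <- kmeans_patterns(fx$profiles, k = 4, seed = 21)
  expect_identical(c1$cluster, c2$cluster)

  one <- kmeans_patterns(fx$profiles, k = 1, seed = 1)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(fx$profiles)))

  dup <- fx$profiles[rep(1, 5), ]
  rownames(dup) <- paste0("DUP", 1:5)
  cl <- kmeans_patterns(rbind(fx$profiles, dup), k = 4, seed = 2)
  expect_length(unique(cl$cluster[paste0("DUP", 1:5)]), 1)
  expect_error(kmeans_patterns(fx$profiles[1:3, ], k = 5), "exceeds")
})

test_that("archetype labels follow the centroid sign patterns", {
  mk <- function(zp, zt, zr) {
    structure(list(cluster = c(g = 1L),
                   centers = matrix(c(zp, zt, zr), 1,
                                    dimnames = list(NULL, c("zP", "zT", "zR"))),
                   sizes = 1L, tot_withinss = 0,
                   archetype = "unassigned"),
              class = "pattern_clusters")
  }
  # up in T, back to parental in R
  expect_identical(label_archetypes(mk(0, 1, 0))$archetype, "A")
  # suppressed in resistant cells
  expect_identical(label_archetypes(mk(0.5, 0.5, -1))$archetype, "B")
  # down under treatment, restored in resistance
  expect_identical(label_archetypes(mk(0.5, -1, 0.5))$archetype, "C")
  # induced only in the resistant state
  expect_identical(label_archetypes(mk(0, 0, 1))$archetype, "D")
  expect_identical(label_archetypes(mk(0, 0, 0))$archetype, "unassigned")

  # labels are invariant to uniform rescaling of the profiles
  fx <- profile_fixture()
  a1 <- label_archetypes(kmeans_patterns(fx$profiles, k = 4, seed = 9))
  a2 <- label_archetypes(kmeans_patterns(fx$profiles * 2, k = 4, seed = 9))
  expect_setequal(a1$archetype, a2$archetype)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  uni <- sprintf("U%02d", 1:20)
  sets <- list(s5 = uni[1:5])
  # fully recovered 5-gene set in a 5-gene list: p = 1 / choose(20, 5)
  row <- overrepresentation(uni[1:5], sets, uni)
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row$overlap, 5)

  # list = universe: overlap = set size and p = 1
  row2 <- overrepresentation(uni, sets, uni)
  expect_equal(row2$overlap, 5)
  expect_equal(row2$p_value, 1)

  # zero overlap under the upper-tail convention: P(X >= 0) = 1
  row3 <- overrepresentation(uni[6:8], list(tiny = uni[1:2]), uni)
  expect_equal(row3$p_value, 1)

  # property: equality with the enumeration oracle over random draws
  set.seed(12)
  for (i in 1:25) {
    n_u <- sample(8:20, 1)
    u <- sprintf("R%02d", seq_len(n_u))
    s <- sample(u, sample(2:min(6, n_u), 1))
    l <- sample(u, sample(2:min(8, n_u), 1))
    got <- overrepresentation(l, list(s = s), u)
    expect_equal(got$p_value,
                 hyper_enum(length(intersect(s, l)), length(s), n_u,
                            length(l)),
                 tolerance = 1e-12)
  }
  expect_error(overrepresentation("A", list(s = "A"), character(0)), "universe")
})

test_that("running-sum enrichment matches hand-run walks", {
  scores <- setNames(seq(10, 1), paste0("G", 1:10))
  # single hit at the top of the list with equal weights: ES = 1 at the hit
  r <- ranked_enrichment(scores, "G1", n_perm = 100, seed = 1, weight = 0)
  expect_equal(r$es, 1)

  # hand-run running sum on a mixed set
  set_genes <- c("G2", "G5", "G9")
  in_set <- names(sort(scores, decreasing = TRUE)) %in% set_genes
  r2 <- ranked_enrichment(scores, set_genes, n_perm = 100, seed = 1)
  expect_equal(r2$es, es_hand(in_set, sort(scores, decreasing = TRUE)))

  # set covering the whole list is degenerate
  expect_warning(r3 <- ranked_enrichment(scores, names(scores)), "entire")
  expect_equal(r3$es, 0)
  expect_error(ranked_enrichment(scores, "ZZZ"), "disjoint")

  # reversing the ranking flips the ES sign (equal-weight statistic)
  set.seed(3)
  sc <- setNames(rnorm(12), paste0("H", 1:12))
  s <- paste0("H", c(1, 4, 7))
  up <- ranked_enrichment(sc, s, n_perm = 10, seed = 1, weight = 0)
  dn <- ranked_enrichment(-sc, s, n_perm = 10, seed = 1, weight = 0)
  expect_equal(up$es, -dn$es)
})

test_that("permutation p matches exhaustive label enumeration", {
  # N = 6, set of 2: all choose(6, 2) = 15 placements enumerable
  scores <- setNames(c(6, 5, 4, 3, 2, 1), paste0("G", 1:6))
  set_genes <- c("G1", "G2")
  obs <- ranked_enrichment(scores, set_genes, n_perm = 20000, seed = 4)
  combos <- combn(6, 2)
  es_all <- apply(combos, 2, function(idx) {
    lab <- logical(6); lab[idx] <- TRUE
    es_hand(lab, sort(scores, decreasing = TRUE))
  })
  exact <- mean(es_all >= obs$es)
  expect_lt(abs(obs$p_value - exact), 0.02)
})
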