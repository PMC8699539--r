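test_that("modified Z-scores match their closed forms and resist outliers", {
  x <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "G1"))
  z <- modified_z(x)
  expect_equal(unname(z[, 1]), c(-0.6745, 0, 0.6745))

  # a huge outlier barely moves the robust scores of the other points,
  # while plain z-scores shift wholesale
  set.seed(15)
  v <- rnorm(100)
  m0 <- matrix(v, dimnames = list(NULL, "G1"))
  m1 <- matrix(c(v, 1e6), dimnames = list(NULL, "G1"))
  z0 <- modified_z(m0)[, 1]
  z1 <- modified_z(m1)[1:100, 1]
  expect_lt(max(abs(z1 - z0)), 0.2)
  plain0 <- (v - mean(v)) / sd(v)
  plain1 <- ((c(v, 1e6) - mean(c(v, 1e6))) / sd(c(v, 1e6)))[1:100]
  expect_gt(max(abs(plain1 - plain0)), 1)

  expect_warning(zc <- modified_z(matrix(rep(7, 5), ncol = 1,
                                         dimnames = list(NULL, "G1"))),
                 "constant")
  expect_true(all(zc == 0))
  expect_error(modified_z(matrix(1:2, ncol = 1)), "3 patients")

  # mean-AD variant uses the 1.2533 consistency constant
  zm <- modified_z(x, method = "mean_ad")
  expect_equal(unname(zm[, 1]),
               (c(1, 2, 3) - 2) / (1.2533 * mean(abs(c(1, 2, 3) - 2))))
})

test_that("signature scores average modified Z over measured genes", {
  z <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("PT%02d", 1:10), c("GA", "GB", "GC")))
  expect_equal(as.numeric(avemz(z, "GA")), unname(z[, "GA"]))
  expect_warning(s <- avemz(z, c("GA", "GB", "NOPE")), "NOPE")
  expect_equal(as.numeric(s), unname(rowMeans(z[, c("GA", "GB")])))
  # gene order never matters
  expect_equal(avemz(z, c("GC", "GA")), avemz(z, c("GA", "GC")))
  expect_error(avemz(z, "NONE"), "no signature genes")

  zz <- matrix(0, 5, 2, dimnames = list(NULL, c("GA", "GB")))
  expect_true(all(avemz(zz, c("GA", "GB")) == 0))
})

test_that("stratification applies the mean + k*SD rule strictly", {
  scores <- c(rep(0, 98), 5, 5.1)
  names(scores) <- sprintf("PT%03d", 1:100)
  st <- stratify(scores, sd_multiplier = 2)
  thr <- mean(scores) + 2 * sqrt(mean((scores - mean(scores))^2))
  expect_equal(attr(st, "threshold"), thr)
  expect_setequal(st$patient_id[st$stratum == "high"], c("PT099", "PT100"))

  expect_warning(st0 <- stratify(rep(1, 10)), "zero score variance")
  expect_true(all(st0$stratum == "low"))

  # multiplier 0: strictly above the mean
  stm <- stratify(c(a = 1, b = 2, c = 3), sd_multiplier = 0)
  expect_identical(stm$stratum, c("low", "low", "high"))
})

test_that("Kaplan-Meier estimates match hand product-limit calculations", {
  co <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_estimate(co)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # censoring reduces the risk set without a step
  co2 <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km2 <- km_estimate(co2)
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$survival[ev$time == 1], 2 / 3)
  expect_equal(ev$survival[ev$time == 3], 0)

  # with no censoring, KM equals the empirical survival function
  set.seed(44)
  t3 <- rexp(40)
  km3 <- km_estimate(data.frame(time = t3, event = 1))
  expect_equal(km3$survival,
               sapply(sort(t3), function(u) mean(t3 > u)))

  all_cens <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(all_cens$survival == 1))
  expect_error(km_estimate(data.frame(time = c(-1, 2), event = c(1, 1))),
               "positive")
})

test_that("logrank test behaves on degenerate and separated cohorts", {
  # duplicated strata: no difference, chi-square 0, p = 1
  base <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
  dup <- rbind(cbind(base, stratum = "high"), cbind(base, stratum = "low"))
  lr <- logrank_test(dup)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  # label swap leaves the statistic unchanged
  swapped <- dup
  swapped$stratum <- ifelse(dup$stratum == "high", "low", "high")
  expect_equal(logrank_test(swapped)$chi_square, lr$chi_square)

  expect_error(logrank_test(data.frame(time = 1:4, event = 0,
                                       stratum = rep(c("a", "b"), 2))),
               "no events")
})

test_that("logrank tail ordering matches exhaustive permutation", {
  # 6 patients, all events, complete separation between groups
  times <- 1:6
  obs_chisq <- function(grp) {
    logrank_test(data.frame(time = times, event = 1, stratum = grp))$chi_square
  }
  observed <- obs_chisq(rep(c("a", "b"), each = 3))
  combos <- combn(6, 3)
  all_stats <- apply(combos, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    obs_chisq(g)
  })
  # the separated labelling is the most extreme of all 20 relabelings
  expect_equal(observed, max(all_stats), tolerance = 1e-9)
  perm_p <- mean(all_stats >= observed - 1e-9)
  expect_equal(perm_p, 2 / 20)  # the split and its mirror
})

test_that("subtype filtering recognizes receptor-status rules", {
  clin <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    er_status = c("+", "+", "-"),
    her2_status = c("-", "+", "-"),
    pr_status = c("+", "+", "-"),
    stringsAsFactors = FALSE
  )
  er <- subtype_filter(clin, "ER+/HER2-")
  expect_identical(er$patient_id, "P1")
  tn <- subtype_filter(clin, "TNBC")
  expect_identical(tn$patient_id, "P3")

  # mixed code spellings normalize; unknown codes are named in the error
  clin2 <- data.frame(er_status = c("pos", "NEG"), her2_status = c("0", "1"),
                      stringsAsFactors = FALSE)
  expect_identical(attr(subtype_filter(clin2, "ER+/HER2-"), "n_kept"), 1L)
  clin2$er_status[2] <- "maybe"
  expect_error(subtype_filter(clin2, "ER+/HER2-"), "maybe")

  clin3 <- data.frame(er_status = "-", her2_status = "+",
                      stringsAsFactors = FALSE)
  expect_warning(out <- subtype_filter(clin3, "ER+/HER2-"), "no patients")
  expect_equal(nrow(out), 0)
})
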