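test_that("feature matrix pivots panel betas and appends the aneuploidy score", {
  samples <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        cohort = c("NDBE", "NDBE", "HGD", "EAC"),
                        platform = "brush")
  meth <- expand.grid(region_id = c("r1", "r2"), strand = "+",
                      sample_id = samples$sample_id,
                      stringsAsFactors = FALSE)
  meth$total_reads <- 10L
  meth$meth_reads <- ifelse(meth$sample_id %in% c("s3", "s4"), 8L, 1L)
  # one zero-coverage cell to exercise mean imputation
  meth$total_reads[meth$sample_id == "s2" & meth$region_id == "r2"] <- 0L
  meth$meth_reads[meth$sample_id == "s2" & meth$region_id == "r2"] <- 0L
  panel <- data.frame(region_id = c("r1", "r2"), strand = "+")
  fm <- build_feature_matrix(meth, samples, panel)
  expect_equal(dim(fm$x), c(4, 2))
  expect_equal(fm$y, c(FALSE, FALSE, TRUE, TRUE))
  expect_false(anyNA(fm$x))
  # imputed value is the marker's observed mean
  expect_equal(fm$x["s2", "r2/+"], mean(c(0.1, 0.8, 0.8)))
  asr <- data.frame(sample_id = samples$sample_id, score = c(0, 1, 10, 20))
  fm2 <- build_feature_matrix(meth, samples, panel, aneuploidy = asr)
  expect_true(fm2$has_as)
  expect_equal(fm2$x$AS, c(0, 1, 10, 20))
  # samples outside the case/control cohorts are dropped
  samples$cohort[1] <- "LGD"
  expect_equal(nrow(build_feature_matrix(meth, samples, panel)$x), 3)
})

test_that("sensitivity at fixed specificity picks the smallest qualifying cutoff", {
  scores <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.25, 0.45, 0.6)
  labels <- c(rep(FALSE, 5), rep(TRUE, 3))
  out <- sensitivity_at_specificity(scores, labels, spec = 0.80)
  expect_equal(out[["threshold"]], 0.45)
  expect_equal(out[["specificity"]], 0.8)
  expect_equal(out[["sensitivity"]], 2 / 3)
  # perfectly separated scores
  sep <- sensitivity_at_specificity(c(1, 2, 3, 11, 12),
                                    c(FALSE, FALSE, FALSE, TRUE, TRUE), 0.9)
  expect_equal(sep[["sensitivity"]], 1)
  expect_equal(sep[["specificity"]], 1)
  # all-equal scores: no finite cutoff, all-negative fallback
  flat <- sensitivity_at_specificity(rep(0.5, 6),
                                     rep(c(TRUE, FALSE), 3), 0.8)
  expect_equal(flat[["sensitivity"]], 0)
  expect_equal(flat[["specificity"]], 1)
  # realized specificity always reaches the requested one
  set.seed(12)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    sc <- round(runif(n), 1)
    got <- sensitivity_at_specificity(sc, lab, spec = 0.75)
    expect_gte(got[["specificity"]], 0.75)
  }
})

test_that("DeLong variance matches explicit component enumeration", {
  set.seed(40)
  for (i in 1:20) {
    m <- sample(3:12, 1); n <- sample(3:12, 1)
    sc <- round(runif(m + n), 1)
    lab <- rep(c(TRUE, FALSE), c(m, n))
    got <- delong_variance(sc, lab)
    ref <- brute_delong_var(sc, lab)
    expect_equal(got$auc, ref$auc)
    expect_equal(got$var, ref$var)
  }
  expect_error(delong_variance(1:4, c(TRUE, FALSE, FALSE, FALSE)),
               "at least 2")
})

test_that("identical strata compare with z = 0 and p = 1", {
  sc <- c(1, 4, 2, 8, 3, 9)
  lab <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  cmp <- delong_compare_strata(sc, lab, sc, lab)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$auc_a, cmp$auc_b)
  # a real difference (with nonzero variance) moves the p-value off 1
  sc_b <- c(1, 4, 2, 8, 9, 3)
  cmp2 <- delong_compare_strata(sc, lab, sc_b, lab)
  expect_lt(cmp2$p_value, 1)
  expect_gt(abs(cmp2$z), 0)
})

test_that("cross-validated forest separates a strong marker and not noise", {
  set.seed(91)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- data.frame(m1 = ifelse(y, 0.8, 0.05) + rnorm(n, 0, 0.02),
                  m2 = runif(n))
  cv <- cv_random_forest(x, y, k = 5, seed = 3, ntree = 100)
  expect_s3_class(cv, "cv_result")
  expect_gt(cv$auc, 0.95)
  expect_equal(length(cv$out_of_fold_scores), n)
  expect_true(cv$auc_ci[1] <= cv$auc && cv$auc <= cv$auc_ci[2])
  # pure-noise features stay near chance
  xn <- data.frame(a = runif(n), b = runif(n))
  cvn <- cv_random_forest(xn, y, k = 5, seed = 3, ntree = 100)
  expect_lt(abs(cvn$auc - 0.5), 0.25)
  # class smaller than k reduces the fold count with a warning
  y_small <- c(rep(TRUE, 3), rep(FALSE, 37))
  expect_warning(cv2 <- cv_random_forest(x, y_small, k = 5, seed = 3,
                                         ntree = 50), "reducing k")
  expect_equal(cv2$fold_plan$k, 3)
})

test_that("4-marker enumeration covers every combination exactly once", {
  for (n in c(4, 5, 9, 28)) {
    panel <- paste0("m", seq_len(n))
    combos <- enumerate_4mdm(panel)
    expect_equal(nrow(combos), choose(n, 4))
    expect_false(anyDuplicated(combos[, 1:4]) > 0)
  }
  expect_equal(nrow(enumerate_4mdm(paste0("m", 1:5))), 5)
  expect_error(enumerate_4mdm(c("a", "b", "c")), "panel")
})

test_that("fitted 4-marker models report apparent performance per combination", {
  set.seed(61)
  n <- 30
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- data.frame(m1 = ifelse(y, 1, 0) + rnorm(n, 0, 0.05),
                  m2 = runif(n), m3 = runif(n), m4 = runif(n),
                  m5 = runif(n), AS = ifelse(y, 20, 1) + rnorm(n))
  res <- enumerate_4mdm(paste0("m", 1:5), x, y)
  expect_equal(nrow(res), choose(5, 4))
  # every combination containing the separating marker scores AUC 1
  has_m1 <- apply(res[, 1:4], 1, function(r) "m1" %in% r)
  expect_true(all(res$apparent_auc[has_m1] > 0.99))
  expect_true(all(res$apparent_auc >= 0 & res$apparent_auc <= 1))
  with_as <- enumerate_4mdm(paste0("m", 2:5), x, y, with_as = TRUE)
  expect_true(all(with_as$with_as))
  expect_true(all(with_as$apparent_auc > 0.99))  # AS separates alone
})

test_that("bootstrap optimism correction removes null-feature overfit", {
  set.seed(77)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  oc <- optimism_correct(x, y, B = 60, seed = 5)
  # pure-noise logistic fits look better than chance in-sample;
  # the correction pulls the AUC back down
  expect_gt(oc$apparent[["auc"]], 0.5)
  expect_gt(oc$optimism[["auc"]], 0)
  expect_lt(oc$corrected[["auc"]], oc$apparent[["auc"]])
  # deterministic given the seed
  oc2 <- optimism_correct(x, y, B = 60, seed = 5)
  expect_identical(oc, oc2)
  # constant feature: chance apparent AUC and zero optimism
  xc <- data.frame(a = rep(1, n))
  occ <- optimism_correct(xc, y, B = 10, seed = 2)
  expect_equal(occ$apparent[["auc"]], 0.5)
  expect_equal(occ$corrected[["auc"]], 0.5)
})

test_that("a single-resample optimism run is reproducible by hand", {
  set.seed(31)
  n <- 20
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  oc <- optimism_correct(x, y, B = 1, seed = 9)
  # replicate the RNG trace: the apparent fit consumes no randomness,
  # the single resample is the first sample.int draw after the seed
  set.seed(9)
  idx <- sample.int(n, replace = TRUE)
  fit <- suppressWarnings(glm(y[idx] ~ ., data = x[idx, ],
                              family = binomial()))
  boot_auc <- region_auc(predict(fit, x[idx, ]), y[idx])
  orig_auc <- region_auc(predict(fit, x), y)
  expect_equal(oc$optimism[["auc"]], boot_auc - orig_auc)
})

test_that("the rule-out threshold is the largest cutoff meeting sensitivity", {
  cases <- (1:10) / 10
  ctrl <- c(0.05, 0.15, 0.33)
  scores <- c(cases, ctrl)
  labels <- rep(c(TRUE, FALSE), c(10, 3))
  ro <- rule_out_threshold(scores, labels, sens = 0.90)
  expect_equal(ro$threshold, 0.2)
  expect_equal(ro$sensitivity, 0.9)
  expect_equal(ro$specificity, 2 / 3)
  # frozen cutoff applied to held-out scores
  ro2 <- rule_out_threshold(scores, labels, sens = 0.90,
                            holdout_scores = c(0.1, 0.25))
  expect_equal(ro2$holdout_sensitivity, 0.5)
  # disjoint groups: full sensitivity and specificity attainable
  ro3 <- rule_out_threshold(c(5, 6, 7, 1, 2), rep(c(TRUE, FALSE), c(3, 2)),
                            sens = 0.90)
  expect_equal(ro3$sensitivity, 1)
  expect_equal(ro3$specificity, 1)
  # relaxing the sensitivity requirement never lowers the threshold
  set.seed(3)
  sc <- round(runif(30), 2)
  lab <- c(TRUE, FALSE, runif(28) < 0.5)
  t_hi <- rule_out_threshold(sc, lab, sens = 0.95)$threshold
  t_lo <- rule_out_threshold(sc, lab, sens = 0.70)$threshold
  expect_gte(t_lo, t_hi)
})

test_that("screening projection reproduces the worked confusion matrix", {
  pr <- screening_projection(0.90, 0.56, 0.05, 10000)
  expect_equal(pr$confusion["test_neg", "control"], 5320)
  expect_equal(pr$confusion["test_neg", "case"], 50)
  expect_equal(pr$confusion["test_pos", "case"], 450)
  expect_equal(sum(pr$confusion), 10000)
  expect_equal(pr$npv_pct, 99)
  expect_equal(pr$npv, 5320 / 5370)
  expect_equal(pr$ppv, 450 / (450 + 4180))
  # a perfect test on any prevalence
  perfect <- screening_projection(1, 1, 0.2, 1000)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$ppv, 1)
  expect_error(screening_projection(1.2, 0.5, 0.1), "sens")
})
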