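test_that("overdispersed logistic regression is calibrated on binomial data", {
  set.seed(101)
  n <- 40
  is_case <- rep(c(TRUE, FALSE), each = n / 2)
  # null: identical binomial groups
  disp <- coefs <- numeric(30)
  for (i in 1:30) {
    tot <- sample(30:70, n, replace = TRUE)
    met <- rbinom(n, tot, 0.2)
    f <- fit_overdispersed_logistic(met, tot, is_case)
    disp[i] <- f$dispersion; coefs[i] <- f$coefficient
  }
  expect_lt(abs(mean(coefs)), 0.05)
  # Pearson chi^2 / df has sd ~ sqrt(2/df); the floor at 1 biases the
  # mean upward slightly but estimates must stay near 1
  expect_lt(mean(disp), 1 + 3 * sqrt(2 / (n - 2)))
  expect_true(all(disp >= 1))
})

test_that("overdispersion inflates the p-value under beta-binomial noise", {
  set.seed(202)
  n <- 40
  is_case <- rep(c(TRUE, FALSE), each = n / 2)
  tot <- sample(40:80, n, replace = TRUE)
  p_i <- rbeta(n, 2, 6)                    # strong extra-binomial noise
  met <- rbinom(n, tot, p_i)
  f <- fit_overdispersed_logistic(met, tot, is_case)
  expect_gt(f$dispersion, 1.5)
  # the naive binomial p uses the uninflated standard error
  naive <- summary(glm(cbind(met, tot - met) ~ is_case,
                       family = binomial()))$coefficients
  p_naive <- naive["is_caseTRUE", "Pr(>|z|)"]
  expect_gt(f$p_value, p_naive)
})

test_that("complete separation is flagged and capped, not fatal", {
  met <- c(rep(50, 4), rep(0, 4))
  tot <- rep(50, 8)
  is_case <- rep(c(TRUE, FALSE), each = 4)
  f <- fit_overdispersed_logistic(met, tot, is_case)
  expect_true(f$separated)
  expect_true(is.finite(f$p_value))
  expect_error(fit_overdispersed_logistic(10, 20, TRUE), "2 samples")
})

test_that("marker AUC equals brute-force pairwise comparison", {
  expect_equal(region_auc(c(0.9, 0.9, 0.1, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(region_auc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # 3 of 4 case/control pairs concordant
  expect_equal(region_auc(c(0.8, 0.3, 0.4, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # a tied pair contributes half: 3.5 / 4
  expect_equal(region_auc(c(0.8, 0.4, 0.4, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  set.seed(33)
  for (i in 1:40) {
    n <- sample(4:200, 1)
    is_case <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    vals <- sample(round(runif(n), 2), n)   # duplicates force tie handling
    expect_equal(region_auc(vals, is_case), brute_auc(vals, is_case))
  }
})

test_that("fold change floors the control denominator", {
  expect_equal(fold_change(30, 10), 3)
  expect_equal(fold_change(5, 0), 50)
  expect_equal(fold_change(10, 10), 1)
})

test_that("the filter cascade applies AUC, FC and noise rules in order", {
  metrics <- data.frame(
    region_id = paste0("r", 1:4), strand = "+",
    auc = c(0.55, 0.90, 0.90, 0.90),
    fc = c(10, 2.9, 10, 10),
    delta_m = 20, p_value = 0.001, dispersion = 1,
    control_mean_beta = c(0.01, 0.01, 0.01, 0.08))
  sel <- filter_cascade(metrics)
  expect_equal(sel$retained$region_id, "r3")
  expect_equal(unname(sel$stage_counts),
               c(4, 3, 2, 1))
  # survivors invariant to input order
  perm <- metrics[c(3, 1, 4, 2), ]
  expect_setequal(filter_cascade(perm)$retained_ids, sel$retained_ids)
})

test_that("cross-platform matching pairs loci within the base gap", {
  a <- data.frame(region_id = "a1", chrom = "chr1", start = 100, end = 200)
  expect_equal(match_cross_platform(a, a)$gap, 0)
  b_far <- data.frame(region_id = "b1", chrom = "chr1",
                      start = 701, end = 800)
  expect_equal(nrow(match_cross_platform(a, b_far, max_gap = 500)), 0)
  b_edge <- data.frame(region_id = "b1", chrom = "chr1",
                       start = 700, end = 800)
  m <- match_cross_platform(a, b_edge, max_gap = 500)
  expect_equal(m$gap, 500)                 # boundary inclusive
  # nearest eligible partner, ties to the smaller start
  b_multi <- data.frame(region_id = c("near", "tie_lo", "tie_hi"),
                        chrom = "chr1",
                        start = c(250, 300, 400), end = c(260, 310, 410))
  expect_equal(match_cross_platform(a, b_multi)$region_id_b, "near")
  a2 <- data.frame(region_id = "a2", chrom = "chr1", start = 340, end = 360)
  m2 <- match_cross_platform(a2, b_multi[-1, ])
  expect_equal(m2$region_id_b, "tie_lo")   # equal gap 30, smaller start
  # chromosomes never match across
  b_chr <- data.frame(region_id = "b", chrom = "chr2", start = 100, end = 200)
  expect_equal(nrow(match_cross_platform(a, b_chr)), 0)
})

test_that("read-level filter separates epiallele signal from background", {
  samples <- data.frame(sample_id = c("c1", "c2", "n1", "n2"),
                        cohort = c("EAC", "HGD", "NDBE", "NE"),
                        platform = "brush")
  fully <- data.frame(region_id = "r1", strand = "+",
                      sample_id = rep(c("c1", "c2", "n1", "n2"), each = 4),
                      cpgs_covered = 5L,
                      cpgs_methylated = rep(c(5L, 5L, 0L, 0L), each = 4))
  res <- read_level_filter(fully, samples)
  expect_true(res$pass)
  # half-methylated case reads never reach the 0.8 concordance bar
  half <- fully
  half$cpgs_methylated[half$sample_id %in% c("c1", "c2")] <- 2L
  half$cpgs_methylated[half$sample_id %in% c("n1", "n2")] <- 0L
  expect_false(read_level_filter(half, samples)$pass)
  # missing cohort reads give an indeterminate flag
  res_na <- read_level_filter(fully[fully$sample_id %in% c("c1", "c2"), ],
                              samples)
  expect_true(is.na(res_na$pass))
})

test_that("generator truth drives the read-level filter", {
  g <- generate_methylation(small_sim_config(seed = 55))
  brush <- g$samples[g$samples$platform == "brush", ]
  rl <- read_level_filter(
    g$read_patterns[g$read_patterns$sample_id %in% brush$sample_id], brush)
  planted <- rl$region_id %in% g$truth$truth_markers
  # planted regions pass (any strand), null regions essentially never do
  pass_by_region <- tapply(rl$pass & !is.na(rl$pass), rl$region_id, any)
  expect_gte(mean(pass_by_region[unique(rl$region_id) %in%
                                   g$truth$truth_markers]), 0.8)
  expect_lte(mean(rl$pass[!planted], na.rm = TRUE), 0.05)
})

test_that("panel supplementation appends the top-ranked remaining markers", {
  pool <- data.frame(region_id = sprintf("r%02d", 1:10),
                     strand = "+",
                     auc = c(0.9, 0.9, 0.8, 0.7, 0.95, 0.6, 0.85,
                             0.9, 0.5, 0.65),
                     fc = c(5, 9, 2, 1, 3, 8, 4, 9, 2, 7))
  passing <- c("r01/+", "r05/+")
  sel <- supplement_panel(passing, pool, target_n = 5)
  # oracle: sort the remaining pool by (auc desc, fc desc)
  rest <- pool[!paste0(pool$region_id, "/+") %in% passing, ]
  oracle <- paste0(rest$region_id[order(-rest$auc, -rest$fc)], "/+")[1:3]
  expect_equal(sel$retained_ids, c(passing, oracle))
  expect_equal(unname(sel$stage_counts["final"]), 5)
  # already at target: unchanged
  expect_equal(supplement_panel(passing, pool, 2)$retained_ids, passing)
  # pool exhaustion warns and returns what exists
  expect_warning(out <- supplement_panel(passing, pool, 50), "exhausted")
  expect_equal(length(out$retained_ids), 10)
})
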