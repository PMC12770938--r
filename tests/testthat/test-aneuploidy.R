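toy <- toy_genome()
euploid <- data.frame(arm_id = character(), cn = integer())

test_that("pooled reference averages normalized control fractions", {
  bins <- rbind(
    data.frame(sample_id = "n1", chrom = "chr1", start = c(0, 1e6),
               end = c(1e6, 2e6), read_count = c(100, 300)),
    data.frame(sample_id = "n2", chrom = "chr1", start = c(0, 1e6),
               end = c(1e6, 2e6), read_count = c(30, 10)))
  ref1 <- pooled_reference(bins, "n1")
  expect_equal(ref1$ref_fraction, c(0.25, 0.75))
  # two identical samples equal one
  twice <- rbind(bins[1:2, ], transform(bins[1:2, ], sample_id = "n2"))
  expect_equal(pooled_reference(twice, c("n1", "n2"))$ref_fraction,
               c(0.25, 0.75))
  # hand-computed mean of (0.25, 0.75) and (0.75, 0.25)
  ref <- pooled_reference(bins, c("n1", "n2"))
  expect_equal(ref$ref_fraction, c(0.5, 0.5))
  expect_error(pooled_reference(bins, "absent"), "no reference")
})

test_that("log2 ratios recover planted multiplicative changes", {
  base <- expected_bin_counts(toy, euploid, sample_id = "ref")
  ref <- pooled_reference(base, "ref")
  same <- log2_ratio(transform(base, sample_id = "s"), ref)
  expect_equal(same$log2_ratio, rep(0, nrow(same)))
  gain <- expected_bin_counts(toy, data.frame(arm_id = "3q", cn = 3),
                              tumor_fraction = 1, sample_id = "s")
  lr <- log2_ratio(gain, ref)
  on_arm <- lr$chrom == "chr3" & lr$start >= 30e6
  expect_equal(lr$log2_ratio[on_arm],
               rep(log2(1.5) - log2(sum(base$read_count) /
                                      sum(gain$read_count) *
                                      sum(gain$read_count) /
                                      sum(base$read_count)) -
                     log2(sum(gain$read_count) / sum(base$read_count)),
                   sum(on_arm)),
               tolerance = 1e-10)
  loss <- expected_bin_counts(toy, data.frame(arm_id = "2p", cn = 1),
                              tumor_fraction = 1, sample_id = "s")
  lr2 <- log2_ratio(loss, ref)
  lo <- lr2$chrom == "chr2" & lr2$start < 30e6
  # -1 up to the sample-total renormalization
  expect_equal(mean(lr2$log2_ratio[lo]),
               -1 - log2(sum(loss$read_count) / sum(base$read_count)),
               tolerance = 1e-10)
})

test_that("GC normalization flattens a planted smooth GC wave", {
  cfg <- small_sim_config(seed = 8, gc_bias = 2,
                          platforms = "brush", count_noise = "none",
                          n_per_cohort = c(NE = 0, NDBE = 2, LGD = 0,
                                           HGD = 0, EAC = 0))
  cfg$arm_event_prob[] <- 0
  cn <- generate_copy_number(cfg)
  one <- as.data.frame(cn$bin_counts[cn$bin_counts$sample_id ==
                                       cn$samples$sample_id[1], ])
  spread_before <- diff(range(tapply(one$read_count, one$chrom, mean)))
  norm <- gc_normalize(one)
  spread_after <- diff(range(tapply(norm$read_count, norm$chrom, mean)))
  expect_lt(spread_after, spread_before / 2)
  expect_equal(sum(norm$read_count), sum(one$read_count))
  # absent GC column: identity with a warning
  expect_warning(out <- gc_normalize(one[, 1:5]), "gc_fraction")
  expect_equal(out$read_count, one$read_count)
})

test_that("segmentation recovers noiseless breakpoints and drops small events", {
  flat <- data.frame(chrom = "chr1", start = (0:39) * 1e6,
                     end = (1:40) * 1e6, log2_ratio = 0)
  seg <- hmm_segment(flat)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "neutral")
  step <- flat
  step$log2_ratio[21:40] <- 0.58
  seg2 <- hmm_segment(step)
  expect_equal(seg2$start, c(0, 20e6))
  expect_equal(seg2$state, c("neutral", "gain"))
  # a 3-Mb gain is absorbed into the flanking neutral state
  small <- flat
  small$log2_ratio[10:12] <- 0.58
  seg3 <- hmm_segment(small, min_event_mb = 5)
  expect_equal(seg3$state, "neutral")
  expect_equal(nrow(seg3), 1)
  # but survives when the minimum event size allows it
  seg4 <- hmm_segment(small, min_event_mb = 3)
  expect_true("gain" %in% seg4$state)
  # single-bin chromosomes yield one neutral segment
  tiny <- data.frame(chrom = "chr9", start = 0, end = 1e6,
                     log2_ratio = 0.9)
  expect_equal(hmm_segment(tiny)$state, "neutral")
})

test_that("weighted median uses the lower-median rule", {
  expect_equal(weighted_median(5, 2), 5)
  expect_equal(weighted_median(c(2, 3), c(1, 1)), 2)
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 10)), 3)
  set.seed(6)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    v <- sample(1:20, n, replace = TRUE)
    w <- sample(1:80, n, replace = TRUE)
    if (sum(w) > 1000) w <- pmax(1, w %/% 4)
    expect_equal(weighted_median(v, w), brute_weighted_median(v, w))
  }
})

test_that("arm calls apply the ploidy +/- 0.5 rule on the weighted median", {
  seg <- function(cn) data.frame(chrom = "chr1", start = 0, end = 30e6,
                                 num_bins = 30, mean_log2 = log2(cn / 2),
                                 state = "neutral", total_cn = cn)
  expect_equal(arm_calls(seg(2.6), toy)$call[1], 1)
  expect_equal(arm_calls(seg(2.5), toy)$call[1], 1)   # boundary inclusive
  expect_equal(arm_calls(seg(2.4), toy)$call[1], 0)
  expect_equal(arm_calls(seg(1.5), toy)$call[1], -1)  # boundary inclusive
  # uncovered arms are neutral and flagged
  ac <- arm_calls(seg(2.6), toy)
  expect_false(ac$covered[ac$arm_id == "4q"])
  expect_equal(ac$call[ac$arm_id == "4q"], 0)
})

test_that("the aneuploidy score counts altered arms", {
  calls <- data.frame(arm_id = c("1p", "1q", "2p", "2q"),
                      call = c(1L, -1L, 0L, 1L))
  expect_equal(aneuploidy_score(calls), 3)
  expect_equal(aneuploidy_score(transform(calls, call = 0L)), 0)
  all44 <- data.frame(arm_id = hg19_genome()$arms$arm_id,
                      call = rep(c(1L, -1L), 22))
  expect_equal(aneuploidy_score(all44), 44)
})

test_that("recurrent alteration flags follow planted events", {
  hg <- hg19_genome()
  ref_profiles <- do.call(rbind, lapply(1:3, function(i)
    expected_bin_counts(hg, euploid, sample_id = paste0("n", i))))
  ref <- pooled_reference(ref_profiles, paste0("n", 1:3))
  # euploid sample: no flags
  lr0 <- log2_ratio(expected_bin_counts(hg, euploid, sample_id = "s"), ref)
  seg0 <- hmm_segment(lr0)
  fl0 <- recurrent_flags(arm_calls(seg0, hg), seg0, hg)
  expect_false(any(fl0))
  # planted 17p loss flips exactly its own flag (8q24 needs a gain)
  lr1 <- log2_ratio(expected_bin_counts(
    hg, data.frame(arm_id = "17p", cn = 1), 1, "s"), ref)
  seg1 <- hmm_segment(lr1)
  fl1 <- recurrent_flags(arm_calls(seg1, hg), seg1, hg)
  expect_true(fl1[["17p_loss"]])
  expect_false(any(fl1[names(fl1) != "17p_loss"]))
  # 8q gain lights the 8q24 window flag too
  lr2 <- log2_ratio(expected_bin_counts(
    hg, data.frame(arm_id = "8q", cn = 3), 1, "s"), ref)
  seg2 <- hmm_segment(lr2)
  fl2 <- recurrent_flags(arm_calls(seg2, hg), seg2, hg)
  expect_true(fl2[["8q24_gain"]])
  # flags whose arm or window the genome lacks are inapplicable (NA);
  # the toy genome has a 1q arm, so that flag stays defined
  segt <- data.frame(chrom = "chr1", start = 0, end = 30e6, num_bins = 30,
                     mean_log2 = 0, state = "neutral", total_cn = 2)
  flt <- recurrent_flags(arm_calls(segt, toy), segt, toy)
  expect_true(all(is.na(flt[c("17p_loss", "9p_loss", "12p_gain",
                              "20q_gain", "8q24_gain")])))
  expect_false(isTRUE(flt[["1q_gain"]]))
})

test_that("cohort scoring runs end to end on generated data", {
  cfg <- small_sim_config(seed = 19, platforms = "brush",
                          count_noise = "none")
  cn <- generate_copy_number(cfg)
  res <- score_aneuploidy(cn$bin_counts, cn$samples, cfg$genome)
  expect_s3_class(res, "aneuploidy_result")
  expect_setequal(res$sample_id, cn$samples$sample_id)
  expect_true(all(res$score >= 0 & res$score <= nrow(cfg$genome$arms)))
  # NE samples (euploid truth) score 0
  ne <- res$sample_id[res$cohort == "NE"]
  expect_true(all(res$score[res$sample_id %in% ne] == 0))
})
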