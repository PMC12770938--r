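#' Pooled control reference for bin counts
#'
#' Builds the per-bin copy-number reference from nondysplastic control
#' samples: each sample's bin counts are normalized to its own total and
#' the reference fraction of a bin is the mean of those normalized
#' counts. Bins with a zero reference fraction are flagged unusable.
#'
#' @param bin_counts bin count table (columns `sample_id`, `chrom`,
#'   `start`, `end`, `read_count`).
#' @param reference_samples sample ids of the control (NDBE) pool.
#' @return data.frame with `chrom`, `start`, `end`, `ref_fraction`,
#'   `usable`.
#' @export
pooled_reference <- function(bin_counts, reference_samples) {
  dt <- data.table::as.data.table(bin_counts)
  dt <- dt[sample_id %in% reference_samples]
  if (nrow(dt) == 0) stop("no reference (NDBE) samples in bin table")
  dt[, frac := read_count / sum(read_count), by = sample_id]
  ref <- dt[, .(ref_fraction = mean(frac)), by = .(chrom, start, end)]
  ref[, usable := ref_fraction > 0]
  as.data.frame(ref)
}

#' Per-bin log2 copy-number ratios against a pooled reference
#'
#' Normalizes the sample's bin counts to its total and takes
#' `log2(sample fraction / reference fraction)` for every usable bin.
#' Bins where the sample has zero counts or the reference is unusable
#' get `NA`.
#'
#' @param sample_bins one sample's rows of the bin table.
#' @param reference output of [pooled_reference()].
#' @return data.frame of bins with a `log2_ratio` column.
#' @export
log2_ratio <- function(sample_bins, reference) {
  sb <- as.data.frame(sample_bins)
  key_s <- paste(sb$chrom, sb$start)
  key_r <- paste(reference$chrom, reference$start)
  m <- match(key_s, key_r)
  if (anyNA(m)) stop("sample bins do not match reference bins")
  frac <- sb$read_count / sum(sb$read_count)
  ref <- reference$ref_fraction[m]
  ok <- reference$usable[m] & frac > 0
  sb$log2_ratio <- ifelse(ok, log2(frac / ref), NA_real_)
  sb
}

#' GC-content normalization of bin counts
#'
#' Divides each bin's count by the median count of its GC-content
#' decile, then rescales so the sample total is preserved. Removes
#' smooth GC-dependent coverage waves before ratio computation.
#'
#' @param sample_bins one sample's bins with a `gc_fraction` column.
#' @return the bins with adjusted `read_count`.
#' @export
gc_normalize <- function(sample_bins) {
  sb <- as.data.frame(sample_bins)
  if (is.null(sb$gc_fraction) || all(is.na(sb$gc_fraction))) {
    warning("no gc_fraction column; returning counts unchanged")
    return(sb)
  }
  br <- unique(quantile(sb$gc_fraction, probs = seq(0, 1, 0.1),
                        na.rm = TRUE))
  if (length(br) < 2) return(sb)   # single occupied decile: identity
  dec <- cut(sb$gc_fraction, breaks = br, include.lowest = TRUE)
  med <- tapply(sb$read_count, dec, median)
  med[med <= 0 | is.na(med)] <- 1
  adj <- sb$read_count / as.numeric(med[dec])
  total <- sum(sb$read_count)
  sb$read_count <- adj * total / sum(adj)
  sb
}

# Viterbi decoding of a 3-state (loss/neutral/gain) Gaussian HMM
.viterbi3 <- function(x, means, sd, self = 1 - 1e-6) {
  n <- length(x)
  k <- length(means)
  log_trans <- matrix(log((1 - self) / (k - 1)), k, k)
  diag(log_trans) <- log(self)
  emis <- vapply(means, function(m) dnorm(x, m, sd, log = TRUE),
                 numeric(n))
  if (n == 1) emis <- matrix(emis, nrow = 1)
  delta <- matrix(-Inf, n, k)
  back <- matrix(0L, n, k)
  delta[1, ] <- log(rep(1 / k, k)) + emis[1, ]
  for (t in seq_len(n)[-1]) {
    for (j in seq_len(k)) {
      cand <- delta[t - 1, ] + log_trans[, j]
      back[t, j] <- which.max(cand)
      delta[t, j] <- max(cand) + emis[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in rev(seq_len(n - 1))) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Segment log2 ratios with a three-state hidden Markov model
#'
#' Decodes a loss/neutral/gain state per bin by the most probable
#' (Viterbi) path of a Gaussian-emission HMM run per chromosome, with
#' fixed state means at one-copy loss/neutral/gain log2 ratios
#' (-0.58, 0, +0.58 at purity 1), a shared emission standard deviation
#' estimated robustly from bin-to-bin differences, and a sticky
#' transition matrix. Adjacent same-state bins merge into segments;
#' non-neutral segments shorter than `min_event_mb` megabases are
#' reassigned to neutral (large-scale events only) and re-merged.
#'
#' @param bins one sample's bins with `log2_ratio` (NA bins are
#'   skipped); must be ordered by position within chromosome.
#' @param min_event_mb minimum non-neutral event size in Mb (default 5).
#' @param ploidy sample ploidy used for the segment total copy number
#'   `ploidy * 2^mean_log2`.
#' @param means emission means for (loss, neutral, gain).
#' @return data.frame of segments: `chrom`, `start`, `end`, `num_bins`,
#'   `mean_log2`, `state` (`"loss"/"neutral"/"gain"`), `total_cn`.
#' @export
hmm_segment <- function(bins, min_event_mb = 5, ploidy = 2,
                        means = c(-0.58, 0, 0.58)) {
  b <- as.data.frame(bins)
  b <- b[!is.na(b$log2_ratio), , drop = FALSE]
  if (nrow(b) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), num_bins = integer(),
                      mean_log2 = numeric(), state = character(),
                      total_cn = numeric(), stringsAsFactors = FALSE))
  # shared emission sd, robust to level shifts at true breakpoints
  d <- unlist(tapply(b$log2_ratio, b$chrom,
                     function(v) if (length(v) > 1) diff(v) else NULL))
  sd_hat <- if (length(d) >= 2) mad(d) / sqrt(2) else 0
  sd_hat <- max(sd_hat, 0.05)
  state_names <- c("loss", "neutral", "gain")
  segs <- lapply(unique(b$chrom), function(ch) {
    bc <- b[b$chrom == ch, , drop = FALSE]
    bc <- bc[order(bc$start), , drop = FALSE]
    st <- if (nrow(bc) < 2) rep(2L, nrow(bc)) else
      .viterbi3(bc$log2_ratio, means, sd_hat)
    seg <- .collapse_segments(bc, st)
    seg <- .absorb_small_events(seg, min_event_mb * 1e6)
    seg
  })
  out <- do.call(rbind, segs)
  out$state <- state_names[out$state_code]
  out$state_code <- NULL
  out$total_cn <- ploidy * 2^out$mean_log2
  rownames(out) <- NULL
  out
}

.collapse_segments <- function(bc, st) {
  runs <- rle(st)
  stop_idx <- cumsum(runs$lengths)
  start_idx <- c(1L, head(stop_idx, -1) + 1L)
  data.frame(
    chrom = bc$chrom[1],
    start = bc$start[start_idx],
    end = bc$end[stop_idx],
    num_bins = runs$lengths,
    mean_log2 = vapply(seq_along(runs$lengths), function(i)
      mean(bc$log2_ratio[start_idx[i]:stop_idx[i]]), numeric(1)),
    state_code = runs$values,
    stringsAsFactors = FALSE
  )
}

.absorb_small_events <- function(seg, min_len) {
  repeat {
    small <- which(seg$state_code != 2L & (seg$end - seg$start) < min_len)
    if (length(small) == 0) break
    seg$state_code[small[1]] <- 2L
    seg <- .merge_adjacent(seg)
  }
  seg
}

.merge_adjacent <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  keep <- logical(nrow(seg))
  keep[1] <- TRUE
  out <- seg[0, ]
  cur <- seg[1, ]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg$state_code[i] == cur$state_code) {
      w <- c(cur$num_bins, seg$num_bins[i])
      cur$mean_log2 <- sum(c(cur$mean_log2, seg$mean_log2[i]) * w) / sum(w)
      cur$end <- seg$end[i]
      cur$num_bins <- sum(w)
    } else {
      out <- rbind(out, cur)
      cur <- seg[i, ]
    }
  }
  rbind(out, cur)
}

#' Weighted median (lower-median rule)
#'
#' The smallest value whose cumulative weight reaches half the total
#' weight. Used for segment-size weighted arm copy numbers.
#'
#' @param values numeric vector.
#' @param weights positive weights.
#' @return a single value from `values`.
#' @examples
#' weighted_median(c(2, 3), c(1, 1))      # 2
#' weighted_median(c(1, 2, 3), c(1, 1, 10))  # 3
#' @export
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), length(values) >= 1,
            all(weights > 0))
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  v[which(cumsum(w) >= sum(w) / 2)[1]]
}

#' Chromosome-arm gain/loss calls from segments
#'
#' Assigns each arm the segment-size weighted median total copy number
#' of its overlapping segments (overlap length is the weight) and calls
#' gain (+1) when that copy number is at least `ploidy + 0.5`, loss (-1)
#' when at most `ploidy - 0.5` (both boundaries inclusive), else
#' neutral (0). Arms with no overlapping segment are neutral with
#' `covered = FALSE`.
#'
#' @param segments segment data.frame from [hmm_segment()].
#' @param genome a [genome_model()].
#' @param ploidy cell ploidy (default 2).
#' @return data.frame with one row per arm: `arm_id`, `arm_cn`, `call`,
#'   `covered`.
#' @export
arm_calls <- function(segments, genome, ploidy = 2) {
  stopifnot(inherits(genome, "genome_model"))
  arms <- genome$arms
  out <- data.frame(arm_id = arms$arm_id, arm_cn = NA_real_,
                    call = 0L, covered = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    seg <- segments[segments$chrom == a$chrom, , drop = FALSE]
    if (nrow(seg) == 0) next
    ov <- pmin(seg$end, a$end) - pmax(seg$start, a$start)
    keep <- ov > 0
    if (!any(keep)) next
    cn <- weighted_median(seg$total_cn[keep], ov[keep])
    out$arm_cn[i] <- cn
    out$covered[i] <- TRUE
    out$call[i] <- if (cn >= ploidy + 0.5) 1L else
      if (cn <= ploidy - 0.5) -1L else 0L
  }
  out
}

#' Aneuploidy score
#'
#' Sum of the absolute values of the arm-level gain/loss calls: the
#' number of chromosome arms altered in the sample. On the 44 human
#' autosomal arms the score ranges from 0 to 44.
#'
#' @param calls arm-call data.frame from [arm_calls()] (needs `call`).
#' @return integer score.
#' @export
aneuploidy_score <- function(calls) {
  stopifnot("call" %in% names(calls),
            all(calls$call %in% c(-1L, 0L, 1L)))
  sum(abs(calls$call))
}

.recurrent_defs <- data.frame(
  flag = c("1q_gain", "9p_loss", "12p_gain", "17p_loss", "20q_gain"),
  arm_id = c("1q", "9p", "12p", "17p", "20q"),
  dir = c(1L, -1L, 1L, -1L, 1L),
  stringsAsFactors = FALSE
)

#' Recurrent esophageal-neoplasia alteration flags
#'
#' Flags the six alterations recurrently associated with HGD/esophageal
#' adenocarcinoma: 1q gain, 9p loss, 12p gain, 17p loss, 20q gain (from
#' arm calls) and 8q24 gain (any gain segment overlapping the genome's
#' 8q24 window). Flags whose arm or window is absent from the genome
#' model (e.g. toy genomes) are `NA` (inapplicable).
#'
#' @param calls arm-call data.frame from [arm_calls()].
#' @param segments segment data.frame from [hmm_segment()].
#' @param genome a [genome_model()].
#' @return named logical vector of the six flags.
#' @export
recurrent_flags <- function(calls, segments, genome) {
  flags <- setNames(rep(NA, 6),
                    c(.recurrent_defs$flag, "8q24_gain"))
  for (i in seq_len(nrow(.recurrent_defs))) {
    d <- .recurrent_defs[i, ]
    j <- match(d$arm_id, calls$arm_id)
    if (!is.na(j)) flags[d$flag] <- calls$call[j] == d$dir
  }
  w <- genome$windows
  if (!is.null(w) && "8q24" %in% w$name) {
    w <- w[w$name == "8q24", ]
    gain <- segments$state == "gain" & segments$chrom == w$chrom &
      segments$end > w$start & segments$start < w$end
    flags["8q24_gain"] <- any(gain)
  }
  flags
}

#' Aneuploidy scoring of a whole cohort
#'
#' Runs the full copy-number path for every sample: pooled NDBE
#' reference, optional GC normalization, per-bin log2 ratios, HMM
#' segmentation, arm calls, aneuploidy score and recurrent flags.
#'
#' @param bin_counts bin count table for all samples.
#' @param samples sample sheet (`sample_id`, `cohort`).
#' @param genome a [genome_model()].
#' @param min_event_mb minimum event size in Mb.
#' @param ploidy assumed ploidy.
#' @param gc_correct apply [gc_normalize()] per sample first.
#' @return an object of class `aneuploidy_result`: data.frame with one
#'   row per sample (`sample_id`, `cohort`, `score`, six flag columns)
#'   and per-sample `segments` and `arm_calls` kept as attributes.
#' @export
score_aneuploidy <- function(bin_counts, samples, genome,
                             min_event_mb = 5, ploidy = 2,
                             gc_correct = FALSE) {
  dt <- data.table::as.data.table(bin_counts)
  ref_ids <- samples$sample_id[samples$cohort == "NDBE"]
  if (gc_correct) {
    dt <- data.table::rbindlist(
      lapply(split(dt, by = "sample_id"), gc_normalize))
  }
  ref <- pooled_reference(dt, ref_ids)
  ids <- unique(dt$sample_id)
  seg_list <- list(); call_list <- list()
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sb <- dt[sample_id == ids[i]]
    lr <- log2_ratio(sb, ref)
    seg <- hmm_segment(lr, min_event_mb = min_event_mb, ploidy = ploidy)
    ac <- arm_calls(seg, genome, ploidy = ploidy)
    fl <- recurrent_flags(ac, seg, genome)
    seg_list[[ids[i]]] <- seg
    call_list[[ids[i]]] <- ac
    rows[[i]] <- data.frame(sample_id = ids[i],
                            cohort = samples$cohort[
                              match(ids[i], samples$sample_id)],
                            score = aneuploidy_score(ac),
                            t(as.matrix(fl)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "segments") <- seg_list
  attr(out, "arm_calls") <- call_list
  class(out) <- c("aneuploidy_result", "data.frame")
  out
}

#' @export
print.aneuploidy_result <- function(x, ...) {
  cat("Aneuploidy scores for", nrow(x), "samples\n")
  print(tapply(x$score, x$cohort, function(s)
    sprintf("n=%d, median AS=%.1f, any-event=%.0f%%",
            length(s), median(s), 100 * mean(s > 0))))
  invisible(x)
}
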