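#' Simulation configuration for synthetic Barrett's esophagus cohorts
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults
#' emulate a case-control validation cohort: per-cohort sample counts
#' matching a brush validation arm (37 NE, 42 NDBE, 23 LGD, 26 HGD,
#' 41 EAC), low beta-distributed background methylation in controls,
#' case hypermethylation carried by a near-fully-methylated epiallele
#' read population at planted marker regions, 2-10 fold dilution of that
#' signal in sponge samples, and grade-dependent chromosome-arm
#' copy-number events (28% of NDBE, 78% of HGD, 94% of EAC) attenuated
#' by a per-sample tumor fraction.
#'
#' @param seed integer seed; every generator call is reproducible given
#'   the seed.
#' @param n_per_cohort named counts for cohorts NE/NDBE/LGD/HGD/EAC.
#' @param n_regions number of candidate marker regions (each present on
#'   both strands).
#' @param n_true_markers number of planted hypermethylated markers
#'   (`<= n_regions`).
#' @param control_beta_mean mean of the background (control) methylation
#'   beta distribution.
#' @param control_beta_concentration concentration of the per-sample
#'   background beta draw (larger = less sample-to-sample noise).
#' @param case_epiallele_fraction mean fraction of reads drawn from the
#'   methylated epiallele in marker-positive case samples at planted
#'   markers, before any sponge dilution.
#' @param marker_positivity_range range of the per-marker probability
#'   that a given case sample expresses the marker at all; heterogeneous
#'   positivity is what keeps per-marker AUCs below 1.
#' @param lgd_attenuation multiplier applied to both positivity and
#'   epiallele fraction in LGD samples (intermediate grade).
#' @param sponge_dilution_range fold-range (low >= 1) of the per-patient
#'   sponge signal dilution, uniform on the fold scale.
#' @param read_depth_mean mean total reads per region per sample (split
#'   across the two strands); negative-binomial across cells.
#' @param read_depth_dispersion negative-binomial size for read depth.
#' @param mean_region_cpgs mean CpGs per region (negative-binomial,
#'   floored at 2; the upper tail exercises large-region handling).
#' @param arm_event_prob named per-cohort probability that a sample
#'   carries any arm-level copy-number event; NE is euploid.
#' @param extra_arm_mean named per-cohort Poisson mean for arm events
#'   beyond the first in event-positive samples (chromosomal instability
#'   grows with grade).
#' @param tumor_fraction_range named list of per-cohort (low, high)
#'   tumor-fraction ranges.
#' @param recurrent_arm_weight sampling weight for the recurrent
#'   alteration arms (1q, 9p, 12p, 17p, 20q, 8q) when present in the
#'   genome.
#' @param bin_depth_mean mean reads per full-width 1-Mb bin.
#' @param bin_count_dispersion negative-binomial size for bin counts.
#' @param gc_bias strength of a smooth GC-dependent count multiplier
#'   (0 disables; used to test GC normalization).
#' @param count_noise `"nbinom"` for overdispersed bin counts, `"none"`
#'   for exact expected counts (noise-free profiles).
#' @param platforms platforms to simulate; `c("brush", "sponge")` gives
#'   paired samples per patient sharing the same underlying case state.
#' @param genome a [genome_model()]; default [hg19_genome()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_cohort = c(NE = 37, NDBE = 42, LGD = 23,
                                        HGD = 26, EAC = 41),
                       n_regions = 300L,
                       n_true_markers = 30L,
                       control_beta_mean = 0.01,
                       control_beta_concentration = 20,
                       case_epiallele_fraction = 0.3,
                       marker_positivity_range = c(0.55, 0.9),
                       lgd_attenuation = 0.6,
                       sponge_dilution_range = c(2, 10),
                       read_depth_mean = 50,
                       read_depth_dispersion = 5,
                       mean_region_cpgs = 10,
                       arm_event_prob = c(NE = 0, NDBE = 0.28, LGD = 0.5,
                                          HGD = 0.78, EAC = 0.94),
                       extra_arm_mean = c(NE = 0, NDBE = 0.5, LGD = 1,
                                          HGD = 4, EAC = 8),
                       tumor_fraction_range = list(
                         NE = c(0, 0), NDBE = c(0.1, 0.3),
                         LGD = c(0.1, 0.5), HGD = c(0.2, 0.8),
                         EAC = c(0.3, 1.0)),
                       recurrent_arm_weight = 3,
                       bin_depth_mean = 100,
                       bin_count_dispersion = 30,
                       gc_bias = 0,
                       count_noise = c("nbinom", "none"),
                       platforms = c("brush", "sponge"),
                       genome = NULL) {
  count_noise <- match.arg(count_noise)
  if (is.null(genome)) genome <- hg19_genome()
  stopifnot(inherits(genome, "genome_model"))
  cfg <- list(seed = as.integer(seed),
              n_per_cohort = n_per_cohort,
              n_regions = as.integer(n_regions),
              n_true_markers = as.integer(n_true_markers),
              control_beta_mean = control_beta_mean,
              control_beta_concentration = control_beta_concentration,
              case_epiallele_fraction = case_epiallele_fraction,
              marker_positivity_range = marker_positivity_range,
              lgd_attenuation = lgd_attenuation,
              sponge_dilution_range = sponge_dilution_range,
              read_depth_mean = read_depth_mean,
              read_depth_dispersion = read_depth_dispersion,
              mean_region_cpgs = mean_region_cpgs,
              arm_event_prob = arm_event_prob,
              extra_arm_mean = extra_arm_mean,
              tumor_fraction_range = tumor_fraction_range,
              recurrent_arm_weight = recurrent_arm_weight,
              bin_depth_mean = bin_depth_mean,
              bin_count_dispersion = bin_count_dispersion,
              gc_bias = gc_bias,
              count_noise = count_noise,
              platforms = platforms,
              genome = genome)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$control_beta_mean, cfg$case_epiallele_fraction,
             cfg$marker_positivity_range, cfg$arm_event_prob,
             unlist(cfg$tumor_fraction_range))
  if (any(probs < 0 | probs > 1))
    stop("probabilities and fractions must lie in [0, 1]")
  if (cfg$n_true_markers > cfg$n_regions)
    stop("n_true_markers must be <= n_regions")
  if (cfg$sponge_dilution_range[1] < 1 ||
      diff(cfg$sponge_dilution_range) < 0)
    stop("sponge_dilution_range must satisfy 1 <= low <= high")
  if (diff(cfg$marker_positivity_range) < 0)
    stop("marker_positivity_range must be (low, high)")
  rng_ok <- vapply(cfg$tumor_fraction_range,
                   function(r) length(r) == 2 && r[1] <= r[2], logical(1))
  if (!all(rng_ok))
    stop("each tumor_fraction_range entry must be (low, high)")
  miss <- setdiff(cohort_levels, names(cfg$n_per_cohort))
  if (length(miss))
    stop("n_per_cohort missing cohorts: ", paste(miss, collapse = ", "))
  if (!all(cfg$platforms %in% c("brush", "sponge")))
    stop("platforms must be a subset of brush/sponge")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (seed ", x$seed, ")\n", sep = "")
  cat("  samples per cohort: ",
      paste(names(x$n_per_cohort), x$n_per_cohort, sep = "=",
            collapse = " "), "\n", sep = "")
  cat("  regions: ", x$n_regions, " (", x$n_true_markers,
      " planted markers), platforms: ",
      paste(x$platforms, collapse = "+"), "\n", sep = "")
  invisible(x)
}

# cohort-level covariate summaries used to draw realistic sample sheets
.covariate_params <- data.frame(
  cohort = cohort_levels,
  age_mean = c(48, 62, 69, 67, 69), age_sd = c(13, 11, 10, 8, 11),
  male_frac = c(0.59, 0.69, 0.74, 0.88, 0.85),
  bmi_mean = c(27, 29, 31, 30, 32), bmi_sd = c(7, 6, 7, 5, 6),
  smoker_frac = c(0.43, 0.43, 0.74, 0.73, 0.71),
  be_mean = c(NA, 4, 5, 4, 5), be_sd = c(NA, 4, 3, 3, 3),
  stringsAsFactors = FALSE
)

.draw_samples <- function(cfg) {
  n <- cfg$n_per_cohort[cohort_levels]
  n[is.na(n)] <- 0
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(sum(n))),
    cohort = rep(cohort_levels, times = n),
    stringsAsFactors = FALSE
  )
  if (nrow(patients) == 0) {
    return(data.frame(sample_id = character(), patient_id = character(),
                      cohort = character(), platform = character(),
                      age = numeric(), sex = character(), bmi = numeric(),
                      ever_smoker = logical(), be_length_cm = numeric(),
                      stringsAsFactors = FALSE))
  }
  cp <- .covariate_params[match(patients$cohort, .covariate_params$cohort), ]
  patients$age <- round(rnorm(nrow(patients), cp$age_mean, cp$age_sd))
  patients$sex <- ifelse(runif(nrow(patients)) < cp$male_frac, "M", "F")
  patients$bmi <- round(rnorm(nrow(patients), cp$bmi_mean, cp$bmi_sd), 1)
  patients$ever_smoker <- runif(nrow(patients)) < cp$smoker_frac
  be_raw <- rnorm(nrow(patients), ifelse(is.na(cp$be_mean), 0, cp$be_mean),
                  ifelse(is.na(cp$be_sd), 1, cp$be_sd))
  patients$be_length_cm <- ifelse(is.na(cp$be_mean), NA_real_,
                                  pmax(1, round(be_raw)))
  samples <- do.call(rbind, lapply(cfg$platforms, function(pf) {
    s <- patients
    s$platform <- pf
    s$sample_id <- paste(s$patient_id, pf, sep = "_")
    s
  }))
  rownames(samples) <- NULL
  samples[, c("sample_id", "patient_id", "cohort", "platform", "age",
              "sex", "bmi", "ever_smoker", "be_length_cm")]
}

.draw_regions <- function(cfg) {
  arms <- cfg$genome$arms
  len <- round(pmax(50, rnorm(cfg$n_regions, 156, 40)))
  w <- arms$end - arms$start
  arm_idx <- sample.int(nrow(arms), cfg$n_regions, replace = TRUE,
                        prob = w / sum(w))
  start <- arms$start[arm_idx] +
    floor(runif(cfg$n_regions) * pmax(1, w[arm_idx] - len))
  n_cpgs <- pmax(2L, rnbinom(cfg$n_regions, mu = cfg$mean_region_cpgs,
                             size = 2))
  ids <- sprintf("R%04d", seq_len(cfg$n_regions))
  one <- data.frame(region_id = ids, chrom = arms$chrom[arm_idx],
                    start = as.integer(start),
                    end = as.integer(start + len),
                    n_cpgs = as.integer(n_cpgs), stringsAsFactors = FALSE)
  both <- rbind(cbind(one, strand = "+", stringsAsFactors = FALSE),
                cbind(one, strand = "-", stringsAsFactors = FALSE))
  both[order(both$region_id, both$strand),
       c("region_id", "chrom", "start", "end", "strand", "n_cpgs")]
}

# beta draw parameterized by mean and concentration
.rbeta_mc <- function(n, mean, conc) {
  mean <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
  rbeta(n, mean * conc, (1 - mean) * conc)
}

.simulate_methylation <- function(cfg, samples, regions) {
  region_ids <- unique(regions$region_id)
  truth_markers <- sort(sample(region_ids, cfg$n_true_markers))
  # per-marker expression probability among case samples
  pos_prob <- runif(cfg$n_true_markers, cfg$marker_positivity_range[1],
                    cfg$marker_positivity_range[2])
  names(pos_prob) <- truth_markers
  # region-level background methylation mean, shared by both strands so
  # that strand-level control variability is correlated (hemimethylation
  # tends to co-occur); a mild strand multiplier adds independent noise
  mu_r <- .rbeta_mc(length(region_ids), cfg$control_beta_mean, 20)
  names(mu_r) <- region_ids

  patients <- unique(samples[, c("patient_id", "cohort")])
  dil <- setNames(runif(nrow(patients), cfg$sponge_dilution_range[1],
                        cfg$sponge_dilution_range[2]),
                  patients$patient_id)

  # patient x marker latent case state (shared across platforms)
  case_like <- patients$cohort %in% c("HGD", "EAC", "LGD")
  pm <- NULL
  if (any(case_like) && cfg$n_true_markers > 0) {
    pm <- data.table::CJ(patient_id = patients$patient_id[case_like],
                         region_id = truth_markers)
    pm[, cohort := patients$cohort[match(patient_id, patients$patient_id)]]
    att <- ifelse(pm$cohort == "LGD", cfg$lgd_attenuation, 1)
    p <- pos_prob[pm$region_id] * att
    pm[, positive := runif(.N) < p]
    f0 <- cfg$case_epiallele_fraction
    if (f0 > 0) {
      fr <- .rbeta_mc(nrow(pm), f0, 4) * att
    } else fr <- rep(0, nrow(pm))
    pm[, epiallele_fraction := ifelse(positive, fr, 0)]
  }

  cells <- data.table::CJ(sample_id = samples$sample_id,
                          region_id = region_ids,
                          strand = c("+", "-"), sorted = TRUE)
  si <- match(cells$sample_id, samples$sample_id)
  cells[, patient_id := samples$patient_id[si]]
  cells[, platform := samples$platform[si]]
  ri <- match(cells$region_id, regions$region_id[regions$strand == "+"])
  cells[, n_cpgs := regions$n_cpgs[regions$strand == "+"][ri]]
  # strand-level background: region mean with mild strand jitter
  strand_mult <- exp(rnorm(nrow(cells), 0, 0.2))
  mu_cell <- pmin(mu_r[cells$region_id] * strand_mult, 0.5)
  cells[, bg := .rbeta_mc(.N, mu_cell, cfg$control_beta_concentration)]
  cells[, f_eff := 0]
  if (!is.null(pm)) {
    key <- paste(cells$patient_id, cells$region_id)
    pkey <- paste(pm$patient_id, pm$region_id)
    mi <- match(key, pkey)
    hit <- !is.na(mi)
    cells$f_eff[hit] <- pm$epiallele_fraction[mi[hit]]
  }
  cells[platform == "sponge", f_eff := f_eff / dil[patient_id]]
  cells[, n_reads := rnbinom(.N, mu = cfg$read_depth_mean / 2,
                             size = cfg$read_depth_dispersion)]

  # expand to reads
  idx <- rep(seq_len(nrow(cells)), cells$n_reads)
  nr <- length(idx)
  is_epi <- runif(nr) < cells$f_eff[idx]
  covered <- pmax(1L, rbinom(nr, cells$n_cpgs[idx], 0.85))
  p_meth <- ifelse(is_epi, 0.95, cells$bg[idx])
  methylated <- rbinom(nr, covered, p_meth)
  reads <- data.table::data.table(
    region_id = cells$region_id[idx],
    sample_id = cells$sample_id[idx],
    strand = cells$strand[idx],
    cpgs_covered = covered,
    cpgs_methylated = methylated)

  agg <- reads[, .(meth_reads = sum(cpgs_methylated),
                   total_reads = sum(cpgs_covered)),
               by = .(region_id, sample_id, strand)]
  meth <- merge(cells[, .(region_id, sample_id, strand)], agg,
                by = c("region_id", "sample_id", "strand"), all.x = TRUE)
  meth[is.na(meth_reads), `:=`(meth_reads = 0L, total_reads = 0L)]
  meth[, beta := compute_beta(meth_reads, total_reads)]
  data.table::setorder(meth, region_id, strand, sample_id)
  data.table::setorder(reads, region_id, strand, sample_id)

  list(methylation = meth[], read_patterns = reads[],
       truth_markers = truth_markers,
       marker_positivity = data.frame(region_id = truth_markers,
                                      positivity = unname(pos_prob),
                                      stringsAsFactors = FALSE),
       patient_markers = if (is.null(pm)) NULL else as.data.frame(pm),
       sponge_dilution = data.frame(patient_id = patients$patient_id,
                                    fold = unname(dil),
                                    stringsAsFactors = FALSE))
}

.simulate_bins <- function(cfg, samples) {
  bins <- genome_bins(cfg$genome)
  nb <- nrow(bins)
  # smooth positional GC content, used only when gc_bias > 0
  bins$gc_fraction <- round(0.45 +
    0.05 * sin(seq_len(nb) / 40) + rnorm(nb, 0, 0.01), 4)

  patients <- unique(samples[, c("patient_id", "cohort")])
  arms <- cfg$genome$arms$arm_id
  wts <- rep(1, length(arms))
  rec <- c("1q", "9p", "12p", "17p", "20q", "8q")
  wts[arms %in% rec] <- cfg$recurrent_arm_weight

  events <- vector("list", nrow(patients))
  tf <- numeric(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    co <- patients$cohort[i]
    rng <- cfg$tumor_fraction_range[[co]]
    tf[i] <- runif(1, rng[1], rng[2])
    if (runif(1) < cfg$arm_event_prob[[co]]) {
      k <- min(1 + rpois(1, cfg$extra_arm_mean[[co]]), length(arms))
      ev_arms <- sample(arms, k, prob = wts)
      events[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                arm_id = ev_arms,
                                cn = sample(c(1L, 3L), k, replace = TRUE),
                                stringsAsFactors = FALSE)
    }
  }
  truth_events <- if (all(vapply(events, is.null, logical(1)))) {
    data.frame(patient_id = character(), arm_id = character(),
               cn = integer(), stringsAsFactors = FALSE)
  } else do.call(rbind, events[!vapply(events, is.null, logical(1))])

  dil_attr <- attr(samples, "sponge_dilution")
  if (is.null(dil_attr) && "sponge" %in% samples$platform)
    dil_attr <- setNames(runif(nrow(patients),
                               cfg$sponge_dilution_range[1],
                               cfg$sponge_dilution_range[2]),
                         patients$patient_id)
  base <- cfg$bin_depth_mean * (bins$end - bins$start) / cfg$genome$bin_size
  if (cfg$gc_bias > 0)
    base <- base * exp(cfg$gc_bias * (bins$gc_fraction - 0.45) / 0.05)

  out <- vector("list", nrow(samples))
  tf_rows <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    pid <- samples$patient_id[j]
    i <- match(pid, patients$patient_id)
    tf_j <- tf[i]
    if (samples$platform[j] == "sponge" && !is.null(dil_attr))
      tf_j <- tf_j / dil_attr[pid]
    mult <- rep(1, nb)
    ev <- events[[i]]
    if (!is.null(ev)) {
      for (r in seq_len(nrow(ev))) {
        sel <- bins$arm_id == ev$arm_id[r]
        mult[sel] <- mult[sel] * (1 + tf_j * (ev$cn[r] - 2) / 2)
      }
    }
    mu <- base * mult
    counts <- if (cfg$count_noise == "none") mu else
      rnbinom(nb, mu = mu, size = cfg$bin_count_dispersion)
    out[[j]] <- data.table::data.table(
      sample_id = samples$sample_id[j], chrom = bins$chrom,
      start = bins$start, end = bins$end, read_count = counts,
      gc_fraction = bins$gc_fraction)
    tf_rows[[j]] <- data.frame(sample_id = samples$sample_id[j],
                               tumor_fraction = tf_j,
                               stringsAsFactors = FALSE)
  }
  list(bin_counts = data.table::rbindlist(out),
       truth_arm_events = truth_events,
       tumor_fraction = do.call(rbind, tf_rows))
}

#' Expected bin counts for a fixed copy-number profile
#'
#' Builds the noise-free expected 1-Mb bin counts of a single sample
#' carrying a given set of arm-level events at a given tumor fraction:
#' an event with integer copy number `cn` multiplies the expected counts
#' of its arm by `1 + tf * (cn - 2) / 2`. Useful for constructing
#' controlled profiles (exact scoring, dilution series) without
#' sampling noise.
#'
#' @param genome a [genome_model()].
#' @param events data.frame with columns `arm_id` and `cn` (integer
#'   copy number, e.g. 1 or 3); may be empty for a euploid profile.
#' @param tumor_fraction fraction of aneuploid DNA in the sample.
#' @param sample_id sample id for the output rows.
#' @param depth expected reads per full-width bin.
#' @return a bin-count data.frame (`sample_id`, `chrom`, `start`, `end`,
#'   `read_count`).
#' @export
expected_bin_counts <- function(genome, events, tumor_fraction = 1,
                                sample_id = "S1", depth = 100) {
  stopifnot(inherits(genome, "genome_model"),
            tumor_fraction >= 0, tumor_fraction <= 1)
  bins <- genome_bins(genome)
  mu <- depth * (bins$end - bins$start) / genome$bin_size
  if (nrow(events) > 0) {
    bad <- setdiff(events$arm_id, genome$arms$arm_id)
    if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(events))) {
      sel <- bins$arm_id == events$arm_id[i]
      mu[sel] <- mu[sel] *
        (1 + tumor_fraction * (events$cn[i] - 2) / 2)
    }
  }
  data.frame(sample_id = sample_id, chrom = bins$chrom,
             start = bins$start, end = bins$end, read_count = mu,
             stringsAsFactors = FALSE)
}

#' Generate synthetic methylation data
#'
#' Draws the methylation half of a synthetic cohort: a region methylation
#' count table, a read-level CpG pattern table and the planted-marker
#' truth. Control samples carry only beta-distributed background
#' methylation; case samples mix in a near-fully-methylated epiallele
#' read population at the planted markers, diluted per patient on sponge
#' samples.
#'
#' @param cfg a [sim_config()].
#' @return list with `samples`, `regions`, `methylation`,
#'   `read_patterns` and `truth` (planted marker ids, per-patient marker
#'   states, sponge dilution folds).
#' @export
generate_methylation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- .draw_samples(cfg)
  regions <- .draw_regions(cfg)
  m <- .simulate_methylation(cfg, samples, regions)
  list(samples = samples, regions = regions,
       methylation = m$methylation, read_patterns = m$read_patterns,
       truth = m[c("truth_markers", "marker_positivity",
                   "patient_markers", "sponge_dilution")])
}

#' Generate synthetic shallow whole-genome bin counts
#'
#' Draws the copy-number half of a synthetic cohort: per-sample 1-Mb bin
#' read counts with planted arm-level events. An event with integer copy
#' number `cn` at tumor fraction `tf` multiplies the expected counts of
#' every bin on the arm by `1 + tf * (cn - 2) / 2`. NE samples are
#' euploid by construction.
#'
#' @param cfg a [sim_config()].
#' @return list with `samples`, `bin_counts` and `truth` (arm events and
#'   per-sample tumor fractions).
#' @export
generate_copy_number <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- .draw_samples(cfg)
  cn <- .simulate_bins(cfg, samples)
  list(samples = samples, bin_counts = cn$bin_counts,
       truth = cn[c("truth_arm_events", "tumor_fraction")])
}

#' Generate a full synthetic cohort
#'
#' Produces paired methylation and copy-number data for every sample.
#' Brush and sponge records of the same patient share the underlying
#' case state (which markers are expressed, which arms are altered); the
#' sponge signal is attenuated by the patient's dilution fold, for both
#' the epiallele fraction and the copy-number tumor fraction. Identical
#' seeds give identical cohorts.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `synthetic_cohort`: a list with `samples`,
#'   `regions`, `methylation`, `read_patterns`, `bin_counts`, `truth`
#'   and the generating `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- .draw_samples(cfg)
  regions <- .draw_regions(cfg)
  m <- .simulate_methylation(cfg, samples, regions)
  attr(samples, "sponge_dilution") <-
    setNames(m$sponge_dilution$fold, m$sponge_dilution$patient_id)
  cn <- .simulate_bins(cfg, samples)
  attr(samples, "sponge_dilution") <- NULL
  structure(list(
    samples = samples, regions = regions,
    methylation = m$methylation, read_patterns = m$read_patterns,
    bin_counts = cn$bin_counts,
    truth = list(markers = m$truth_markers,
                 marker_positivity = m$marker_positivity,
                 patient_markers = m$patient_markers,
                 sponge_dilution = m$sponge_dilution,
                 arm_events = cn$truth_arm_events,
                 tumor_fraction = cn$tumor_fraction),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$samples), "samples,",
      length(unique(x$regions$region_id)), "regions (",
      length(x$truth$markers), "planted markers ),",
      nrow(x$truth$arm_events), "planted arm events\n")
  print(table(cohort = x$samples$cohort, platform = x$samples$platform))
  invisible(x)
}

#' Write a synthetic cohort to TSV tables
#'
#' Writes the sample sheet, region BED, methylation and read-pattern
#' tables, bin counts and truth sidecars into a directory, in the
#' formats the analysis functions read back.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "samples.tsv"),
    regions = file.path(dir, "regions.bed"),
    methylation = file.path(dir, "methylation.tsv"),
    read_patterns = file.path(dir, "read_patterns.tsv"),
    bin_counts = file.path(dir, "bin_counts.tsv"),
    truth_markers = file.path(dir, "truth_markers.tsv"),
    truth_arm_events = file.path(dir, "truth_arm_events.tsv"),
    truth_tumor_fraction = file.path(dir, "truth_tumor_fraction.tsv"))
  data.table::fwrite(cohort$samples, paths["samples"], sep = "\t")
  write_regions_bed(cohort$regions, paths["regions"])
  cols <- c("region_id", "sample_id", "strand", "meth_reads", "total_reads")
  data.table::fwrite(cohort$methylation[, cols, with = FALSE],
                     paths["methylation"], sep = "\t")
  data.table::fwrite(cohort$read_patterns, paths["read_patterns"],
                     sep = "\t")
  data.table::fwrite(cohort$bin_counts, paths["bin_counts"], sep = "\t")
  data.table::fwrite(data.frame(region_id = cohort$truth$markers),
                     paths["truth_markers"], sep = "\t")
  data.table::fwrite(cohort$truth$arm_events, paths["truth_arm_events"],
                     sep = "\t")
  data.table::fwrite(cohort$truth$tumor_fraction,
                     paths["truth_tumor_fraction"], sep = "\t")
  invisible(paths)
}
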