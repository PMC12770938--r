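#' Overdispersed logistic regression for one marker region
#'
#' Fits a binomial logistic regression of the per-sample methylated /
#' total read counts on case status, then inflates the Wald standard
#' error by a quasi-likelihood dispersion estimated as the Pearson
#' statistic divided by the residual degrees of freedom (floored at 1).
#' Sequencing read counts of bisulfite data are overdispersed relative
#' to the binomial, so the naive binomial p-value would be anticonservative.
#'
#' @param meth_reads,total_reads per-sample counts (`total_reads > 0`).
#' @param is_case logical per sample (controls are the reference group).
#' @return list with `coefficient` (log-odds of methylation, case vs
#'   control), `se`, `p_value`, `dispersion` and `separated` (TRUE when
#'   the fit is degenerate and the statistic was capped).
#' @export
fit_overdispersed_logistic <- function(meth_reads, total_reads, is_case) {
  stopifnot(length(meth_reads) == length(total_reads),
            length(is_case) == length(meth_reads))
  keep <- total_reads > 0 & !is.na(meth_reads)
  meth_reads <- meth_reads[keep]
  total_reads <- total_reads[keep]
  is_case <- as.logical(is_case)[keep]
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("need at least 2 samples per group")
  fit <- suppressWarnings(
    glm(cbind(meth_reads, total_reads - meth_reads) ~ is_case,
        family = binomial()))
  co <- summary(fit)$coefficients
  beta <- co["is_caseTRUE", "Estimate"]
  se <- co["is_caseTRUE", "Std. Error"]
  df <- fit$df.residual
  disp <- if (df > 0)
    sum(residuals(fit, type = "pearson")^2) / df else 1
  disp <- max(disp, 1)
  separated <- !fit$converged || abs(beta) > 15 || se > 100
  z <- beta / (se * sqrt(disp))
  if (separated) z <- sign(z) * min(abs(z), 40)
  list(coefficient = beta, se = se * sqrt(disp),
       p_value = 2 * pnorm(-abs(z)), dispersion = disp,
       separated = separated)
}

#' Mann-Whitney AUC of a marker
#'
#' Area under the ROC curve computed as the Mann-Whitney probability
#' that a random case beta exceeds a random control beta, with ties
#' counted one half.
#'
#' @param values per-sample values (e.g. region beta).
#' @param is_case logical per sample.
#' @return AUC in \[0, 1\].
#' @export
region_auc <- function(values, is_case) {
  is_case <- as.logical(is_case)
  keep <- !is.na(values)
  values <- values[keep]; is_case <- is_case[keep]
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  r <- rank(values)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Case/control fold change of percent methylation
#'
#' `FC = case %M / control %M`, with the denominator floored (default
#' 0.1 percentage points) so that fully unmethylated control groups give
#' a large finite fold change rather than infinity.
#'
#' @param case_pct,control_pct group mean percent methylation (>= 0).
#' @param floor_pct denominator floor in percentage points.
#' @return fold-change ratio(s).
#' @export
fold_change <- function(case_pct, control_pct, floor_pct = 0.1) {
  stopifnot(all(case_pct >= 0, na.rm = TRUE),
            all(control_pct >= 0, na.rm = TRUE), floor_pct > 0)
  case_pct / pmax(control_pct, floor_pct)
}

#' Per-marker discovery metrics
#'
#' Computes, for each (region, strand) marker record, the discovery
#' statistics used for ranking and filtering: Mann-Whitney AUC of the
#' region beta, fold change of percent methylation (case mean %M over
#' control mean %M), the case-control difference in percentage points,
#' the overdispersed-logistic p-value and dispersion, and the control
#' mean beta (stochastic background level). Group %M means are
#' arithmetic means of per-sample beta times 100.
#'
#' @param methylation methylation table (see [read_methylation_tsv()] or
#'   a `synthetic_cohort`); must carry `beta`.
#' @param samples sample sheet with `sample_id` and `cohort`.
#' @param case_cohorts,control_cohorts cohort labels defining the
#'   contrast (defaults: HGD/EAC vs NDBE/NE).
#' @param floor_pct fold-change denominator floor, percentage points.
#' @return a `marker_metrics` data.frame with one row per
#'   (region_id, strand): columns `auc`, `fc`, `delta_m`, `p_value`,
#'   `dispersion`, `control_mean_beta`, `separated`.
#' @export
marker_metrics <- function(methylation, samples,
                           case_cohorts = c("HGD", "EAC"),
                           control_cohorts = c("NDBE", "NE"),
                           floor_pct = 0.1) {
  dt <- data.table::as.data.table(methylation)
  dt[, cohort := samples$cohort[match(sample_id, samples$sample_id)]]
  dt <- dt[cohort %in% c(case_cohorts, control_cohorts)]
  if (!"beta" %in% names(dt))
    dt[, beta := compute_beta(meth_reads, total_reads)]
  dt[, is_case := cohort %in% case_cohorts]
  res <- dt[, {
    ok <- !is.na(beta)
    odl <- fit_overdispersed_logistic(meth_reads[ok], total_reads[ok],
                                      is_case[ok])
    case_m <- mean(beta[ok & is_case]) * 100
    ctrl_m <- mean(beta[ok & !is_case]) * 100
    .(auc = region_auc(beta[ok], is_case[ok]),
      fc = fold_change(case_m, ctrl_m, floor_pct),
      delta_m = case_m - ctrl_m,
      p_value = odl$p_value,
      dispersion = odl$dispersion,
      control_mean_beta = ctrl_m / 100,
      separated = odl$separated)
  }, by = .(region_id, strand)]
  out <- as.data.frame(res)
  class(out) <- c("marker_metrics", "data.frame")
  out
}

#' @export
print.marker_metrics <- function(x, ...) {
  cat("Marker metrics for", nrow(x), "region x strand records\n")
  cat(sprintf("  AUC: median %.3f  [%.3f, %.3f]\n",
              median(x$auc), min(x$auc), max(x$auc)))
  NextMethod()
}

#' Discovery filter cascade
#'
#' Applies the discovery retention rules in order: AUC at least
#' `auc_min`, then fold change at least `fc_min`, then control
#' background (mean control beta) strictly below `noise_max`. The
#' surviving set is order-independent; the per-stage survivor counts are
#' defined by this order.
#'
#' @param metrics a [marker_metrics()] data.frame.
#' @param auc_min minimum AUC (default 0.60).
#' @param fc_min minimum fold change (default 3).
#' @param noise_max maximum control mean beta (default 0.05, i.e.
#'   markers with >= 5% background in nondysplastic controls are
#'   removed).
#' @return an object of class `panel_selection`: list with `retained`
#'   (data.frame of surviving records), `retained_ids` (ordered
#'   region/strand keys) and `stage_counts`.
#' @export
filter_cascade <- function(metrics, auc_min = 0.60, fc_min = 3,
                           noise_max = 0.05) {
  stopifnot(is.data.frame(metrics))
  n0 <- nrow(metrics)
  s1 <- metrics[!is.na(metrics$auc) & metrics$auc >= auc_min, ]
  s2 <- s1[!is.na(s1$fc) & s1$fc >= fc_min, ]
  s3 <- s2[!is.na(s2$control_mean_beta) &
             s2$control_mean_beta < noise_max, ]
  structure(list(
    retained = s3,
    retained_ids = paste(s3$region_id, s3$strand, sep = "/"),
    stage_counts = c(input = n0, auc = nrow(s1), fc = nrow(s2),
                     noise = nrow(s3))
  ), class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("Panel selection:", length(x$retained_ids), "records retained\n")
  cat("  stage counts:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = " -> "), "\n")
  invisible(x)
}

#' Match marker loci across two platforms
#'
#' Pairs each region in `set_a` with its nearest eligible region in
#' `set_b` on the same chromosome whose interval gap is at most
#' `max_gap` bases (overlapping intervals have gap 0; the bound is
#' inclusive). Ties on distance are broken toward the partner with the
#' smaller start. Cross-platform agreement within 500 bases is the
#' criterion for a locus discovered on one platform to be confirmed on
#' the other (CpG islands can extend up to a kilobase).
#'
#' @param set_a,set_b data.frames with `region_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param max_gap maximum gap in bases (default 500).
#' @return data.frame with columns `region_id_a`, `region_id_b`, `gap`;
#'   one row per matched `set_a` region.
#' @export
match_cross_platform <- function(set_a, set_b, max_gap = 500) {
  stopifnot(is.data.frame(set_a), is.data.frame(set_b))
  out <- vector("list", nrow(set_a))
  for (i in seq_len(nrow(set_a))) {
    a <- set_a[i, ]
    cand <- set_b[set_b$chrom == a$chrom, ]
    if (nrow(cand) == 0) next
    # half-open intervals: bases strictly between the two regions
    gap <- pmax(cand$start - a$end, a$start - cand$end, 0)
    eligible <- gap <= max_gap
    if (!any(eligible)) next
    cand <- cand[eligible, ]; gap <- gap[eligible]
    ord <- order(gap, cand$start)
    out[[i]] <- data.frame(region_id_a = a$region_id,
                           region_id_b = cand$region_id[ord[1]],
                           gap = gap[ord[1]], stringsAsFactors = FALSE)
  }
  hit <- !vapply(out, is.null, logical(1))
  if (!any(hit))
    return(data.frame(region_id_a = character(),
                      region_id_b = character(), gap = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[hit])
}

#' Read-level epiallele concordance filter
#'
#' Algorithmic replacement for visual read-pile curation: a marker
#' passes when case samples show a sufficient mean fraction of
#' concordantly methylated reads (per-read methylation >= `tau_hi`)
#' while control samples show almost no reads above `tau_lo`.
#'
#' @param read_patterns read-level table for one or more markers
#'   (columns `region_id`, `sample_id`, `strand`, `cpgs_covered`,
#'   `cpgs_methylated`).
#' @param samples sample sheet with `sample_id`, `cohort`.
#' @param case_cohorts,control_cohorts cohort labels for the contrast.
#' @param tau_hi,tau_lo per-read thresholds (defaults 0.8 and 0.2).
#' @param min_case_frac minimum mean concordant-read fraction across
#'   case samples (default 0.05).
#' @param max_ctrl_frac maximum mean fraction of control reads exceeding
#'   `tau_lo` (default 0.05).
#' @return data.frame with one row per (region_id, strand): mean case
#'   concordant fraction, mean control discordant fraction, and `pass`
#'   (NA when a required cohort has no reads).
#' @export
read_level_filter <- function(read_patterns, samples,
                              case_cohorts = c("HGD", "EAC"),
                              control_cohorts = c("NDBE", "NE"),
                              tau_hi = 0.8, tau_lo = 0.2,
                              min_case_frac = 0.05,
                              max_ctrl_frac = 0.05) {
  stopifnot(tau_lo >= 0, tau_hi <= 1, tau_lo <= tau_hi)
  dt <- data.table::as.data.table(read_patterns)
  dt[, cohort := samples$cohort[match(sample_id, samples$sample_id)]]
  dt <- dt[cohort %in% c(case_cohorts, control_cohorts)]
  dt[, is_case := cohort %in% case_cohorts]
  dt[, ratio := cpgs_methylated / cpgs_covered]
  # per-sample read fractions, then averaged across samples of the cohort
  per_sample <- dt[, .(hi = mean(ratio >= tau_hi),
                       above_lo = mean(ratio > tau_lo)),
                   by = .(region_id, strand, sample_id, is_case)]
  res <- per_sample[, .(
    case_concordant = if (any(is_case)) mean(hi[is_case]) else NA_real_,
    ctrl_discordant = if (any(!is_case)) mean(above_lo[!is_case])
                      else NA_real_
  ), by = .(region_id, strand)]
  res[, pass := ifelse(is.na(case_concordant) | is.na(ctrl_discordant),
                       NA,
                       case_concordant >= min_case_frac &
                         ctrl_discordant <= max_ctrl_frac)]
  as.data.frame(res)
}

#' Supplement a marker panel to a target size
#'
#' Appends to the passing set the highest-ranked pool records not
#' already present, ranked by AUC (descending) then fold change
#' (descending), until the panel reaches `target_n` records.
#'
#' @param passing character vector of retained record keys
#'   (`region_id/strand`), kept in order.
#' @param pool a [marker_metrics()] data.frame to draw supplements from.
#' @param target_n final panel size (>= `length(passing)`).
#' @return a `panel_selection` whose `retained_ids` has length
#'   `target_n` (or fewer, with a warning, when the pool is exhausted).
#' @export
supplement_panel <- function(passing, pool, target_n) {
  stopifnot(target_n >= length(passing))
  pool_ids <- paste(pool$region_id, pool$strand, sep = "/")
  avail <- !(pool_ids %in% passing)
  ord <- order(-pool$auc[avail], -pool$fc[avail])
  add_ids <- pool_ids[avail][ord]
  n_add <- target_n - length(passing)
  short <- n_add > length(add_ids)
  if (short) {
    warning("pool exhausted: panel has ",
            length(passing) + length(add_ids), " of ", target_n,
            " requested records")
    n_add <- length(add_ids)
  }
  structure(list(
    retained = NULL,
    retained_ids = c(passing, add_ids[seq_len(n_add)]),
    stage_counts = c(passing = length(passing), supplemented = n_add,
                     final = length(passing) + n_add),
    pool_exhausted = short
  ), class = "panel_selection")
}
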