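#' Control-variability coefficient of determination for one marker
#'
#' Regresses the methylated read count on the total read count across
#' nondysplastic (NDBE) control samples and reports the coefficient of
#' determination. A marker whose background methylation is stable
#' tracks sequencing depth predictably (high R^2); stochastic, noisy
#' background breaks that relationship (low R^2). Markers with fewer
#' than 30 CpGs use a straight-line fit; larger markers use a penalized
#' thin-plate spline with GCV smoothing, since their count relationship
#' is less well approximated by a line.
#'
#' @param total_reads,meth_reads per-control-sample counts.
#' @param n_cpgs CpG count of the marker (selects the model).
#' @return list with `r2`, `model_kind` (`"line"` or `"smooth"`), `n`
#'   and `indeterminate` (TRUE when fewer than 3 usable controls).
#' @export
control_r2 <- function(total_reads, meth_reads, n_cpgs) {
  keep <- !is.na(total_reads) & !is.na(meth_reads) & total_reads > 0
  x <- total_reads[keep]; y <- meth_reads[keep]
  kind <- if (n_cpgs < 30) "line" else "smooth"
  if (length(x) < 3)
    return(list(r2 = NA_real_, model_kind = kind, n = length(x),
                indeterminate = TRUE))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    return(list(r2 = 1, model_kind = kind, n = length(x),
                indeterminate = FALSE))
  if (kind == "line") {
    fit <- stats::lm(y ~ x)
    res <- residuals(fit)
  } else {
    k <- max(3, min(10, floor(length(x) / 2)))
    fit <- mgcv::gam(y ~ s(x, k = k), method = "GCV.Cp")
    res <- residuals(fit)
  }
  list(r2 = max(0, 1 - sum(res^2) / ss_tot), model_kind = kind,
       n = length(x), indeterminate = FALSE)
}

#' Control-variability fits for a marker panel
#'
#' Runs [control_r2()] for every (region, strand) record restricted to
#' the control cohort.
#'
#' @param methylation methylation count table.
#' @param samples sample sheet.
#' @param regions region definitions carrying `n_cpgs`.
#' @param panel_ids optional `region_id/strand` keys restricting the
#'   panel.
#' @param control_cohort cohort used for the fits (default `"NDBE"`).
#' @return data.frame with `region_id`, `strand`, `n_cpgs`, `r2`,
#'   `model_kind`, `indeterminate`.
#' @export
control_fit_panel <- function(methylation, samples, regions,
                              panel_ids = NULL,
                              control_cohort = "NDBE") {
  dt <- data.table::as.data.table(methylation)
  ctrl <- samples$sample_id[samples$cohort %in% control_cohort]
  dt <- dt[sample_id %in% ctrl]
  if (!is.null(panel_ids))
    dt <- dt[paste(region_id, strand, sep = "/") %in% panel_ids]
  key <- paste(regions$region_id, regions$strand)
  res <- dt[, {
    nc <- regions$n_cpgs[match(paste(region_id[1], strand[1]), key)]
    f <- control_r2(total_reads, meth_reads, nc)
    .(n_cpgs = nc, r2 = f$r2, model_kind = f$model_kind,
      indeterminate = f$indeterminate)
  }, by = .(region_id, strand)]
  as.data.frame(res)
}

#' Retain markers at or above a coefficient-of-determination percentile
#'
#' Keeps the top `100 - pct` percent of fits by R^2: the cutoff is the
#' value at rank `floor(pct/100 * n) + 1` of the sorted R^2
#' (nearest-rank), and retention at the cutoff value is inclusive, so
#' ties at the boundary are all kept.
#'
#' @param fits data.frame from [control_fit_panel()] (needs `r2`).
#' @param pct retention percentile (default 80: keep the top 20%).
#' @return the retained rows of `fits`.
#' @export
percentile_filter <- function(fits, pct = 80) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1, pct > 0, pct <= 100)
  r2 <- fits$r2
  usable <- !is.na(r2)
  n <- sum(usable)
  if (n == 0) stop("no usable fits")
  cutoff <- sort(r2[usable])[min(n, floor(pct / 100 * n) + 1)]
  fits[usable & r2 >= cutoff, , drop = FALSE]
}

#' Resolve forward/reverse strand records to one marker per region
#'
#' When both strands of a region survive filtering, the strand with the
#' larger coefficient of determination is kept, to maintain independence
#' across markers; ties keep the plus strand.
#'
#' @param fits data.frame with `region_id`, `strand`, `r2`.
#' @return one row per `region_id`.
#' @export
resolve_strands <- function(fits) {
  stopifnot(is.data.frame(fits))
  if (nrow(fits) == 0) return(fits)
  # order: higher r2 first; on ties, plus strand first
  ord <- order(fits$region_id, -fits$r2,
               match(fits$strand, c("+", "-")))
  sorted <- fits[ord, , drop = FALSE]
  sorted[!duplicated(sorted$region_id), , drop = FALSE]
}

#' Validation-phase marker reduction
#'
#' Full control-variability filter: fit the coefficient of
#' determination per strand record on the control cohort, retain records
#' at or above the percentile cutoff, and resolve strands.
#'
#' @inheritParams control_fit_panel
#' @param pct retention percentile.
#' @return list with `fits` (all fits), `retained` (post-percentile) and
#'   `panel` (one row per region after strand resolution).
#' @export
reduce_marker_panel <- function(methylation, samples, regions,
                                panel_ids = NULL, pct = 80,
                                control_cohort = "NDBE") {
  fits <- control_fit_panel(methylation, samples, regions, panel_ids,
                            control_cohort)
  retained <- percentile_filter(fits, pct)
  list(fits = fits, retained = retained,
       panel = resolve_strands(retained))
}
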