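#' Build a sample-by-marker feature matrix
#'
#' Pivots region beta values into a samples x markers matrix for the
#' requested panel (after strand resolution), optionally appending the
#' aneuploidy score as an extra column, and attaches case/control
#' labels.
#'
#' @param methylation methylation table with `beta`.
#' @param samples sample sheet.
#' @param panel data.frame with `region_id` and `strand` (one row per
#'   marker, e.g. the `panel` element of [reduce_marker_panel()]).
#' @param aneuploidy optional [score_aneuploidy()] result; its `score`
#'   is appended as column `AS`.
#' @param case_cohorts,control_cohorts cohort labels; samples in
#'   neither group are dropped.
#' @return list with `x` (data.frame of features), `y` (logical case
#'   labels), `sample_id`, `strata` (covariate data.frame) and `has_as`.
#' @export
build_feature_matrix <- function(methylation, samples, panel,
                                 aneuploidy = NULL,
                                 case_cohorts = c("HGD", "EAC"),
                                 control_cohorts = "NDBE") {
  dt <- data.table::as.data.table(methylation)
  keys <- paste(panel$region_id, panel$strand, sep = "/")
  dt <- dt[paste(region_id, strand, sep = "/") %in% keys]
  if (!"beta" %in% names(dt))
    dt[, beta := compute_beta(meth_reads, total_reads)]
  wide <- data.table::dcast(dt, sample_id ~ region_id + strand,
                            value.var = "beta", sep = "/")
  keep <- samples$cohort %in% c(case_cohorts, control_cohorts)
  info <- samples[keep, , drop = FALSE]
  wide <- wide[match(info$sample_id, wide$sample_id), ]
  x <- as.data.frame(wide[, -1])
  rownames(x) <- info$sample_id
  # zero-coverage markers: impute the marker's observed mean
  for (j in seq_along(x)) {
    miss <- is.na(x[[j]])
    if (any(miss)) x[[j]][miss] <- mean(x[[j]], na.rm = TRUE)
  }
  has_as <- FALSE
  if (!is.null(aneuploidy)) {
    x$AS <- aneuploidy$score[match(info$sample_id,
                                   aneuploidy$sample_id)]
    if (anyNA(x$AS)) stop("aneuploidy scores missing for some samples")
    has_as <- TRUE
  }
  cov_cols <- intersect(c("age", "sex", "bmi", "ever_smoker",
                          "be_length_cm"), names(info))
  list(x = x, y = info$cohort %in% case_cohorts,
       sample_id = info$sample_id,
       strata = info[, cov_cols, drop = FALSE], has_as = has_as)
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Cross-validated random-forest classification
#'
#' Fits a random forest (500 trees) under stratified k-fold
#' cross-validation and evaluates the pooled out-of-fold case
#' probabilities: AUC with a DeLong 95% confidence interval and
#' sensitivity at a fixed specificity.
#'
#' @param x data.frame of features (samples x markers, optionally
#'   with an `AS` column).
#' @param y logical case labels.
#' @param k folds (default 5; reduced with a warning if a class is
#'   smaller than `k`).
#' @param repeats number of CV repeats; per-sample scores are averaged
#'   across repeats.
#' @param seed RNG seed for fold assignment and forest fitting.
#' @param spec specificity at which sensitivity is reported.
#' @param ntree trees per forest.
#' @return an object of class `cv_result`: list with
#'   `out_of_fold_scores`, `auc`, `auc_ci`, `sens_at_spec`, `threshold`
#'   and `fold_plan`.
#' @export
cv_random_forest <- function(x, y, k = 5, repeats = 1, seed = 1,
                             spec = 0.80, ntree = 500) {
  stopifnot(nrow(x) == length(y), is.logical(y))
  n_min <- min(table(y))
  if (n_min < k) {
    warning("smallest class has ", n_min, " samples; reducing k")
    k <- max(2, n_min)
  }
  set.seed(seed)
  scores <- matrix(NA_real_, nrow(x), repeats)
  yf <- factor(y, levels = c(FALSE, TRUE))
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(y, k)
    for (f in seq_len(k)) {
      test <- fold == f
      rf <- randomForest::randomForest(x[!test, , drop = FALSE],
                                       yf[!test], ntree = ntree)
      scores[test, r] <- predict(rf, x[test, , drop = FALSE],
                                 type = "prob")[, "TRUE"]
    }
  }
  s <- rowMeans(scores)
  auc <- region_auc(s, y)
  ci <- delong_ci(s, y)
  ss <- sensitivity_at_specificity(s, y, spec = spec)
  structure(list(out_of_fold_scores = s, auc = auc, auc_ci = ci,
                 sens_at_spec = ss[["sensitivity"]],
                 threshold = ss[["threshold"]],
                 fold_plan = list(seed = seed, k = k, repeats = repeats)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validated AUC %.2f (%.2f-%.2f), sensitivity %.0f%% at threshold %.3f\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], 100 * x$sens_at_spec, x$threshold))
  cat("  folds:", x$fold_plan$k, "x", x$fold_plan$repeats,
      "repeat(s), seed", x$fold_plan$seed, "\n")
  invisible(x)
}

#' Sensitivity at a fixed specificity
#'
#' Chooses the smallest positive-call cutoff (score >= threshold is
#' positive, ties positive) whose control specificity reaches `spec`,
#' and reports the case sensitivity there. When no finite cutoff
#' satisfies the constraint (e.g. all scores equal), the all-negative
#' cutoff is returned with sensitivity 0.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels logical case labels.
#' @param spec required specificity among controls (default 0.80).
#' @return named vector `c(sensitivity =, threshold =, specificity =)`.
#' @export
sensitivity_at_specificity <- function(scores, labels, spec = 0.80) {
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  ctrl <- scores[!labels]; cases <- scores[labels]
  cand <- sort(unique(scores))
  ok <- vapply(cand, function(t) mean(ctrl < t) >= spec, logical(1))
  t <- if (any(ok)) cand[which(ok)[1]] else Inf
  c(sensitivity = mean(cases >= t), threshold = t,
    specificity = if (is.finite(t)) mean(ctrl < t) else 1)
}

# DeLong structural components: V10 per case, V01 per control
.delong_components <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong variance of the Mann-Whitney AUC
#'
#' @param scores numeric scores.
#' @param labels logical case labels.
#' @return list with `auc` and `var`.
#' @export
delong_variance <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least 2 cases and 2 controls")
  cc <- .delong_components(scores, labels)
  list(auc = cc$auc,
       var = var(cc$v10) / cc$m + var(cc$v01) / cc$n)
}

#' DeLong 95% confidence interval for an AUC
#'
#' @inheritParams delong_variance
#' @param level confidence level.
#' @return length-2 vector (low, high), clamped to \[0, 1\].
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  dv <- delong_variance(scores, labels)
  z <- qnorm(1 - (1 - level) / 2)
  pmin(pmax(dv$auc + c(-1, 1) * z * sqrt(dv$var), 0), 1)
}

#' Compare AUCs between two independent strata (DeLong)
#'
#' Computes the AUC and its DeLong variance in each stratum (e.g. male
#' vs female patients) and tests the difference with a two-sided z-test,
#' treating the strata as independent samples (they partition the
#' patients), so the variances add.
#'
#' @param scores_a,labels_a scores and logical labels in stratum A.
#' @param scores_b,labels_b scores and logical labels in stratum B.
#' @return list with `auc_a`, `auc_b`, `ci_a`, `ci_b`, `z`, `p_value`.
#' @export
delong_compare_strata <- function(scores_a, labels_a,
                                  scores_b, labels_b) {
  if (sum(labels_a) < 2 || sum(!labels_a) < 2 ||
      sum(labels_b) < 2 || sum(!labels_b) < 2)
    stop("each stratum needs at least 2 cases and 2 controls")
  da <- delong_variance(scores_a, labels_a)
  db <- delong_variance(scores_b, labels_b)
  se <- sqrt(da$var + db$var)
  z <- if (se == 0) 0 else (da$auc - db$auc) / se
  list(auc_a = da$auc, auc_b = db$auc,
       ci_a = delong_ci(scores_a, labels_a),
       ci_b = delong_ci(scores_b, labels_b),
       z = z, p_value = 2 * pnorm(-abs(z)))
}

# logistic fit on a feature subset; ridge fallback under separation
.fit_logistic <- function(x, y) {
  xm <- as.matrix(x)
  fit <- suppressWarnings(
    glm.fit(cbind(1, xm), y, family = binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients[-1]) > 15,
                                     na.rm = TRUE)
  if (separated) {
    # weak ridge penalty stabilizes separated fits
    co <- .ridge_logistic(xm, y, lambda = 1e-2)
    score <- drop(cbind(1, xm) %*% co)
  } else {
    score <- drop(cbind(1, xm) %*% ifelse(is.na(fit$coefficients), 0,
                                          fit$coefficients))
  }
  list(score = score, separated = separated,
       coef = if (separated) co else fit$coefficients)
}

.ridge_logistic <- function(xm, y, lambda = 1e-2, iter = 50) {
  p <- ncol(xm) + 1
  beta <- rep(0, p)
  X <- cbind(1, xm)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (i in seq_len(iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X * sqrt(w)) + pen,
                      crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Harrell bootstrap optimism correction
#'
#' Estimates the in-sample optimism of a logistic model's performance:
#' for each bootstrap resample, the model is refit on the resample and
#' its metric computed both on the resample and on the original data;
#' optimism is the mean of those differences and is subtracted from the
#' apparent metric.
#'
#' @param x data.frame/matrix of predictors.
#' @param y logical case labels.
#' @param B bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @param spec specificity for the sensitivity metric.
#' @return list with `apparent`, `optimism`, `corrected` (each a named
#'   vector over metrics `auc` and `sens_at_spec`), `n_redrawn`
#'   (degenerate one-class resamples redrawn) and `separated`.
#' @export
optimism_correct <- function(x, y, B = 200, seed = 1, spec = 0.80) {
  stopifnot(B >= 1, nrow(x) == length(y))
  set.seed(seed)
  metric <- function(score, lab) {
    c(auc = region_auc(score, lab),
      sens_at_spec = unname(
        sensitivity_at_specificity(score, lab, spec)["sensitivity"]))
  }
  fit0 <- .fit_logistic(x, y)
  apparent <- metric(fit0$score, y)
  opt <- matrix(NA_real_, B, 2)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(length(y), replace = TRUE)
      if (any(y[idx]) && any(!y[idx])) break
      n_redrawn <- n_redrawn + 1L
    }
    fb <- .fit_logistic(x[idx, , drop = FALSE], y[idx])
    boot_m <- metric(fb$score, y[idx])
    orig_score <- drop(cbind(1, as.matrix(x)) %*%
                         ifelse(is.na(fb$coef), 0, fb$coef))
    orig_m <- metric(orig_score, y)
    opt[b, ] <- boot_m - orig_m
  }
  optimism <- colMeans(opt)
  names(optimism) <- names(apparent)
  list(apparent = apparent, optimism = optimism,
       corrected = apparent - optimism, n_redrawn = n_redrawn,
       separated = fit0$separated)
}

#' Exhaustive 4-marker logistic models
#'
#' Enumerates every 4-subset of a marker panel and (when data are
#' supplied) fits a logistic regression per subset, optionally with the
#' aneuploidy score as a fifth covariate, reporting the apparent AUC and
#' sensitivity at fixed specificity, with Harrell optimism correction
#' when `B > 0`.
#'
#' @param panel character vector of marker column names (>= 4).
#' @param x optional data.frame of features containing `panel` columns
#'   (and `AS` when `with_as`); when `NULL`, only the enumeration is
#'   returned.
#' @param y logical case labels (required with `x`).
#' @param with_as add the `AS` column to every model.
#' @param B optimism-correction bootstrap resamples (0 skips
#'   correction).
#' @param seed RNG seed.
#' @param spec specificity for the sensitivity metric.
#' @return data.frame with one row per combination: marker ids `m1..m4`,
#'   `with_as`, and (with data) `apparent_auc`, `apparent_sens`,
#'   `separated`, plus `optimism_auc`, `corrected_auc`,
#'   `corrected_sens` when `B > 0`.
#' @export
enumerate_4mdm <- function(panel, x = NULL, y = NULL, with_as = FALSE,
                           B = 0, seed = 1, spec = 0.80) {
  stopifnot(length(panel) >= 4)
  combos <- t(combn(panel, 4))
  out <- data.frame(m1 = combos[, 1], m2 = combos[, 2],
                    m3 = combos[, 3], m4 = combos[, 4],
                    with_as = with_as, stringsAsFactors = FALSE)
  if (is.null(x)) return(out)
  stopifnot(!is.null(y), all(panel %in% names(x)),
            !with_as || "AS" %in% names(x))
  set.seed(seed)
  n <- nrow(out)
  ap_auc <- ap_sens <- opt_auc <- co_auc <- co_sens <- rep(NA_real_, n)
  sep <- logical(n)
  for (i in seq_len(n)) {
    cols <- c(combos[i, ], if (with_as) "AS")
    xi <- x[, cols, drop = FALSE]
    f <- .fit_logistic(xi, y)
    sep[i] <- f$separated
    ap_auc[i] <- region_auc(f$score, y)
    ap_sens[i] <- unname(
      sensitivity_at_specificity(f$score, y, spec)["sensitivity"])
    if (B > 0) {
      oc <- optimism_correct(xi, y, B = B, seed = seed + i, spec = spec)
      opt_auc[i] <- oc$optimism[["auc"]]
      co_auc[i] <- oc$corrected[["auc"]]
      co_sens[i] <- oc$corrected[["sens_at_spec"]]
    }
  }
  out$apparent_auc <- ap_auc
  out$apparent_sens <- ap_sens
  out$separated <- sep
  if (B > 0) {
    out$optimism_auc <- opt_auc
    out$corrected_auc <- co_auc
    out$corrected_sens <- co_sens
  }
  out
}

#' Rule-out threshold at fixed sensitivity
#'
#' Chooses the largest positive-call cutoff (score >= threshold
#' positive) whose case sensitivity reaches `sens`, reports the control
#' specificity there, and optionally applies the frozen cutoff to a
#' held-out score set (e.g. LGD samples). A high-sensitivity cutoff lets
#' test-negative patients safely defer endoscopy.
#'
#' @param scores numeric scores.
#' @param labels logical case labels.
#' @param sens required case sensitivity (default 0.90).
#' @param holdout_scores optional scores to evaluate at the frozen
#'   cutoff.
#' @return list with `threshold`, `sensitivity`, `specificity` and
#'   (when holdout scores are given) `holdout_sensitivity`.
#' @export
rule_out_threshold <- function(scores, labels, sens = 0.90,
                               holdout_scores = NULL) {
  stopifnot(any(labels))
  cases <- scores[labels]; ctrl <- scores[!labels]
  cand <- sort(unique(scores), decreasing = TRUE)
  ok <- vapply(cand, function(t) mean(cases >= t) >= sens, logical(1))
  t <- cand[which(ok)[1]]   # largest cutoff meeting the sensitivity
  out <- list(threshold = t, sensitivity = mean(cases >= t),
              specificity = if (length(ctrl)) mean(ctrl < t) else NA_real_)
  if (!is.null(holdout_scores))
    out$holdout_sensitivity <- mean(holdout_scores >= t)
  out
}

#' Screening projection of NPV and PPV
#'
#' Projects a test with the given sensitivity and specificity onto a
#' hypothetical screening population, building the rounded confusion
#' matrix and the negative and positive predictive values.
#'
#' @param sens,spec test sensitivity and specificity (fractions).
#' @param prevalence disease prevalence (fraction).
#' @param n population size (default 10,000).
#' @return list with `confusion` (2x2 integer matrix), `npv`, `ppv`
#'   (fractions, `NA` when a predicted-negative/positive cell is empty)
#'   and `npv_pct`, `ppv_pct` (rounded to the nearest integer percent).
#' @examples
#' screening_projection(0.90, 0.56, 0.05, 10000)$npv_pct  # 99
#' @export
screening_projection <- function(sens, spec, prevalence, n = 10000) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1, n >= 1)
  cases <- round(n * prevalence)
  controls <- n - cases
  tp <- round(cases * sens); fn <- cases - tp
  tn <- round(controls * spec); fp <- controls - tn
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(c("test_pos", "test_neg"),
                                 c("case", "control")))
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  list(confusion = conf, npv = npv, ppv = ppv,
       npv_pct = if (is.na(npv)) NA_integer_ else round(100 * npv),
       ppv_pct = if (is.na(ppv)) NA_integer_ else round(100 * ppv))
}
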