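#' Validate and complete a pipeline configuration
#'
#' Fills defaults for every tunable of the analysis pipeline and
#' validates domains, reporting all violations at once. The defaults
#' are the pipeline's operating constants: discovery retention at
#' AUC >= 0.60, FC >= 3 and control background < 5%; 500-base
#' cross-platform matching; read-level thresholds 0.8/0.2;
#' 80th-percentile control-R^2 retention; 80% specificity and 90%
#' sensitivity operating points; 1-Mb bins with >= 5 Mb events at
#' ploidy 2; and a 5% prevalence, 10,000-patient screening projection.
#'
#' @param cfg named list of overrides (may be empty); unknown names are
#'   rejected.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(cfg = list()) {
  defaults <- list(
    dir = tempfile("mdmscreen_run_"),
    seed = 1L,
    auc_min = 0.60, fc_min = 3, noise_max = 0.05,
    max_gap = 500,
    tau_hi = 0.8, tau_lo = 0.2,
    min_case_frac = 0.05, max_ctrl_frac = 0.05,
    r2_pct = 80,
    spec_target = 0.80, sens_target = 0.90,
    bin_size = 1e6, min_event_mb = 5, ploidy = 2,
    prevalence = 0.05, n_projection = 10000,
    panel_target = 200,
    cv_k = 5, ntree = 500,
    sim = NULL   # optional sim_config; default built from seed at run
  )
  unknown <- setdiff(names(cfg), names(defaults))
  problems <- character()
  if (length(unknown))
    problems <- c(problems,
                  paste("unknown option(s):", paste(unknown, collapse = ", ")))
  out <- utils::modifyList(defaults, cfg[setdiff(names(cfg), unknown)])
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  frac01 <- function(v) is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1
  chk(frac01(out$auc_min), "auc_min must be in [0, 1]")
  chk(is.numeric(out$fc_min) && out$fc_min >= 0, "fc_min must be >= 0")
  chk(frac01(out$noise_max), "noise_max must be in [0, 1]")
  chk(out$max_gap >= 0, "max_gap must be >= 0")
  chk(frac01(out$tau_hi) && frac01(out$tau_lo) && out$tau_lo <= out$tau_hi,
      "need 0 <= tau_lo <= tau_hi <= 1")
  chk(frac01(out$min_case_frac) && frac01(out$max_ctrl_frac),
      "read-level fractions must be in [0, 1]")
  chk(out$r2_pct > 0 && out$r2_pct <= 100, "r2_pct must be in (0, 100]")
  chk(frac01(out$spec_target), "spec_target must be in [0, 1]")
  chk(frac01(out$sens_target), "sens_target must be in [0, 1]")
  chk(out$bin_size >= 1e4, "bin_size must be >= 10 kb")
  chk(out$min_event_mb >= 0, "min_event_mb must be >= 0")
  chk(out$ploidy > 0, "ploidy must be > 0")
  chk(frac01(out$prevalence), "prevalence must be in [0, 1]")
  chk(out$n_projection >= 1, "n_projection must be >= 1")
  chk(out$panel_target >= 1, "panel_target must be >= 1")
  chk(is.null(out$sim) || inherits(out$sim, "sim_config"),
      "sim must be NULL or a sim_config")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(out) <- c("pipeline_config", "list")
  out
}

pipeline_stages <- c("simulate", "discover", "filter", "aneuploidy",
                     "classify", "evaluate")

# which stage produces each input file
.producers <- c(
  samples.tsv = "simulate", regions.bed = "simulate",
  methylation.tsv = "simulate", read_patterns.tsv = "simulate",
  bin_counts.tsv = "simulate", genome_arms.tsv = "simulate",
  genome_windows.tsv = "simulate",
  discovery_panel.tsv = "discover", marker_metrics.tsv = "discover",
  validation_panel.tsv = "filter",
  aneuploidy_scores.tsv = "aneuploidy",
  cv_scores.tsv = "classify", classify.json = "classify"
)

.require_inputs <- function(cfg, files) {
  paths <- file.path(cfg$dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    by_stage <- .producers[missing]
    stop("missing input(s): ",
         paste0(missing, " (produced by stage '", by_stage, "')",
                collapse = ", "))
  }
  setNames(paths, files)
}

.write_manifest <- function(cfg, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    package_version = as.character(packageVersion("mdmscreen")),
    config = cfg[setdiff(names(cfg), c("dir", "sim"))],
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    output_md5 = as.list(tools::md5sum(unname(outputs)))
  )
  path <- file.path(cfg$dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

.read_genome <- function(cfg) {
  arms <- utils::read.delim(file.path(cfg$dir, "genome_arms.tsv"),
                            stringsAsFactors = FALSE)
  wpath <- file.path(cfg$dir, "genome_windows.tsv")
  windows <- NULL
  if (file.exists(wpath)) {
    w <- utils::read.delim(wpath, stringsAsFactors = FALSE)
    if (nrow(w) > 0) windows <- w
  }
  genome_model(arms[, c("chrom", "arm", "start", "end")],
               bin_size = cfg$bin_size, windows = windows)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic cohort), `discover`
#' (marker metrics, filter cascade, read-level filter, panel
#' supplementation), `filter` (control-variability marker reduction),
#' `aneuploidy` (arm-level scoring), `classify` (cross-validated
#' random-forest with and without the aneuploidy score) and `evaluate`
#' (operating points, rule-out threshold, screening projection). Each
#' stage reads its inputs from `cfg$dir`, writes its outputs there, and
#' records a manifest with input/output checksums, the seed and the
#' configuration; identical config and inputs reproduce identical
#' outputs.
#'
#' @param name stage name.
#' @param cfg a [pipeline_config()].
#' @return named character vector of output paths, invisibly.
#' @export
run_stage <- function(name, cfg) {
  name <- match.arg(name, pipeline_stages)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$dir, recursive = TRUE, showWarnings = FALSE)
  switch(name,
         simulate = .stage_simulate(cfg),
         discover = .stage_discover(cfg),
         filter = .stage_filter(cfg),
         aneuploidy = .stage_aneuploidy(cfg),
         classify = .stage_classify(cfg),
         evaluate = .stage_evaluate(cfg))
}

.stage_simulate <- function(cfg) {
  sim <- if (is.null(cfg$sim)) sim_config(seed = cfg$seed) else cfg$sim
  cohort <- generate_cohort(sim)
  paths <- write_cohort(cohort, cfg$dir)
  g <- sim$genome
  arms_path <- file.path(cfg$dir, "genome_arms.tsv")
  data.table::fwrite(g$arms[, c("chrom", "arm", "start", "end")],
                     arms_path, sep = "\t")
  win_path <- file.path(cfg$dir, "genome_windows.tsv")
  win <- if (is.null(g$windows))
    data.frame(name = character(), chrom = character(),
               start = numeric(), end = numeric()) else g$windows
  data.table::fwrite(win, win_path, sep = "\t")
  outputs <- c(paths, genome_arms = arms_path, genome_windows = win_path)
  .write_manifest(cfg, "simulate", character(), outputs)
  invisible(outputs)
}

.stage_discover <- function(cfg) {
  inp <- .require_inputs(cfg, c("samples.tsv", "methylation.tsv",
                                "read_patterns.tsv"))
  samples <- read_sample_sheet(inp["samples.tsv"])
  meth <- read_methylation_tsv(inp["methylation.tsv"])
  pats <- read_read_patterns_tsv(inp["read_patterns.tsv"])
  brush <- samples[samples$platform == "brush", , drop = FALSE]
  metrics <- marker_metrics(meth, brush)
  casc <- filter_cascade(metrics, auc_min = cfg$auc_min,
                         fc_min = cfg$fc_min, noise_max = cfg$noise_max)
  rl <- read_level_filter(pats, brush, tau_hi = cfg$tau_hi,
                          tau_lo = cfg$tau_lo,
                          min_case_frac = cfg$min_case_frac,
                          max_ctrl_frac = cfg$max_ctrl_frac)
  rl_pass <- paste(rl$region_id, rl$strand, sep = "/")[
    !is.na(rl$pass) & rl$pass]
  passing <- intersect(casc$retained_ids, rl_pass)
  target <- min(cfg$panel_target, nrow(metrics))
  panel <- if (length(passing) < target)
    supplement_panel(passing, metrics, target)
  else structure(list(retained_ids = passing,
                      stage_counts = c(passing = length(passing))),
                 class = "panel_selection")
  metrics_path <- file.path(cfg$dir, "marker_metrics.tsv")
  data.table::fwrite(metrics, metrics_path, sep = "\t")
  panel_path <- file.path(cfg$dir, "discovery_panel.tsv")
  keys <- do.call(rbind, strsplit(panel$retained_ids, "/", fixed = TRUE))
  data.table::fwrite(data.frame(region_id = keys[, 1],
                                strand = keys[, 2]),
                     panel_path, sep = "\t")
  counts_path <- file.path(cfg$dir, "stage_counts.json")
  jsonlite::write_json(
    list(cascade = as.list(casc$stage_counts),
         read_level_pass = length(rl_pass),
         cascade_and_read_level = length(passing),
         final_panel = length(panel$retained_ids)),
    counts_path, auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(marker_metrics = metrics_path,
               discovery_panel = panel_path,
               stage_counts = counts_path)
  .write_manifest(cfg, "discover", inp, outputs)
  invisible(outputs)
}

.stage_filter <- function(cfg) {
  inp <- .require_inputs(cfg, c("samples.tsv", "methylation.tsv",
                                "regions.bed", "discovery_panel.tsv"))
  samples <- read_sample_sheet(inp["samples.tsv"])
  meth <- read_methylation_tsv(inp["methylation.tsv"])
  regions <- read_regions_bed(inp["regions.bed"])
  panel <- utils::read.delim(inp["discovery_panel.tsv"],
                             stringsAsFactors = FALSE)
  brush <- samples[samples$platform == "brush", , drop = FALSE]
  red <- reduce_marker_panel(
    meth[meth$sample_id %in% brush$sample_id],
    brush, regions,
    panel_ids = paste(panel$region_id, panel$strand, sep = "/"),
    pct = cfg$r2_pct)
  out_path <- file.path(cfg$dir, "validation_panel.tsv")
  data.table::fwrite(red$panel, out_path, sep = "\t")
  fits_path <- file.path(cfg$dir, "control_fits.tsv")
  data.table::fwrite(red$fits, fits_path, sep = "\t")
  outputs <- c(validation_panel = out_path, control_fits = fits_path)
  .write_manifest(cfg, "filter", inp, outputs)
  invisible(outputs)
}

.stage_aneuploidy <- function(cfg) {
  inp <- .require_inputs(cfg, c("samples.tsv", "bin_counts.tsv",
                                "genome_arms.tsv"))
  samples <- read_sample_sheet(inp["samples.tsv"])
  bins <- data.table::fread(inp["bin_counts.tsv"])
  genome <- .read_genome(cfg)
  res_all <- list()
  for (pf in unique(samples$platform)) {
    sp <- samples[samples$platform == pf, , drop = FALSE]
    res <- score_aneuploidy(bins[sample_id %in% sp$sample_id], sp,
                            genome, min_event_mb = cfg$min_event_mb,
                            ploidy = cfg$ploidy)
    res$platform <- pf
    res_all[[pf]] <- as.data.frame(res)
  }
  out <- do.call(rbind, res_all)
  rownames(out) <- NULL
  out_path <- file.path(cfg$dir, "aneuploidy_scores.tsv")
  data.table::fwrite(out, out_path, sep = "\t")
  outputs <- c(aneuploidy_scores = out_path)
  .write_manifest(cfg, "aneuploidy", inp, outputs)
  invisible(outputs)
}

.stage_classify <- function(cfg) {
  inp <- .require_inputs(cfg, c("samples.tsv", "methylation.tsv",
                                "validation_panel.tsv",
                                "aneuploidy_scores.tsv"))
  samples <- read_sample_sheet(inp["samples.tsv"])
  meth <- read_methylation_tsv(inp["methylation.tsv"])
  panel <- utils::read.delim(inp["validation_panel.tsv"],
                             stringsAsFactors = FALSE)
  as_tab <- utils::read.delim(inp["aneuploidy_scores.tsv"],
                              stringsAsFactors = FALSE)
  results <- list()
  score_rows <- list()
  for (pf in unique(samples$platform)) {
    sp <- samples[samples$platform == pf, , drop = FALSE]
    fm <- build_feature_matrix(meth[meth$sample_id %in% sp$sample_id],
                               sp, panel)
    fm_as <- build_feature_matrix(meth[meth$sample_id %in% sp$sample_id],
                                  sp, panel,
                                  aneuploidy = as_tab[
                                    as_tab$platform == pf, ])
    cv <- cv_random_forest(fm$x, fm$y, k = cfg$cv_k, seed = cfg$seed,
                           spec = cfg$spec_target, ntree = cfg$ntree)
    cv_as <- cv_random_forest(fm_as$x, fm_as$y, k = cfg$cv_k,
                              seed = cfg$seed, spec = cfg$spec_target,
                              ntree = cfg$ntree)
    results[[pf]] <- list(
      mdm = list(auc = cv$auc, auc_ci = cv$auc_ci,
                 sens_at_spec = cv$sens_at_spec),
      mdm_plus_as = list(auc = cv_as$auc, auc_ci = cv_as$auc_ci,
                         sens_at_spec = cv_as$sens_at_spec),
      fold_plan = cv$fold_plan)
    score_rows[[pf]] <- data.frame(
      sample_id = fm$sample_id, platform = pf, is_case = fm$y,
      score_mdm = cv$out_of_fold_scores,
      score_mdm_as = cv_as$out_of_fold_scores,
      stringsAsFactors = FALSE)
  }
  json_path <- file.path(cfg$dir, "classify.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  scores_path <- file.path(cfg$dir, "cv_scores.tsv")
  data.table::fwrite(do.call(rbind, score_rows), scores_path, sep = "\t")
  outputs <- c(classify = json_path, cv_scores = scores_path)
  .write_manifest(cfg, "classify", inp, outputs)
  invisible(outputs)
}

.stage_evaluate <- function(cfg) {
  inp <- .require_inputs(cfg, c("cv_scores.tsv", "classify.json"))
  scores <- utils::read.delim(inp["cv_scores.tsv"],
                              stringsAsFactors = FALSE)
  out <- list()
  for (pf in unique(scores$platform)) {
    sc <- scores[scores$platform == pf, ]
    ss <- sensitivity_at_specificity(sc$score_mdm, sc$is_case,
                                     spec = cfg$spec_target)
    ro <- rule_out_threshold(sc$score_mdm, sc$is_case,
                             sens = cfg$sens_target)
    proj <- screening_projection(ro$sensitivity, ro$specificity,
                                 cfg$prevalence, cfg$n_projection)
    out[[pf]] <- list(
      sens_at_spec = as.list(ss),
      rule_out = ro,
      projection = list(npv_pct = proj$npv_pct, ppv_pct = proj$ppv_pct,
                        confusion = as.list(as.data.frame(proj$confusion))))
  }
  json_path <- file.path(cfg$dir, "evaluation.json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  outputs <- c(evaluation = json_path)
  .write_manifest(cfg, "evaluate", inp, outputs)
  invisible(outputs)
}

#' Run the full pipeline
#'
#' Executes every stage in order on a fresh or existing run directory.
#'
#' @param cfg a [pipeline_config()] (or a list of overrides).
#' @return named list of per-stage output paths, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  out <- lapply(pipeline_stages, run_stage, cfg = cfg)
  names(out) <- pipeline_stages
  invisible(out)
}
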