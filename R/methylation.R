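#' Region-level methylation beta value
#'
#' The beta value of a region in a sample is the fraction of methylated
#' CpG observations, `meth_reads / total_reads`. Zero-coverage
#' measurements are missing (`NA`), never 0: an unobserved region is not
#' an unmethylated region.
#'
#' @param meth_reads non-negative count(s) of methylated observations.
#' @param total_reads non-negative count(s) of total observations.
#' @return numeric vector of fractions in \[0, 1\]; `NA` where
#'   `total_reads == 0`.
#' @examples
#' compute_beta(8, 10)   # 0.8
#' compute_beta(0, 0)    # NA
#' @export
compute_beta <- function(meth_reads, total_reads) {
  if (any(meth_reads < 0, na.rm = TRUE) || any(total_reads < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(meth_reads > total_reads, na.rm = TRUE))
    stop("meth_reads exceeds total_reads: invalid measurement")
  ifelse(total_reads > 0, meth_reads / total_reads, NA_real_)
}

#' Per-CpG methylation ratio with a coverage floor
#'
#' Computes the methylation ratio C/(C+T) for a CpG call; calls from
#' reads mapping to the reverse strand supply G and A counts in the same
#' two slots. Calls with coverage below `min_cov` are reported missing.
#'
#' @param c_count methylated-base count (C, or G on the reverse strand).
#' @param t_count unmethylated-base count (T, or A on the reverse strand).
#' @param min_cov minimum coverage (>= 1) for a defined ratio.
#' @return numeric vector; `NA` where `c_count + t_count < min_cov`.
#' @export
methylation_ratio <- function(c_count, t_count, min_cov = 1L) {
  stopifnot(min_cov >= 1)
  if (any(c_count < 0) || any(t_count < 0))
    stop("counts must be non-negative")
  cov <- c_count + t_count
  ifelse(cov >= min_cov, c_count / cov, NA_real_)
}

#' Filter CpG calls on coverage
#'
#' Retains exactly the calls whose coverage (`c_count + t_count`) meets
#' `min_cov`; input order is preserved.
#'
#' @param calls data.frame with columns `c_count` and `t_count` (plus any
#'   others, carried through).
#' @param min_cov minimum coverage, >= 1.
#' @return the retained rows of `calls`.
#' @export
filter_cpg_coverage <- function(calls, min_cov = 5L) {
  stopifnot(min_cov >= 1, is.data.frame(calls))
  if (nrow(calls) == 0) return(calls)
  keep <- (calls$c_count + calls$t_count) >= min_cov
  calls[keep, , drop = FALSE]
}

#' Read-level epiallele concordance fractions
#'
#' For one region/sample/strand, classifies each sequencing read by its
#' per-read CpG methylation ratio: reads with at least `tau_hi` of their
#' covered CpGs methylated are concordantly methylated; reads with at
#' most `tau_lo` are concordantly unmethylated.
#'
#' @param cpgs_covered positive integer per read.
#' @param cpgs_methylated non-negative integer per read, `<= cpgs_covered`.
#' @param tau_hi,tau_lo per-read methylation-ratio thresholds,
#'   `0 <= tau_lo <= tau_hi <= 1`.
#' @return named numeric vector `c(frac_hi =, frac_lo =)`.
#' @examples
#' read_concordance_fractions(c(5, 5, 5), c(5, 4, 0))  # 2/3, 1/3
#' @export
read_concordance_fractions <- function(cpgs_covered, cpgs_methylated,
                                       tau_hi = 0.8, tau_lo = 0.2) {
  stopifnot(tau_lo >= 0, tau_hi <= 1, tau_lo <= tau_hi,
            length(cpgs_covered) == length(cpgs_methylated),
            length(cpgs_covered) >= 1)
  if (any(cpgs_covered <= 0))
    stop("every read must cover at least one CpG")
  if (any(cpgs_methylated > cpgs_covered))
    stop("cpgs_methylated exceeds cpgs_covered")
  r <- cpgs_methylated / cpgs_covered
  c(frac_hi = mean(r >= tau_hi), frac_lo = mean(r <= tau_lo))
}

cohort_levels <- c("NE", "NDBE", "LGD", "HGD", "EAC")
platform_levels <- c("brush", "sponge", "tissue")

#' Read a sample sheet
#'
#' Loads a tab-separated sample sheet and validates the closed `cohort`
#' and `platform` vocabularies.
#'
#' @param path TSV with columns `sample_id`, `cohort`
#'   (NE/NDBE/LGD/HGD/EAC), `platform` (brush/sponge/tissue) and optional
#'   covariates (`age`, `sex`, `bmi`, `ever_smoker`, `be_length_cm`).
#' @return data.frame of sample information.
#' @export
read_sample_sheet <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t"))
  req <- c("sample_id", "cohort", "platform")
  if (!all(req %in% names(x)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(x$cohort), cohort_levels)
  if (length(bad))
    stop("unknown cohort value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(x$platform), platform_levels)
  if (length(bad))
    stop("unknown platform value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id in sample sheet")
  x
}

#' Read region definitions from BED6
#'
#' Regions are 0-based half-open; the BED name column holds the region
#' id and the strand column is used. The same region id may appear on
#' both strands (forward and reverse strand markers are assessed
#' independently); `(region_id, strand)` must be unique.
#'
#' @param path BED6 file. An optional 7th column `n_cpgs` is read when
#'   present.
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `strand` and (if present) `n_cpgs`.
#' @export
read_regions_bed <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (ncol(x) < 6)
    stop("expected BED6 (chrom, start, end, name, score, strand)")
  out <- data.frame(region_id = as.character(x[[4]]),
                    chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    strand = as.character(x[[6]]),
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 7) out$n_cpgs <- as.integer(x[[7]])
  validate_regions(out)
  out
}

validate_regions <- function(regions) {
  stopifnot(all(c("region_id", "chrom", "start", "end", "strand") %in%
                  names(regions)))
  if (any(regions$start >= regions$end))
    stop("region start must be < end (0-based half-open)")
  if (!all(regions$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(regions[, c("region_id", "strand")]))
    stop("(region_id, strand) must be unique")
  if ("n_cpgs" %in% names(regions) && any(regions$n_cpgs < 1))
    stop("n_cpgs must be >= 1")
  invisible(regions)
}

#' Write region definitions to BED6
#'
#' @param regions data.frame as returned by [read_regions_bed()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  validate_regions(regions)
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$region_id, 0L, regions$strand)
  if ("n_cpgs" %in% names(regions)) bed$n_cpgs <- regions$n_cpgs
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a region methylation count table
#'
#' @param path TSV with columns `region_id`, `sample_id`, `strand`,
#'   `meth_reads`, `total_reads`.
#' @return data.table with those columns plus `beta`
#'   (see [compute_beta()]).
#' @export
read_methylation_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  req <- c("region_id", "sample_id", "strand", "meth_reads", "total_reads")
  if (!all(req %in% names(x)))
    stop("methylation table must have columns: ", paste(req, collapse = ", "))
  x[, beta := compute_beta(meth_reads, total_reads)]
  x[]
}

#' Read a read-level CpG pattern table
#'
#' One row per sequencing read: the number of CpGs it covers in the
#' region and how many of those are methylated.
#'
#' @param path TSV with columns `region_id`, `sample_id`, `strand`,
#'   `cpgs_covered`, `cpgs_methylated`.
#' @return data.table.
#' @export
read_read_patterns_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  req <- c("region_id", "sample_id", "strand", "cpgs_covered",
           "cpgs_methylated")
  if (!all(req %in% names(x)))
    stop("read pattern table must have columns: ",
         paste(req, collapse = ", "))
  if (any(x$cpgs_methylated > x$cpgs_covered))
    stop("cpgs_methylated exceeds cpgs_covered")
  x
}
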