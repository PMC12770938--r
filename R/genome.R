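#' Genome models for arm-level copy-number analysis
#'
#' A genome model lists chromosomes, chromosome arms (0-based half-open
#' coordinates) and a bin size, and optionally named focal windows (such
#' as the 8q24 region) used by [recurrent_flags()].
#'
#' @param arms data.frame with columns `chrom`, `arm` (`"p"`/`"q"`),
#'   `start`, `end` (0-based half-open).
#' @param bin_size bin width in bases (default 1e6, i.e. 1 Mb).
#' @param windows optional data.frame of named focal windows with columns
#'   `name`, `chrom`, `start`, `end`.
#' @return an object of class `genome_model` with elements `chromosomes`,
#'   `arms` (with an `arm_id` column `chrom` + arm letter), `bin_size`
#'   and `windows`.
#' @export
genome_model <- function(arms, bin_size = 1e6, windows = NULL) {
  stopifnot(is.data.frame(arms),
            all(c("chrom", "arm", "start", "end") %in% names(arms)))
  arms <- as.data.frame(arms)
  if (!all(arms$arm %in% c("p", "q")))
    stop("arm must be 'p' or 'q'")
  if (any(arms$start >= arms$end))
    stop("arm start must be < end")
  arms$arm_id <- paste0(sub("^chr", "", arms$chrom), arms$arm)
  if (anyDuplicated(arms$arm_id))
    stop("duplicate chromosome arms")
  # arms must not overlap within a chromosome
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
      stop("overlapping arms on ", ch)
  }
  structure(list(
    chromosomes = unique(arms$chrom),
    arms = arms,
    bin_size = as.numeric(bin_size),
    windows = windows
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model:", length(x$chromosomes), "chromosomes,",
      nrow(x$arms), "arms, bin size", format(x$bin_size, big.mark = ","),
      "bp\n")
  if (!is.null(x$windows))
    cat("Focal windows:", paste(x$windows$name, collapse = ", "), "\n")
  invisible(x)
}

#' Miniature genome for fast tests
#'
#' Builds a small genome of `n_chrom` metacentric chromosomes with two
#' arms of `arm_mb` megabases each. Useful for exercising segmentation
#' and arm-call logic at low cost; it carries no focal windows, so
#' recurrent-alteration flags are inapplicable on it.
#'
#' @param n_chrom number of chromosomes.
#' @param arm_mb arm length in Mb.
#' @param bin_size bin width in bases.
#' @return a [genome_model()].
#' @export
toy_genome <- function(n_chrom = 4, arm_mb = 30, bin_size = 1e6) {
  arm_len <- arm_mb * 1e6
  arms <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(chrom = paste0("chr", i),
               arm = c("p", "q"),
               start = c(0, arm_len),
               end = c(arm_len, 2 * arm_len))
  }))
  genome_model(arms, bin_size = bin_size)
}

#' Human autosome (hg19) arm model
#'
#' The 44 autosomal chromosome arms of the hg19 assembly (centromere
#' coordinates from the UCSC cytoband track), with the 8q24 focal window
#' used for recurrent-gain flagging.
#'
#' @param bin_size bin width in bases (default 1 Mb).
#' @return a [genome_model()] with 44 arms.
#' @export
hg19_genome <- function(bin_size = 1e6) {
  path <- system.file("extdata", "hg19_arms.tsv", package = "mdmscreen")
  arms <- utils::read.delim(path, stringsAsFactors = FALSE)
  windows <- data.frame(name = "8q24", chrom = "chr8",
                        start = 117700000, end = 146364022,
                        stringsAsFactors = FALSE)
  genome_model(arms, bin_size = bin_size, windows = windows)
}

#' Tile a genome model into fixed-size bins
#'
#' Bins tile each arm at the model's bin size; a terminal remainder
#' shorter than the bin size is kept as its own (shorter) bin.
#'
#' @param genome a [genome_model()].
#' @return data.frame with columns `chrom`, `start`, `end`, `arm_id`.
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  bs <- genome$bin_size
  out <- lapply(seq_len(nrow(genome$arms)), function(i) {
    a <- genome$arms[i, ]
    starts <- seq(a$start, a$end - 1, by = bs)
    ends <- pmin(starts + bs, a$end)
    data.frame(chrom = a$chrom, start = starts, end = ends,
               arm_id = a$arm_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
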