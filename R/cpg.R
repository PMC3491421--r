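# CpG density, LCP/ICP/HCP promoter classes, 5hmC-enriched TSS detection and
# the information-theoretic tissue specificity score.

#' CpG density of a sequence window
#'
#' Counts CG dinucleotides (case-insensitive; N never matches) per 100 bp of
#' window length. CG is its own reverse complement, so the density is strand
#' symmetric.
#'
#' @param sequence character vector of sequences over A/C/G/T/N.
#' @return numeric vector of CpGs per 100 bp.
#' @examples
#' cpg_density("CGCGCG") # 50
#' @export
cpg_density <- function(sequence) {
  stopifnot(all(nchar(sequence) > 0))
  vapply(toupper(sequence), function(s) {
    hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
    n <- if (hits[1] == -1) 0L else length(hits)
    100 * n / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify promoters by CpG density
#'
#' Low CpG content (LCP) below 1 CpG per 100 bp, intermediate (ICP) from 1
#' to 5 inclusive, high (HCP) above 5.
#'
#' @param density numeric vector of CpGs per 100 bp (>= 0).
#' @return factor with levels `LCP`, `ICP`, `HCP`.
#' @export
classify_promoter <- function(density) {
  stopifnot(all(density >= 0))
  cls <- ifelse(density < 1, "LCP", ifelse(density <= 5, "ICP", "HCP"))
  factor(cls, levels = c("LCP", "ICP", "HCP"))
}

#' Genes with 5hmC-enriched TSS regions
#'
#' Genes whose strand-aware TSS window intersects at least one peak of the
#' (group-mean) 5hmC peak set.
#'
#' @param ann a `genome_annotation`.
#' @param peakset a `peak_set` called on a 5hmC group-mean track.
#' @param tss_halfwidth TSS window half-width in bp.
#' @return character vector of gene ids.
#' @export
tss_5hmc_enriched <- function(ann, peakset, tss_halfwidth = 500) {
  if (nrow(peakset$peaks) == 0) return(character(0))
  tt <- tss_table(ann)
  wins <- data.frame(chrom = tt$chrom,
                     start = pmax(0, tt$tss - tss_halfwidth),
                     end = tt$tss + tss_halfwidth)
  sl <- names(ann$chromosomes)
  n <- GenomicRanges::countOverlaps(.as_granges(wins, sl),
                                    .as_granges(peakset$peaks, sl))
  tt$gene_id[n > 0]
}

#' Information-theoretic tissue specificity score
#'
#' With expression shares p_t = e_t / sum(e) over T tissues, the score is
#' the Kullback-Leibler divergence from the uniform distribution,
#' `Si = sum_t p_t * log2(p_t * T)` (zero shares contribute nothing). It is
#' exactly 0 for uniform expression, exactly `log2(T)` for single-tissue
#' expression, and invariant to rescaling.
#'
#' @param expression non-negative expression values across T >= 2 tissues,
#'   not all zero.
#' @return The specificity score in `[0, log2(T)]`.
#' @export
specificity_score <- function(expression) {
  T <- length(expression)
  stopifnot(T >= 2, all(expression >= 0), sum(expression) > 0)
  p <- expression / sum(expression)
  p <- p[p > 0]
  sum(p * log2(p * T))
}
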