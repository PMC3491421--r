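# Region-count scoring of ChIP-seq fragment libraries: dedup, any-overlap
# counting, library-size scaling, and log2 IP/background scores.

#' Remove duplicated fragment locations
#'
#' Exact (chrom, start, end) duplicates collapse to one; the removal count
#' is reported via a message and stored in attribute `"n_removed"`.
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @return deduplicated fragment table.
#' @export
dedup_fragments <- function(fragments) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$start >= fragments$end)) {
    stop("fragment(s) with start >= end")
  }
  keep <- !duplicated(fragments[, c("chrom", "start", "end")])
  n_removed <- sum(!keep)
  if (n_removed > 0) message(n_removed, " duplicated locations removed")
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n_removed
  out
}

#' Count fragments overlapping each region
#'
#' A fragment counts for every region it intersects by at least 1 bp (a
#' fragment spanning two regions is counted in both).
#'
#' @param fragments fragment table (`chrom`, `start`, `end`).
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`.
#' @return named integer vector of counts per region.
#' @export
count_in_regions <- function(fragments, regions) {
  stopifnot(all(regions$end > regions$start))
  if (nrow(fragments) == 0) {
    return(stats::setNames(rep(0L, nrow(regions)), regions$region_id))
  }
  sl <- unique(c(as.character(regions$chrom), as.character(fragments$chrom)))
  counts <- GenomicRanges::countOverlaps(.as_granges(regions, sl),
                                         .as_granges(fragments, sl))
  stats::setNames(as.integer(counts), regions$region_id)
}

#' Scale counts to the mean library size
#'
#' Each library's counts are multiplied by `mean(library sizes) / own size`,
#' preserving within-library count ratios.
#'
#' @param counts numeric vector or regions x libraries matrix.
#' @param library_sizes numeric vector of total fragments per library (> 0).
#' @return scaled counts, same shape as `counts`.
#' @export
normalize_counts <- function(counts, library_sizes) {
  stopifnot(all(library_sizes > 0))
  f <- mean(library_sizes) / library_sizes
  if (is.null(dim(counts))) {
    stopifnot(length(library_sizes) == 1)
    counts * f
  } else {
    stopifnot(ncol(counts) == length(library_sizes))
    sweep(counts, 2, f, `*`)
  }
}

#' log2 enrichment of scaled IP counts over matched background
#'
#' @param ip_scaled,bg_scaled scaled counts (vectors or matrices of the same
#'   shape).
#' @param pseudocount positive constant added to both (avoids -Inf on empty
#'   regions).
#' @return log2((IP + c) / (background + c)).
#' @export
log2_vs_background <- function(ip_scaled, bg_scaled, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  log2((ip_scaled + pseudocount) / (bg_scaled + pseudocount))
}

#' Per-region, per-sample ChIP scores for one histone mark
#'
#' Runs the full region-count pipeline on matched IP/background fragment
#' libraries: deduplication, any-overlap counting over the mark's regions,
#' scaling of all libraries (IP and background together) to their mean size,
#' and per-sample log2 IP/background scores; then group means and the
#' treated - control change.
#'
#' @param ip_libs named list of IP fragment tables (names = sample ids).
#' @param bg_libs named list of matched background tables (same names).
#' @param regions region table (`region_id`, `chrom`, `start`, `end`).
#' @param groups named character vector, sample -> group label.
#' @param pseudocount pseudocount for [log2_vs_background()].
#' @return list with `scores` (regions x samples), `group_means`, and
#'   `change` (treated - control), plus the scaled count matrices.
#' @export
chip_region_scores <- function(ip_libs, bg_libs, regions, groups,
                               pseudocount = 1) {
  stopifnot(identical(names(ip_libs), names(bg_libs)),
            all(names(ip_libs) %in% names(groups)))
  ip_libs <- lapply(ip_libs, dedup_fragments)
  bg_libs <- lapply(bg_libs, dedup_fragments)
  ip_counts <- vapply(ip_libs, count_in_regions, numeric(nrow(regions)),
                      regions = regions)
  bg_counts <- vapply(bg_libs, count_in_regions, numeric(nrow(regions)),
                      regions = regions)
  sizes <- c(vapply(ip_libs, nrow, integer(1)), vapply(bg_libs, nrow, integer(1)))
  ip_scaled <- normalize_counts(ip_counts, sizes[seq_along(ip_libs)])
  bg_scaled <- normalize_counts(bg_counts, sizes[length(ip_libs) + seq_along(bg_libs)])
  scores <- log2_vs_background(ip_scaled, bg_scaled, pseudocount)
  rownames(scores) <- regions$region_id
  grp <- groups[colnames(scores)]
  gm <- vapply(unique(grp), function(g) {
    rowMeans(scores[, grp == g, drop = FALSE])
  }, numeric(nrow(scores)))
  change <- if (all(c("control", "treated") %in% colnames(gm))) {
    gm[, "treated"] - gm[, "control"]
  } else NULL
  list(scores = scores, group_means = gm, change = change,
       ip_scaled = ip_scaled, bg_scaled = bg_scaled)
}
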