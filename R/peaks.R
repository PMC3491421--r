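# Probe-window percentile peak calling.
#
# A peak is a merged run of five-probe windows in which at least four probes
# exceed the 90th-percentile score of the whole track. Windows never span
# tiled-region boundaries nor probe gaps larger than max_gap.

#' Empirical percentile threshold of a score vector
#'
#' Linear interpolation between order statistics (the standard type-7
#' quantile convention); missing values are excluded.
#'
#' @param scores numeric vector of probe scores.
#' @param q percentile in (0, 100).
#' @return The threshold score.
#' @examples
#' percentile_threshold(1:100, 90) # 90.1
#' @export
percentile_threshold <- function(scores, q = 90) {
  stopifnot(q > 0, q < 100)
  x <- scores[!is.na(scores)]
  if (length(x) == 0) stop("all scores missing; cannot compute a percentile")
  unname(stats::quantile(x, q / 100, type = 7))
}

#' Call enrichment peaks with the probe-window percentile rule
#'
#' Probes are scanned in windows of `w` consecutive probes, where consecutive
#' means adjacent in sorted order, in the same tiled region, and with
#' start-to-start gaps of at most `max_gap` bp. A window qualifies iff at
#' least `k` of its probes strictly exceed the threshold (ties at the
#' threshold do not count; missing scores count as below). Overlapping or
#' adjacent qualifying windows merge into a single peak spanning the first
#' member probe's start to the last member probe's end; the peak's probes are
#' all probes inside the merged span. Runs shorter than `w` probes are
#' skipped (counted in `n_skipped_runs`).
#'
#' @param probes probe table (`chrom`, `start`, `end`, `probe_id`, optional
#'   `region_id`), sorted by (chrom, start).
#' @param scores numeric score vector aligned with `probes` (typically a
#'   group-mean track).
#' @param q threshold percentile of the entire data set.
#' @param k minimum number of above-threshold probes per window (k <= w).
#' @param w window size in probes.
#' @param max_gap maximum probe start-to-start gap within a window, bp.
#' @param threshold score threshold; defaults to
#'   `percentile_threshold(scores, q)`.
#' @return A `peak_set`: list with `peaks` (data.frame with `chrom`,
#'   `start`, `end`, `peak_id`, `n_probes`, `max_score`, `mean_score`),
#'   `members` (list of member probe-id vectors per peak), `threshold`,
#'   `params`, and `n_skipped_runs`.
#' @export
call_peaks <- function(probes, scores, q = 90, k = 4, w = 5, max_gap = 500,
                       threshold = NULL) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  stopifnot(length(scores) == nrow(probes), k <= w, w >= 1)
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$start)
  if (!identical(ord, seq_len(nrow(probes)))) {
    stop("probes must be sorted by (chrom, start) before peak calling")
  }
  if (is.null(threshold)) threshold <- percentile_threshold(scores, q)

  n <- nrow(probes)
  region <- if ("region_id" %in% names(probes)) probes$region_id else probes$chrom
  new_run <- c(TRUE, probes$chrom[-1] != probes$chrom[-n] |
                 region[-1] != region[-n] |
                 (probes$start[-1] - probes$start[-n]) > max_gap)
  run <- cumsum(new_run)
  above <- !is.na(scores) & scores > threshold

  peaks <- list(); members <- list(); n_skipped <- 0L
  for (idx in split(seq_len(n), run)) {
    m <- length(idx)
    if (m < w) { n_skipped <- n_skipped + 1L; next }
    cs <- cumsum(above[idx])
    win_count <- cs[w:m] - c(0, cs)[seq_len(m - w + 1)]
    qual <- which(win_count >= k)
    if (length(qual) == 0) next
    # merge overlapping/adjacent qualifying windows over probe indices
    starts <- qual
    ends <- qual + w - 1L
    brk <- c(TRUE, starts[-1] > ends[-length(ends)] + 1L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      a <- min(starts[grp == g]); b <- max(ends[grp == g])
      sel <- idx[a:b]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = probes$chrom[sel[1]],
        start = probes$start[sel[1]],
        end = probes$end[sel[length(sel)]],
        n_probes = length(sel),
        max_score = max(scores[sel], na.rm = TRUE),
        mean_score = mean(scores[sel], na.rm = TRUE),
        stringsAsFactors = FALSE
      )
      members[[length(members) + 1L]] <- probes$probe_id[sel]
    }
  }

  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_probes = integer(0), max_score = numeric(0),
               mean_score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
    peaks <- peaks[, c("chrom", "start", "end", "peak_id", "n_probes",
                       "max_score", "mean_score")]
  } else {
    peaks$peak_id <- character(0)
  }
  structure(list(peaks = peaks, members = members, threshold = threshold,
                 params = list(q = q, k = k, w = w, max_gap = max_gap,
                               exceedance = "strict"),
                 n_skipped_runs = n_skipped),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", nrow(x$peaks), "peaks,", length(peak_probes(x)),
      "member probes, threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' All probe ids inside peaks
#' @param peakset a `peak_set`.
#' @return character vector of unique member probe ids.
#' @export
peak_probes <- function(peakset) {
  out <- unique(unlist(peakset$members, use.names = FALSE))
  if (is.null(out)) character(0) else out
}

#' Percentage formatting of a probe count ratio
#'
#' @param n_in number of probes in the class of interest.
#' @param n_total total probe count (> 0).
#' @param digits decimals to report.
#' @return The percentage, rounded to `digits`.
#' @examples
#' probe_percent(96003, 2056330) # 4.7
#' @export
probe_percent <- function(n_in, n_total, digits = 1) {
  stopifnot(n_total > 0)
  round(100 * n_in / n_total, digits)
}

#' Fraction of all probes residing in peaks
#'
#' @param peakset a `peak_set`.
#' @param track a `probe_track` over the same probe universe, or the total
#'   probe count.
#' @param digits decimals for the percent report.
#' @return list with `n_peak_probes`, `n_probes`, `fraction`, `percent`.
#' @export
peak_probe_fraction <- function(peakset, track, digits = 1) {
  n_total <- if (inherits(track, "probe_track")) nrow(track$probes)
             else if (is.data.frame(track)) nrow(track)
             else as.numeric(track)
  if (is.na(n_total) || n_total == 0) stop("empty probe track")
  n_in <- length(peak_probes(peakset))
  list(n_peak_probes = n_in, n_probes = n_total,
       fraction = n_in / n_total,
       percent = probe_percent(n_in, n_total, digits))
}
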