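# Independent oracles, deliberately naive: they re-derive expected results
# by direct enumeration without touching the implementation's internals.

# Brute-force probe-window enumerator: tries every window of w consecutive
# probes and collects the probes of every qualifying window.
brute_force_peak_probes <- function(probes, scores, threshold, k = 4, w = 5,
                                    max_gap = 500) {
  n <- nrow(probes)
  region <- if ("region_id" %in% names(probes)) probes$region_id else probes$chrom
  hit <- character(0)
  if (n < w) return(hit)
  for (i in seq_len(n - w + 1)) {
    idx <- i:(i + w - 1)
    if (length(unique(probes$chrom[idx])) > 1) next
    if (length(unique(region[idx])) > 1) next
    if (any(diff(probes$start[idx]) > max_gap)) next
    s <- scores[idx]
    if (sum(!is.na(s) & s > threshold) >= k) {
      hit <- c(hit, probes$probe_id[idx])
    }
  }
  sort(unique(hit))
}

# Count of qualifying windows (for the merged-peaks <= windows invariant).
brute_force_window_count <- function(probes, scores, threshold, k = 4, w = 5,
                                     max_gap = 500) {
  n <- nrow(probes)
  region <- if ("region_id" %in% names(probes)) probes$region_id else probes$chrom
  cnt <- 0L
  if (n < w) return(cnt)
  for (i in seq_len(n - w + 1)) {
    idx <- i:(i + w - 1)
    if (length(unique(probes$chrom[idx])) > 1) next
    if (length(unique(region[idx])) > 1) next
    if (any(diff(probes$start[idx]) > max_gap)) next
    s <- scores[idx]
    if (sum(!is.na(s) & s > threshold) >= k) cnt <- cnt + 1L
  }
  cnt
}

# Random peak-caller test instance: 200 probes, occasional large gaps and
# two tiled regions, N(0,1) scores.
random_peak_instance <- function(seed, n = 200) {
  set.seed(seed)
  gaps <- sample(c(100, 100, 100, 100, 700), n - 1, replace = TRUE)
  starts <- cumsum(c(0, gaps))
  probes <- data.frame(
    chrom = "chr1", start = starts, end = starts + 60,
    probe_id = sprintf("p%04d", seq_len(n)),
    region_id = rep(c("trA", "trB"), c(floor(n / 2), ceiling(n / 2))),
    stringsAsFactors = FALSE
  )
  list(probes = probes, scores = stats::rnorm(n))
}
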