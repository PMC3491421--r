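# Within- and between-array normalization of probe-level log2(IP/input)
# scores, and group summaries. The 5hmC and 5mC tracks are always normalized
# separately (they are distinct probe_track objects).

#' Within-array loess normalization against probe intensity
#'
#' For each sample a locally weighted degree-1 regression (tricube weights,
#' robust "symmetric" family, i.e. three robustness iterations) of the score
#' on the probe mean log-intensity (A-value) is fitted and subtracted,
#' removing intensity-dependent saturation trends. Samples whose intensity
#' column is constant fall back to subtracting the column median (flagged via
#' a message).
#'
#' @param track a `probe_track` carrying an `intensity` matrix.
#' @param samples samples to normalize (default all).
#' @param span loess span in (0, 1].
#' @return The normalized `probe_track`.
#' @export
loess_normalize <- function(track, samples = NULL, span = 0.3) {
  stopifnot(inherits(track, "probe_track"), span > 0, span <= 1)
  if (is.null(track$intensity)) stop("track has no intensity matrix")
  if (nrow(track$probes) < 50) {
    stop("loess normalization requires at least 50 probes, got ",
         nrow(track$probes))
  }
  if (is.null(samples)) samples <- colnames(track$scores)
  for (s in samples) {
    y <- track$scores[, s]
    a <- track$intensity[, s]
    ok <- !is.na(y) & !is.na(a)
    if (stats::sd(a[ok]) == 0) {
      message("constant intensity for sample ", s, "; subtracting median")
      track$scores[ok, s] <- y[ok] - stats::median(y[ok])
      next
    }
    fit <- stats::loess(y[ok] ~ a[ok], span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(surface = "interpolate"))
    track$scores[ok, s] <- y[ok] - stats::fitted(fit)
  }
  track
}

#' Between-array scale normalization
#'
#' Equalizes the spread of all sample columns: each column is divided by its
#' median absolute deviation and multiplied by the geometric mean of all
#' columns' MADs, so that afterwards every per-sample MAD equals that
#' geometric mean. This is the contract of scale normalization between
#' two-colour arrays.
#'
#' @param track a `probe_track` with >= 2 samples.
#' @return The normalized `probe_track`.
#' @export
scale_normalize <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  if (ncol(track$scores) < 2) stop("scale normalization requires >= 2 samples")
  mads <- apply(track$scores, 2, stats::mad, na.rm = TRUE)
  if (any(mads == 0)) {
    stop("zero MAD in sample(s): ",
         paste(colnames(track$scores)[mads == 0], collapse = ", "))
  }
  gm <- exp(mean(log(mads)))
  track$scores <- sweep(track$scores, 2, gm / mads, `*`)
  track
}

#' Per-probe mean score of a sample group
#'
#' Arithmetic mean across the group's samples, excluding missing values
#' pairwise (a probe missing in every sample stays `NA`; the number of
#' excluded values is reported via a message).
#'
#' @param track a `probe_track`.
#' @param group group label present in `track$groups`.
#' @return Named numeric vector (names = probe ids).
#' @export
group_mean <- function(track, group) {
  stopifnot(inherits(track, "probe_track"))
  samples <- names(track$groups)[track$groups == group]
  if (length(samples) == 0) stop("unknown group label: ", group)
  m <- track$scores[, samples, drop = FALSE]
  n_missing <- sum(is.na(m))
  if (n_missing > 0) message(n_missing, " missing values excluded pairwise")
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-probe change upon treatment
#'
#' Elementwise `treated - control`; positive values are gains upon
#' treatment.
#'
#' @param control_mean,treated_mean named per-probe mean vectors over the
#'   identical probe set (e.g. from [group_mean()]).
#' @return Named numeric vector of changes.
#' @export
delta_track <- function(control_mean, treated_mean) {
  if (!identical(names(control_mean), names(treated_mean))) {
    bad <- c(setdiff(names(control_mean), names(treated_mean)),
             setdiff(names(treated_mean), names(control_mean)))
    stop("probe sets differ between groups; offending ids: ",
         paste(utils::head(unique(bad), 10), collapse = ", "),
         if (length(unique(bad)) > 10) ", ..." else "",
         if (length(bad) == 0) " (same ids, different order)" else "")
  }
  treated_mean - control_mean
}
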