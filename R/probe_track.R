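# ProbeTrack: ordered array probes with per-sample log2(IP/input) scores.

#' Construct a probe track
#'
#' @param probes data.frame with `chrom`, `start`, `end`, `probe_id`,
#'   `region_id` (0-based half-open intervals, sorted by chromosome then
#'   start).
#' @param scores numeric matrix, probes x samples, of log2(IP/input) scores.
#' @param groups named character vector mapping sample name to group label
#'   (e.g. `"control"`, `"treated"`).
#' @param intensity optional numeric matrix (probes x samples) of mean
#'   log-intensities (A-values) used by within-array normalization.
#' @param mark label for the modification measured (e.g. `"5hmC"`).
#' @return An object of class `probe_track`.
#' @export
probe_track <- function(probes, scores, groups, intensity = NULL, mark = NA_character_) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "start", "end", "probe_id") %in% names(probes)),
            is.matrix(scores), nrow(scores) == nrow(probes),
            !is.null(colnames(scores)),
            all(colnames(scores) %in% names(groups)))
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id in probe table")
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$start)
  if (!identical(ord, seq_len(nrow(probes)))) {
    stop("probes must be sorted by (chrom, start)")
  }
  if (!is.null(intensity)) {
    stopifnot(is.matrix(intensity), dim(intensity) == dim(scores))
    dimnames(intensity) <- list(probes$probe_id, colnames(scores))
  }
  rownames(scores) <- probes$probe_id
  structure(list(probes = probes, scores = scores,
                 intensity = intensity,
                 groups = groups[colnames(scores)], mark = mark),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat("probe_track (", x$mark, "): ", nrow(x$probes), " probes x ",
      ncol(x$scores), " samples [",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Probe midpoints
#' @param probes probe table of a `probe_track`.
#' @return integer vector of interval midpoints.
#' @keywords internal
.probe_mid <- function(probes) floor((probes$start + probes$end) / 2)

#' Lay out array probes over the tiled regions of an annotation
#' @keywords internal
.layout_probes <- function(ann, probe_spacing, probe_len_range) {
  tr <- ann$tiled_regions
  out <- lapply(seq_len(nrow(tr)), function(i) {
    lo <- tr$start[i]; hi <- tr$end[i]
    if (hi - lo < probe_len_range[2]) return(NULL)
    starts <- seq(lo, hi - probe_len_range[2], by = probe_spacing)
    data.frame(chrom = tr$chrom[i], start = starts,
               end = starts + sample(seq(probe_len_range[1], probe_len_range[2]),
                                     length(starts), replace = TRUE),
               region_id = tr$region_id[i], stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, out)
  probes$probe_id <- sprintf("p%06d", seq_len(nrow(probes)))
  probes[, c("chrom", "start", "end", "probe_id", "region_id")]
}

#' Simulate 5hmC and 5mC probe tracks with planted effects
#'
#' Emulates log2(IP/input) scores from a two-colour promoter tiling array for
#' a control and a treated group. Baseline probe scores are Gaussian with sd
#' `noise_sd` plus a per-animal offset (`between_animal_sd`). On top of the
#' baseline the generator plants, and records in a truth ledger:
#'
#' * intra-genic 5hmC peaks in a fraction of genes, with effect size
#'   `peak_effect` (log2) scaled by the gene's expression tier
#'   (`tier_weights`), present in all animals;
#' * a broad low-level 5mC elevation (`body_5mc`) over every gene body;
#' * for `n_induced` randomly chosen "induced" genes, in treated animals
#'   only: a gain of 5hmC and loss of 5mC over the promoter flanks
#'   (`core_halfwidth` < |offset| <= `flank_reach` from the TSS), scaled per
#'   gene by its true expression fold change, and a loss of both marks over
#'   the TSS core (|offset| <= `core_halfwidth`);
#' * a per-probe mean log-intensity covariate (A-value); when
#'   `intensity_coef` is non-zero a linear intensity trend
#'   `intensity_coef * A` is added to the scores so within-array
#'   normalization can be exercised.
#'
#' Probe membership in any planted interval is decided by the probe midpoint,
#' the same rule the analysis uses, so planted effects are exactly
#' recoverable from the raw tables.
#'
#' @param ann A `genome_annotation` from [simulate_annotation()].
#' @param n_control,n_treated animals per group (>= 2).
#' @param noise_sd probe-level Gaussian noise sd, log2 units (> 0).
#' @param between_animal_sd sd of per-animal global offsets, log2 units.
#' @param probe_spacing start-to-start probe spacing in bp.
#' @param probe_len_range probe length range in bp.
#' @param peak_gene_fraction fraction of genes given an intra-genic 5hmC peak.
#' @param peak_effect planted peak effect size in log2 units.
#' @param peak_width_range planted peak width range in bp.
#' @param tier_weights multiplier of `peak_effect` per expression tier.
#' @param body_5mc broad 5mC gene-body elevation, log2 units.
#' @param n_induced number of treatment-induced genes.
#' @param induced_lfc_range range of true log2 expression fold changes for
#'   induced genes.
#' @param induced_delta_5hmc,induced_delta_5mc mean planted flank change for
#'   each mark in treated animals (log2; reciprocal by default). Per gene the
#'   change is scaled by `true_lfc / mean(true_lfc)`.
#' @param core_delta change of both marks over the TSS core in treated
#'   animals (log2).
#' @param core_halfwidth half-width of the TSS core in bp.
#' @param flank_reach outer limit of the planted promoter flanks in bp.
#' @param intensity_coef linear coefficient of the planted intensity trend.
#' @param enhancer_5hmc_effect 5hmC elevation planted over enhancer elements
#'   (log2, all animals; enhancers are 5hmC-enriched relative to 5mC).
#' @param enhancer_fraction fraction of enhancers receiving the elevation.
#' @param seed integer seed.
#' @return list with elements `hmc` and `mc` (class `probe_track`) and
#'   `truth` (class `truth_ledger`) recording every planted effect.
#' @export
simulate_probe_signals <- function(ann,
                                   n_control = 5, n_treated = 5,
                                   noise_sd = 0.5, between_animal_sd = 0.1,
                                   probe_spacing = 100,
                                   probe_len_range = c(50, 70),
                                   peak_gene_fraction = 0.3,
                                   peak_effect = 2,
                                   peak_width_range = c(1500, 3000),
                                   tier_weights = c(low = 0.5, medium = 1, high = 1.5),
                                   body_5mc = 0.5,
                                   n_induced = 30,
                                   induced_lfc_range = c(1.6, 4),
                                   induced_delta_5hmc = 1,
                                   induced_delta_5mc = -1,
                                   core_delta = -1,
                                   core_halfwidth = 250,
                                   flank_reach = 3000,
                                   intensity_coef = 0,
                                   enhancer_5hmc_effect = 1.5,
                                   enhancer_fraction = 0.5,
                                   seed = 1) {
  stopifnot(inherits(ann, "genome_annotation"), noise_sd > 0,
            n_control >= 2, n_treated >= 2,
            n_induced <= nrow(ann$genes))
  set.seed(seed)
  probes <- .layout_probes(ann, probe_spacing, probe_len_range)
  n <- nrow(probes)
  mid <- .probe_mid(probes)
  samples <- c(paste0("C", seq_len(n_control)), paste0("T", seq_len(n_treated)))
  groups <- stats::setNames(rep(c("control", "treated"), c(n_control, n_treated)),
                            samples)
  ns <- length(samples)

  base_mat <- function() {
    m <- matrix(stats::rnorm(n * ns, 0, noise_sd), n, ns,
                dimnames = list(probes$probe_id, samples))
    sweep(m, 2, stats::rnorm(ns, 0, between_animal_sd), `+`)
  }
  hmc <- base_mat()
  mc <- base_mat()

  g <- ann$genes
  tssv <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  tiers <- expression_tiers(stats::setNames(g$base_expr, g$gene_id))

  # strand-aware offset of every probe midpoint from every gene's TSS is
  # only needed gene-locally; helper returns probe indices with midpoint in
  # a genomic interval
  probes_in <- function(cn, lo, hi) which(probes$chrom == cn & mid >= lo & mid < hi)

  # planted intra-genic 5hmC peaks -----------------------------------------
  covered_len <- pmin(g$length, ann$params$downstream_reach)
  eligible <- which(covered_len >= peak_width_range[1] / 2 + 200)
  n_peaks <- round(peak_gene_fraction * nrow(g))
  peak_idx <- if (n_peaks > 0) {
    eligible[sample.int(length(eligible), min(n_peaks, length(eligible)))]
  } else integer(0)
  planted <- lapply(peak_idx, function(i) {
    cl <- covered_len[i]
    w <- round(stats::runif(1, min(peak_width_range[1], cl - 100),
                            min(peak_width_range[2], cl)))
    off <- round(stats::runif(1, 0, cl - w))
    if (g$strand[i] == "+") c(tssv[i] + off, tssv[i] + off + w)
    else c(tssv[i] - off - w, tssv[i] - off)
  })
  planted_df <- NULL
  if (length(peak_idx)) {
    planted_df <- data.frame(
      chrom = g$chrom[peak_idx],
      start = vapply(planted, `[`, numeric(1), 1),
      end = vapply(planted, `[`, numeric(1), 2),
      gene_id = g$gene_id[peak_idx],
      effect = peak_effect * unname(tier_weights[as.character(tiers[g$gene_id[peak_idx]])]),
      stringsAsFactors = FALSE
    )
    # planted intervals must lie inside tiled regions
    tiled_gr <- .as_granges(ann$tiled_regions, names(ann$chromosomes))
    pk_gr <- .as_granges(planted_df, names(ann$chromosomes))
    cov <- GenomicRanges::countOverlaps(pk_gr, tiled_gr, type = "within")
    if (any(cov == 0)) {
      stop("planted peak interval(s) fall outside tiled regions: ",
           paste(planted_df$gene_id[cov == 0], collapse = ", "))
    }
    for (r in seq_len(nrow(planted_df))) {
      sel <- probes_in(planted_df$chrom[r], planted_df$start[r], planted_df$end[r])
      hmc[sel, ] <- hmc[sel, ] + planted_df$effect[r]
    }
  }

  # broad gene-body 5mC ------------------------------------------------------
  if (body_5mc != 0) {
    for (i in seq_len(nrow(g))) {
      sel <- probes_in(g$chrom[i], g$tx_start[i], g$tx_end[i])
      mc[sel, ] <- mc[sel, ] + body_5mc
    }
  }

  # enhancer 5hmC enrichment -------------------------------------------------
  enhancer_df <- NULL
  if (!is.null(ann$enhancers) && enhancer_5hmc_effect != 0 &&
      enhancer_fraction > 0) {
    ne <- nrow(ann$enhancers)
    eidx <- sort(sample.int(ne, round(enhancer_fraction * ne)))
    if (length(eidx)) {
      enhancer_df <- ann$enhancers[eidx, c("chrom", "start", "end", "enhancer_id")]
      enhancer_df$effect <- enhancer_5hmc_effect
      for (r in seq_len(nrow(enhancer_df))) {
        sel <- probes_in(enhancer_df$chrom[r], enhancer_df$start[r],
                         enhancer_df$end[r])
        hmc[sel, ] <- hmc[sel, ] + enhancer_5hmc_effect
      }
    }
  }

  # treatment-induced promoter reprogramming --------------------------------
  induced_df <- NULL
  treated_cols <- names(groups)[groups == "treated"]
  if (n_induced > 0) {
    iidx <- sample(seq_len(nrow(g)), n_induced)
    lfc <- stats::runif(n_induced, induced_lfc_range[1], induced_lfc_range[2])
    wts <- lfc / mean(lfc)
    induced_df <- data.frame(gene_id = g$gene_id[iidx], true_lfc = lfc,
                             flank_weight = wts, stringsAsFactors = FALSE)
    for (j in seq_len(n_induced)) {
      i <- iidx[j]
      rel_all <- if (g$strand[i] == "+") mid - tssv[i] else tssv[i] - mid
      on_chrom <- probes$chrom == g$chrom[i]
      core <- which(on_chrom & abs(rel_all) <= core_halfwidth)
      flank <- which(on_chrom & abs(rel_all) > core_halfwidth &
                       abs(rel_all) <= flank_reach)
      hmc[core, treated_cols] <- hmc[core, treated_cols] + core_delta
      mc[core, treated_cols] <- mc[core, treated_cols] + core_delta
      hmc[flank, treated_cols] <- hmc[flank, treated_cols] +
        wts[j] * induced_delta_5hmc
      mc[flank, treated_cols] <- mc[flank, treated_cols] +
        wts[j] * induced_delta_5mc
    }
  }

  # intensity covariate ------------------------------------------------------
  make_A <- function() {
    a <- stats::runif(n, 8, 14)
    matrix(a, n, ns, dimnames = list(probes$probe_id, samples)) +
      matrix(stats::rnorm(n * ns, 0, 0.3), n, ns)
  }
  A_hmc <- make_A(); A_mc <- make_A()
  if (intensity_coef != 0) {
    hmc <- hmc + intensity_coef * A_hmc
    mc <- mc + intensity_coef * A_mc
  }

  truth <- structure(list(
    planted_peaks = list("5hmC" = planted_df,
                         "5mC" = data.frame(chrom = g$chrom, start = g$tx_start,
                                            end = g$tx_end, gene_id = g$gene_id,
                                            effect = body_5mc,
                                            stringsAsFactors = FALSE)),
    planted_enhancers = enhancer_df,
    induced_genes = induced_df,
    tss_core_loss = if (is.null(induced_df)) character(0) else induced_df$gene_id,
    tiers = tiers,
    params = list(noise_sd = noise_sd, between_animal_sd = between_animal_sd,
                  peak_effect = peak_effect, tier_weights = tier_weights,
                  body_5mc = body_5mc, core_delta = core_delta,
                  core_halfwidth = core_halfwidth, flank_reach = flank_reach,
                  induced_delta_5hmc = induced_delta_5hmc,
                  induced_delta_5mc = induced_delta_5mc,
                  intensity_coef = intensity_coef),
    seeds = c(signals = seed)
  ), class = "truth_ledger")

  list(
    hmc = probe_track(probes, hmc, groups, intensity = A_hmc, mark = "5hmC"),
    mc = probe_track(probes, mc, groups, intensity = A_mc, mark = "5mC"),
    truth = truth
  )
}

#' Probes whose midpoint lies in any of a set of intervals
#'
#' Convenience accessor used to compare calls against the truth ledger.
#'
#' @param track a `probe_track` (or bare probe table).
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return character vector of probe ids.
#' @export
probes_in_intervals <- function(track, intervals) {
  probes <- if (inherits(track, "probe_track")) track$probes else track
  if (is.null(intervals) || nrow(intervals) == 0) return(character(0))
  mid <- .probe_mid(probes)
  sl <- unique(c(as.character(probes$chrom), as.character(intervals$chrom)))
  hits <- GenomicRanges::findOverlaps(
    .point_granges(probes$chrom, mid, sl),
    .as_granges(intervals, sl)
  )
  unique(probes$probe_id[S4Vectors::queryHits(hits)])
}
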