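# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Mid-sized synthetic study used by several test files: one chromosome,
# 80 genes, 15 induced, defaults otherwise.
shared_sim <- function() {
  if (!exists("sim", envir = .fixtures)) {
    ann <- simulate_annotation(n_genes = 80, n_chrom = 1,
                               chrom_length = 2.4e6,
                               enhancers_per_chrom = 12, seed = 11)
    sim <- simulate_probe_signals(ann, n_induced = 15, seed = 12)
    cm <- group_mean(sim$hmc, "control")
    tm <- group_mean(sim$hmc, "treated")
    cm_mc <- group_mean(sim$mc, "control")
    tm_mc <- group_mean(sim$mc, "treated")
    assign("sim", list(
      ann = ann, hmc = sim$hmc, mc = sim$mc, truth = sim$truth,
      hmc_control = cm, hmc_treated = tm,
      mc_control = cm_mc, mc_treated = tm_mc,
      delta_hmc = delta_track(cm, tm),
      delta_mc = delta_track(cm_mc, tm_mc),
      peaks_hmc = call_peaks(sim$hmc$probes, cm),
      peaks_mc = call_peaks(sim$mc$probes, cm_mc)
    ), envir = .fixtures)
  }
  get("sim", envir = .fixtures)
}

# Hand-built probe track on one chromosome: fixed 60 bp probes every 100 bp.
synth_track <- function(scores, intensity = NULL, groups = NULL,
                        start0 = 0, spacing = 100, probe_len = 60,
                        region_id = "tr1", mark = "5hmC") {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = 1, dimnames = list(NULL, "S1"))
  }
  n <- nrow(scores)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("S", seq_len(ncol(scores)))
  if (is.null(groups)) {
    groups <- stats::setNames(rep("control", ncol(scores)), colnames(scores))
  }
  starts <- start0 + spacing * (seq_len(n) - 1)
  probes <- data.frame(chrom = "chr1", start = starts, end = starts + probe_len,
                       probe_id = sprintf("p%05d", seq_len(n)),
                       region_id = region_id, stringsAsFactors = FALSE)
  probe_track(probes, scores, groups, intensity = intensity, mark = mark)
}

# Mirror a genome (coordinate x -> L - x), flipping strands; used for the
# strand-symmetry invariants.
mirror_intervals <- function(df, L) {
  out <- df
  out$start <- L - df$end
  out$end <- L - df$start
  out[order(out$chrom, out$start), , drop = FALSE]
}

mirror_annotation <- function(ann) {
  L <- unname(ann$chromosomes[1])
  stopifnot(length(ann$chromosomes) == 1) # mirror fixture is single-chrom
  g <- ann$genes
  g2 <- g
  g2$tx_start <- L - g$tx_end
  g2$tx_end <- L - g$tx_start
  g2$strand <- ifelse(g$strand == "+", "-", "+")
  g2 <- g2[order(g2$tx_start), ]
  ex <- ann$exons
  ex2 <- ex
  ex2$start <- L - ex$end
  ex2$end <- L - ex$start
  ex2 <- ex2[order(ex2$gene_id, ex2$start), ]
  ann2 <- ann
  ann2$genes <- g2
  ann2$exons <- ex2
  if (!is.null(ann$cgis)) ann2$cgis <- mirror_intervals(ann$cgis, L)
  if (!is.null(ann$enhancers)) ann2$enhancers <- mirror_intervals(ann$enhancers, L)
  ann2$tiled_regions <- mirror_intervals(ann$tiled_regions, L)
  ann2
}
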