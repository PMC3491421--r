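# End-to-end orchestration: configuration, validation, and the full
# synthetic-study pipeline from simulation through differential analysis.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. The defaults encode the
#' study conditions the package emulates: groups of five livers, 90th
#' percentile 4-of-5-probe peak windows, TSS +/- 1.5 kb 200/50 bp profiles,
#' a +2/-1 kb promoter window for H3K4me2 and gene bodies for
#' H3K27me3/H3K36me3, and the induction threshold of log2 1.5.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    annotation = list(n_genes = 200, n_chrom = 2, chrom_length = 5e6,
                      short_gene_fraction = 0.2, cgi_promoter_fraction = 0.4,
                      enhancers_per_chrom = 20),
    signals = list(n_control = 5, n_treated = 5, noise_sd = 0.5,
                   between_animal_sd = 0.1, peak_gene_fraction = 0.3,
                   peak_effect = 2, n_induced = 30,
                   induced_delta_5hmc = 1, induced_delta_5mc = -1,
                   core_delta = -1, intensity_coef = 0),
    expression = list(noise_sd = 0.2, tissue_count = 8),
    chipseq = list(n_fragments = 50000, n_replicates = 2, dup_rate = 0.1,
                   base_enrichment = 4, lfc_coupling = 0.5,
                   marks = c("H3K4me2", "H3K27me3", "H3K36me3")),
    normalize = list(order = c("loess", "scale"), span = 0.3),
    peaks = list(q = 90, k = 4, w = 5, max_gap = 500),
    profile = list(span = 1500, window = 200, step = 50),
    ppr_halfwidth = 1000,
    induction_threshold = 1.5,
    pseudocount = 1,
    heatmap_clip = 2.5,
    epimark = list(n_loci = 6, cq_uncut = 20, noise_sd = 0.1,
                   n_replicates = 2),
    outdir = NULL
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every tunable and reports all violations at once rather than
#' failing fast.
#'
#' @param config a `pipeline_config` (or compatible list).
#' @return character vector of error messages; empty when valid.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  pk <- config$peaks
  if (!is.null(pk)) {
    if (pk$k > pk$w) add("min_above exceeds window (k > w)")
    if (pk$q <= 0 || pk$q >= 100) add("percentile q must lie in (0, 100)")
    if (pk$max_gap <= 0) add("max_gap must be positive")
  }
  pr <- config$profile
  if (!is.null(pr)) {
    if (pr$span <= 0) add("profile span must be positive")
    if (pr$window <= 0) add("profile window must be positive")
    if (pr$step <= 0) add("profile step must be positive")
    else if (pr$span > 0 && pr$span %% pr$step != 0) {
      add("profile span must be a multiple of step")
    }
  }
  sg <- config$signals
  if (!is.null(sg)) {
    if (sg$noise_sd <= 0) add("noise_sd must be positive")
    if (sg$n_control < 2 || sg$n_treated < 2) add("groups need >= 2 animals")
  }
  if (!is.null(config$pseudocount) && config$pseudocount <= 0) {
    add("pseudocount must be positive")
  }
  if (!is.null(config$annotation) && config$annotation$n_genes < 1) {
    add("n_genes must be >= 1")
  }
  for (p in config$inputs) {
    if (!file.exists(p)) add(paste0("input path does not exist: ", p))
  }
  errors
}

#' Run the full synthetic-study pipeline
#'
#' Simulates annotation, probe tracks, expression, ChIP-seq libraries and
#' EpiMark Cq tables from the configuration's seeds, then runs every
#' analysis stage in order: normalization (loess within arrays, then scale
#' between), group means and change tracks, peak calling on the group-mean
#' tracks, genic category distribution with chi-square, enhancer/CGI
#' overlap, expression-tier TSS meta-profiles, the PPR heat map, ChIP-seq
#' region scores, induced-gene selection, the five change correlations, TSS
#' change profiles, the family region analysis, and EpiMark quantification.
#'
#' Deterministic given the config seed. When `outdir` is set, tables are
#' written as TSV/BED/GFF3 and a JSON manifest records parameters, package
#' version and file digests.
#'
#' @param config a `pipeline_config`; see [default_config()].
#' @param outdir optional output directory (overrides `config$outdir`).
#' @return A result bundle (list) with all stage outputs.
#' @export
run_pipeline <- function(config = default_config(), outdir = config$outdir) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  seed <- config$seed
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[%6.1fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))

  stage("simulating annotation")
  ann <- do.call(simulate_annotation,
                 c(config$annotation, list(seed = seed)))

  stage("simulating probe signals")
  sim <- do.call(simulate_probe_signals,
                 c(list(ann = ann), config$signals, list(seed = seed + 1)))
  truth <- sim$truth

  stage("simulating expression")
  ex <- do.call(simulate_expression,
                c(list(ann = ann, induced = truth$induced_genes,
                       n_control = config$signals$n_control,
                       n_treated = config$signals$n_treated),
                  config$expression, list(seed = seed + 2)))

  stage("normalizing probe tracks")
  norm <- function(track) {
    for (step in config$normalize$order) {
      track <- switch(step,
                      loess = loess_normalize(track, span = config$normalize$span),
                      scale = scale_normalize(track),
                      stop("unknown normalization step: ", step))
    }
    track
  }
  hmc <- norm(sim$hmc); mc <- norm(sim$mc)

  stage("group means and change tracks")
  means <- list(
    hmc_control = group_mean(hmc, "control"),
    hmc_treated = group_mean(hmc, "treated"),
    mc_control = group_mean(mc, "control"),
    mc_treated = group_mean(mc, "treated")
  )
  delta_hmc <- delta_track(means$hmc_control, means$hmc_treated)
  delta_mc <- delta_track(means$mc_control, means$mc_treated)

  stage("peak calling")
  pk <- config$peaks
  peaks_hmc <- call_peaks(hmc$probes, means$hmc_control, q = pk$q, k = pk$k,
                          w = pk$w, max_gap = pk$max_gap)
  peaks_mc <- call_peaks(mc$probes, means$mc_control, q = pk$q, k = pk$k,
                         w = pk$w, max_gap = pk$max_gap)

  stage("genic category distribution")
  scheme <- category_scheme(upstream = c(-ann$params$upstream_reach, -1000))
  all_cat <- assign_category(hmc$probes, ann, scheme)
  probe_counts <- table(all_cat$category)
  pk_cat <- function(ps) {
    ids <- peak_probes(ps)
    table(all_cat$category[match(ids, hmc$probes$probe_id)])
  }
  hmc_counts <- pk_cat(peaks_hmc); mc_counts <- pk_cat(peaks_mc)
  distribution <- list(
    probe_counts = probe_counts,
    hmc = list(counts = hmc_counts,
               chi2 = distribution_chi2(c(hmc_counts), c(probe_counts)),
               normalized = coverage_normalized_distribution(c(hmc_counts),
                                                             c(probe_counts))),
    mc = list(counts = mc_counts,
              chi2 = distribution_chi2(c(mc_counts), c(probe_counts)),
              normalized = coverage_normalized_distribution(c(mc_counts),
                                                            c(probe_counts)))
  )

  stage("feature overlap (enhancers, CGIs, shores)")
  overlap <- list(
    enhancer_hmc = feature_overlap(peaks_hmc, ann$enhancers, hmc$probes),
    enhancer_mc = feature_overlap(peaks_mc, ann$enhancers, mc$probes),
    cgi_hmc = feature_overlap(peaks_hmc, ann$cgis, hmc$probes),
    shore_hmc = feature_overlap(peaks_hmc, cgi_shores(ann), hmc$probes)
  )

  stage("meta-profiles by expression tier")
  tiers <- truth$tiers
  anchors <- tss_table(ann)
  prof <- config$profile
  profiles <- lapply(levels(tiers), function(tr) {
    a <- anchors[anchors$gene_id %in% names(tiers)[tiers == tr], ]
    meta_profile(hmc$probes, means$hmc_control, a, span = prof$span,
                 window = prof$window, step = prof$step)
  })
  names(profiles) <- levels(tiers)

  stage("PPR heat map")
  ppr_mat <- ppr_means(hmc$probes, hmc$scores, ann,
                       halfwidth = config$ppr_halfwidth)
  heatmap <- ppr_heatmap(ppr_mat[stats::complete.cases(ppr_mat), ,
                                 drop = FALSE],
                         clip = config$heatmap_clip)

  stage("ChIP-seq region scores")
  cs <- config$chipseq
  tiers_z <- as.numeric(scale(ann$genes$base_expr))
  lfc_map <- stats::setNames(rep(0, nrow(ann$genes)), ann$genes$gene_id)
  if (!is.null(truth$induced_genes)) {
    lfc_map[truth$induced_genes$gene_id] <- truth$induced_genes$true_lfc
  }
  chip <- list()
  cseed <- seed + 10
  for (mk in cs$marks) {
    dir_sign <- if (mk == "H3K27me3") -1 else 1
    base_e <- cs$base_enrichment * 2^(0.4 * dir_sign * tiers_z)
    names(base_e) <- ann$genes$gene_id
    ip <- list(); bg <- list(); groups <- character(0)
    for (grp in c("control", "treated")) {
      e <- base_e
      if (grp == "treated") e <- e * 2^(dir_sign * cs$lfc_coupling * lfc_map)
      for (r in seq_len(cs$n_replicates)) {
        cseed <- cseed + 1
        lib <- simulate_fragments(ann, mark = mk, enrichment = e,
                                  n_fragments = cs$n_fragments,
                                  dup_rate = cs$dup_rate, seed = cseed)
        id <- paste0(substr(grp, 1, 1), r)
        ip[[id]] <- lib$ip; bg[[id]] <- lib$background
        groups[id] <- grp
      }
    }
    chip[[mk]] <- chip_region_scores(ip, bg, mark_regions(ann, mk), groups,
                                     pseudocount = config$pseudocount)
  }

  stage("differential analysis")
  changes <- expression_change(ex$expr, ex$groups)
  induced <- select_induced(changes, config$induction_threshold)
  unaffected <- select_unaffected(changes, n = max(length(induced), 3),
                                  seed = seed + 3)
  d_hmc_ppr <- ppr_means(hmc$probes, delta_hmc, ann,
                         halfwidth = config$ppr_halfwidth)
  d_mc_ppr <- ppr_means(mc$probes, delta_mc, ann,
                        halfwidth = config$ppr_halfwidth)
  records <- data.frame(gene_id = changes$gene_id, lfc = changes$lfc,
                        p = changes$p, stringsAsFactors = FALSE)
  records$d5hmc <- d_hmc_ppr[records$gene_id]
  records$d5mc <- d_mc_ppr[records$gene_id]
  records$dH3K4me2 <- chip$H3K4me2$change[records$gene_id]
  records$dH3K27me3 <- chip$H3K27me3$change[records$gene_id]
  records$dH3K36me3 <- chip$H3K36me3$change[records$gene_id]
  records$status <- ifelse(records$gene_id %in% induced, "induced",
                    ifelse(records$gene_id %in% unaffected, "unaffected",
                           "other"))
  corr_marks <- c("d5hmc", "d5mc", "dH3K4me2", "dH3K36me3", "dH3K27me3")
  correlations <- lapply(corr_marks, function(mk) {
    change_correlation(records, induced, mk)
  })
  names(correlations) <- corr_marks

  stage("change profiles and family analysis")
  change_profiles <- list(
    hmc_induced = change_profile(hmc$probes, delta_hmc, ann, induced),
    mc_induced = change_profile(mc$probes, delta_mc, ann, induced),
    hmc_unaffected = change_profile(hmc$probes, delta_hmc, ann, unaffected),
    mc_unaffected = change_profile(mc$probes, delta_mc, ann, unaffected)
  )
  deltas_long <- rbind(
    gene_region_deltas(hmc$probes, delta_hmc, ann, scheme,
                       config$ppr_halfwidth, mark = "5hmC"),
    gene_region_deltas(mc$probes, delta_mc, ann, scheme,
                       config$ppr_halfwidth, mark = "5mC")
  )
  family <- family_region_analysis(deltas_long, induced, unaffected)

  stage("EpiMark quantification")
  em <- config$epimark
  set.seed(seed + 4)
  n_loci <- em$n_loci
  # fraction triples on the simplex: the three CpG states partition the site
  fr <- matrix(stats::runif(n_loci * 3), n_loci, 3)
  fr <- fr / rowSums(fr)
  true_fractions <- data.frame(locus = sprintf("locus%02d", seq_len(n_loci)),
                               f_5hmc = fr[, 1], f_5mc = fr[, 2],
                               f_c = fr[, 3])
  cq <- simulate_epimark_cq(true_fractions, cq_uncut = em$cq_uncut,
                            noise_sd = em$noise_sd,
                            n_replicates = em$n_replicates, seed = seed + 5)
  epimark <- list(true_fractions = true_fractions, cq = cq,
                  fractions = epimark_fractions(cq))

  bundle <- list(
    annotation = ann, truth = truth, tracks = list(hmc = hmc, mc = mc),
    expression = ex, means = means,
    delta = list(hmc = delta_hmc, mc = delta_mc),
    peaks = list(hmc = peaks_hmc, mc = peaks_mc),
    distribution = distribution, overlap = overlap,
    profiles = profiles, heatmap = heatmap, chip = chip,
    records = records, induced = induced, unaffected = unaffected,
    correlations = correlations, change_profiles = change_profiles,
    family = family, epimark = epimark,
    config = config
  )

  if (!is.null(outdir)) {
    stage(paste("writing outputs to", outdir))
    bundle$manifest <- .write_bundle(bundle, outdir)
  }
  stage("done")
  bundle
}

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  paths <- c(paths, write_annotation(bundle$annotation,
                                     file.path(outdir, "annotation")))
  paths <- c(paths,
             write_probe_track(bundle$tracks$hmc, file.path(outdir, "hmc_track.tsv")),
             write_probe_track(bundle$tracks$mc, file.path(outdir, "mc_track.tsv")),
             write_peaks_bed(bundle$peaks$hmc, file.path(outdir, "peaks_5hmC.bed")),
             write_peaks_bed(bundle$peaks$mc, file.path(outdir, "peaks_5mC.bed")),
             wt(bundle$records, "gene_change_records.tsv"),
             wt(bundle$family, "family_region_analysis.tsv"),
             wt(bundle$epimark$fractions, "epimark_fractions.tsv"),
             wt(do.call(rbind, lapply(names(bundle$profiles), function(tr) {
               cbind(tier = tr, as.data.frame(bundle$profiles[[tr]]))
             })), "tss_profiles.tsv"))
  tp <- file.path(outdir, "truth_ledger.json")
  write_truth(bundle$truth, tp)
  paths <- c(paths, tp)
  manifest <- list(
    package = "hydroxyscan",
    version = as.character(utils::packageVersion("hydroxyscan")),
    seed = bundle$config$seed,
    parameters = bundle$config[setdiff(names(bundle$config), "outdir")],
    files = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
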