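# Simulators for the assays surrounding the tiling arrays: ChIP-seq fragment
# libraries, expression matrices (with a tissue panel) and EpiMark-style
# glucosylation/restriction qPCR Cq tables.

#' Canonical scored region for a histone mark
#'
#' H3K4me2 is scored over a promoter window (TSS-1 kb..+2 kb, strand-aware);
#' H3K27me3 and H3K36me3 over the gene body.
#'
#' @param ann A `genome_annotation`.
#' @param mark one of `"H3K4me2"`, `"H3K27me3"`, `"H3K36me3"`.
#' @return data.frame with `region_id` (gene id), `chrom`, `start`, `end`.
#' @export
mark_regions <- function(ann, mark = c("H3K4me2", "H3K27me3", "H3K36me3")) {
  mark <- match.arg(mark)
  g <- ann$genes
  if (mark == "H3K4me2") {
    tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
    start <- ifelse(g$strand == "+", tss - 1000, tss - 2000)
    end <- ifelse(g$strand == "+", tss + 2000, tss + 1000)
  } else {
    start <- g$tx_start; end <- g$tx_end
  }
  data.frame(region_id = g$gene_id, chrom = g$chrom,
             start = pmax(0, start), end = end, stringsAsFactors = FALSE)
}

#' Simulate a ChIP-seq fragment library with a matched background
#'
#' Fragment positions are drawn region-proportionally: each canonical region
#' of the mark receives sampling weight `length x enrichment`, and the
#' remainder of the genome weight `length x 1`. Fragment lengths are uniform
#' in `frag_len_range`. A stated fraction of duplicate locations is then
#' injected (resampled existing rows) so that downstream deduplication is
#' exercised; the number of unique locations is recorded. The matched
#' background library is sampled uniformly over the genome with the same
#' duplicate rate.
#'
#' @param ann A `genome_annotation`.
#' @param mark histone mark label (decides the canonical region kind).
#' @param enrichment named numeric vector, gene id -> fold enrichment over
#'   background (>= 0). Genes absent from the vector get enrichment 1.
#' @param n_fragments total fragments per library (duplicates included).
#' @param frag_len_range fragment length range in bp.
#' @param dup_rate fraction of the library that is duplicated locations.
#' @param seed integer seed.
#' @return list with `ip` and `background` fragment tables (`chrom`,
#'   `start`, `end`), the region table, and `n_unique_ip` /
#'   `n_unique_background` ground-truth counts.
#' @export
simulate_fragments <- function(ann, mark = "H3K4me2", enrichment = NULL,
                               n_fragments = 50000,
                               frag_len_range = c(100, 300),
                               dup_rate = 0.1, seed = 1) {
  stopifnot(inherits(ann, "genome_annotation"), n_fragments >= 0,
            dup_rate >= 0, dup_rate < 1)
  set.seed(seed)
  regions <- mark_regions(ann, mark)
  if (any(regions$end <= regions$start)) {
    stop("zero-length region(s): ",
         paste(regions$region_id[regions$end <= regions$start], collapse = ", "))
  }
  e <- rep(1, nrow(regions))
  if (!is.null(enrichment)) {
    if (any(enrichment < 0)) stop("enrichment must be >= 0")
    hit <- match(regions$region_id, names(enrichment))
    e[!is.na(hit)] <- enrichment[hit[!is.na(hit)]]
  }

  chrom_names <- names(ann$chromosomes)
  genome_len <- sum(ann$chromosomes)
  region_len <- regions$end - regions$start
  weights <- c(region_len * e, max(genome_len - sum(region_len), 0))

  draw_lib <- function(n, uniform = FALSE) {
    if (n == 0) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    }
    n_unique <- max(1L, round(n * (1 - dup_rate)))
    len <- round(stats::runif(n_unique, frag_len_range[1], frag_len_range[2]))
    if (uniform) {
      pos <- stats::runif(n_unique, 0, genome_len)
      cidx <- findInterval(pos, cumsum(c(0, unname(ann$chromosomes))),
                           rightmost.closed = TRUE)
      cidx <- pmin(pmax(cidx, 1L), length(chrom_names))
      start <- round(pos - cumsum(c(0, unname(ann$chromosomes)))[cidx])
      chrom <- chrom_names[cidx]
    } else {
      ridx <- sample.int(length(weights), n_unique, replace = TRUE,
                         prob = weights)
      bg <- ridx > nrow(regions)
      chrom <- character(n_unique); start <- integer(n_unique)
      if (any(bg)) {
        pos <- stats::runif(sum(bg), 0, genome_len)
        cidx <- findInterval(pos, cumsum(c(0, unname(ann$chromosomes))),
                             rightmost.closed = TRUE)
        cidx <- pmin(pmax(cidx, 1L), length(chrom_names))
        chrom[bg] <- chrom_names[cidx]
        start[bg] <- round(pos - cumsum(c(0, unname(ann$chromosomes)))[cidx])
      }
      if (any(!bg)) {
        r <- ridx[!bg]
        start[!bg] <- regions$start[r] +
          round(stats::runif(sum(!bg), 0, pmax(region_len[r] - len[!bg], 1)))
        chrom[!bg] <- regions$chrom[r]
      }
    }
    df <- data.frame(chrom = chrom, start = as.integer(pmax(0, start)),
                     end = as.integer(pmax(0, start) + len),
                     stringsAsFactors = FALSE)
    n_dup <- n - n_unique
    if (n_dup > 0) df <- rbind(df, df[sample.int(n_unique, n_dup, replace = TRUE), ])
    rownames(df) <- NULL
    df
  }

  ip <- draw_lib(n_fragments, uniform = FALSE)
  bg <- draw_lib(n_fragments, uniform = TRUE)
  list(ip = ip, background = bg, regions = regions, mark = mark,
       n_unique_ip = nrow(unique(ip)),
       n_unique_background = nrow(unique(bg)))
}

#' Simulate an expression matrix and a tissue panel
#'
#' Per-gene baseline log2 expression comes from the annotation's latent
#' `base_expr`; samples add Gaussian noise, and treated samples of induced
#' genes are shifted by the gene's true log2 fold change. The tissue panel
#' (linear scale) contains designed uniformly-expressed genes and designed
#' single-tissue genes for specificity-score tests.
#'
#' @param ann A `genome_annotation`.
#' @param induced optional data.frame with `gene_id` and `true_lfc` (> 0),
#'   e.g. `truth$induced_genes` from [simulate_probe_signals()].
#' @param n_control,n_treated samples per group.
#' @param noise_sd per-sample log2 noise sd.
#' @param tissue_count number of tissues in the panel (>= 2).
#' @param n_single_tissue,n_uniform designed genes of each kind.
#' @param seed integer seed.
#' @return list with `expr` (log2 matrix, genes x samples), `groups`,
#'   `tissue` (linear matrix, genes x tissues) and `tissue_design`
#'   (data.frame of designed genes).
#' @export
simulate_expression <- function(ann, induced = NULL,
                                n_control = 5, n_treated = 5,
                                noise_sd = 0.2, tissue_count = 8,
                                n_single_tissue = 5, n_uniform = 5,
                                seed = 1) {
  stopifnot(inherits(ann, "genome_annotation"), tissue_count >= 2)
  set.seed(seed)
  g <- ann$genes
  if (!is.null(induced)) {
    bad <- setdiff(induced$gene_id, g$gene_id)
    if (length(bad)) stop("induced gene id(s) not in annotation: ",
                          paste(bad, collapse = ", "))
    if (any(induced$true_lfc <= 0)) stop("true_lfc must be > 0 for induced genes")
  }
  samples <- c(paste0("C", seq_len(n_control)), paste0("T", seq_len(n_treated)))
  groups <- stats::setNames(rep(c("control", "treated"), c(n_control, n_treated)),
                            samples)
  expr <- matrix(g$base_expr, nrow(g), length(samples)) +
    matrix(stats::rnorm(nrow(g) * length(samples), 0, noise_sd),
           nrow(g), length(samples))
  dimnames(expr) <- list(g$gene_id, samples)
  if (!is.null(induced) && nrow(induced) > 0) {
    ridx <- match(induced$gene_id, g$gene_id)
    expr[ridx, groups == "treated"] <- expr[ridx, groups == "treated"] +
      induced$true_lfc
  }

  tissue <- matrix(2^(g$base_expr +
                        stats::rnorm(nrow(g) * tissue_count, 0, 0.5)),
                   nrow(g), tissue_count,
                   dimnames = list(g$gene_id, paste0("tissue", seq_len(tissue_count))))
  n_design <- min(nrow(g), n_single_tissue + n_uniform)
  didx <- sample.int(nrow(g), n_design)
  single <- didx[seq_len(min(n_single_tissue, n_design))]
  uniform <- setdiff(didx, single)
  design <- NULL
  if (length(single)) {
    tcol <- sample.int(tissue_count, length(single), replace = TRUE)
    tissue[single, ] <- 0
    tissue[cbind(single, tcol)] <- 2^g$base_expr[single]
    design <- data.frame(gene_id = g$gene_id[single], design = "single_tissue",
                         tissue = colnames(tissue)[tcol], stringsAsFactors = FALSE)
  }
  if (length(uniform)) {
    tissue[uniform, ] <- matrix(2^g$base_expr[uniform], length(uniform),
                                tissue_count)
    design <- rbind(design,
                    data.frame(gene_id = g$gene_id[uniform], design = "uniform",
                               tissue = NA_character_, stringsAsFactors = FALSE))
  }
  list(expr = expr, groups = groups, tissue = tissue, tissue_design = design)
}

#' Simulate an EpiMark-style qPCR Cq table
#'
#' Forward model of the glucosylation/restriction assay at a CCGG site. With
#' locus fractions (f_5hmC, f_5mC, f_C), the surviving template fraction per
#' reaction is: MspI with glucosylation, f_5hmC (glucosyl-5hmC resists MspI);
#' MspI without glucosylation, 0 (MspI cuts regardless of methylation); HpaII
#' in either state, f_5hmC + f_5mC (HpaII is blocked by any CpG
#' modification); uncut, 1. Cq = cq_uncut - log2(f); complete digestion
#' (f below the detectable range) reports the Cq ceiling.
#'
#' The three states are intended to partition the template molecules at the
#' site. A shortfall (fractions summing to < 1) is tolerated and behaves
#' like unmodified C in the chemistry (it is cut by HpaII), so the
#' quantification recovers `1 - f_5hmc - f_5mc` as the unmodified fraction;
#' the inversion is exact for triples summing to 1.
#'
#' @param true_fractions data.frame with `locus`, `f_5hmc`, `f_5mc`, `f_c`
#'   (each in \[0,1\], summing to <= 1), or an unnamed numeric length-3
#'   vector for a single locus.
#' @param cq_uncut Cq of the uncut reaction (cycles).
#' @param noise_sd per-reaction Gaussian Cq noise (cycles).
#' @param n_replicates replicate reactions per locus.
#' @param cq_ceiling maximum reportable Cq; encodes complete digestion.
#' @param seed integer seed.
#' @return data.frame with `locus`, `glucosylated`, `digest`, `replicate`,
#'   `cq` (six reactions per locus and replicate).
#' @export
simulate_epimark_cq <- function(true_fractions, cq_uncut = 20, noise_sd = 0,
                                n_replicates = 1, cq_ceiling = 40, seed = 1) {
  if (is.numeric(true_fractions) && length(true_fractions) == 3) {
    true_fractions <- data.frame(locus = "locus1",
                                 f_5hmc = true_fractions[1],
                                 f_5mc = true_fractions[2],
                                 f_c = true_fractions[3])
  }
  stopifnot(all(c("locus", "f_5hmc", "f_5mc", "f_c") %in% names(true_fractions)),
            cq_uncut > 0, cq_uncut < cq_ceiling, noise_sd >= 0)
  f <- true_fractions
  if (any(f$f_5hmc < 0 | f$f_5mc < 0 | f$f_c < 0) ||
      any(f$f_5hmc > 1 | f$f_5mc > 1 | f$f_c > 1) ||
      any(f$f_5hmc + f$f_5mc + f$f_c > 1 + 1e-9)) {
    stop("fractions must lie in [0,1] and sum to <= 1 per locus")
  }
  set.seed(seed)
  grid <- expand.grid(locus = f$locus, glucosylated = c(TRUE, FALSE),
                      digest = c("MspI", "HpaII", "uncut"),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- match(grid$locus, f$locus)
  surv <- ifelse(grid$digest == "uncut", 1,
          ifelse(grid$digest == "HpaII", f$f_5hmc[li] + f$f_5mc[li],
          ifelse(grid$glucosylated, f$f_5hmc[li], 0)))
  floor_f <- 2^(cq_uncut - cq_ceiling)
  cq <- ifelse(surv < floor_f, cq_ceiling, cq_uncut - log2(pmax(surv, floor_f)))
  if (noise_sd > 0) cq <- cq + stats::rnorm(length(cq), 0, noise_sd)
  grid$cq <- pmin(cq, cq_ceiling)
  grid[order(grid$locus, grid$replicate, !grid$glucosylated, grid$digest), ]
}
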