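# Treatment-induced changes per gene and region: expression fold changes,
# induced/unaffected gene selection, change correlations, TSS change
# profiles, and the gene-family region analysis.

#' Per-gene expression change between groups
#'
#' Log2 fold change (mean treated - mean control, on already-log2 data) with
#' a Welch two-sample t-test p-value per gene.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param groups named character vector, sample -> group label.
#' @param control,treated group labels (>= 2 samples each).
#' @return data.frame with `gene_id`, `lfc`, `t`, `p`.
#' @export
expression_change <- function(expr, groups, control = "control",
                              treated = "treated") {
  grp <- groups[colnames(expr)]
  a <- expr[, grp == control, drop = FALSE]
  b <- expr[, grp == treated, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 samples per group")
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(gene_id = rownames(expr), lfc = m2 - m1, t = tstat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select induced genes
#'
#' Genes whose expression log2 fold change strictly exceeds the threshold,
#' in stable input order.
#'
#' @param changes data.frame from [expression_change()].
#' @param threshold log2 induction threshold.
#' @return character vector of gene ids.
#' @export
select_induced <- function(changes, threshold = 1.5) {
  changes$gene_id[!is.na(changes$lfc) & changes$lfc > threshold]
}

#' Select expression-unaffected control genes
#'
#' Genes with |lfc| below `lfc_band` and p above `p_min`, down-sampled to
#' `n` (seeded) to match the induced-set size.
#'
#' @param changes data.frame from [expression_change()].
#' @param n number of genes wanted.
#' @param lfc_band,p_min selection bands.
#' @param seed integer seed for the down-sampling.
#' @return character vector of gene ids.
#' @export
select_unaffected <- function(changes, n, lfc_band = 0.1, p_min = 0.5,
                              seed = 1) {
  ok <- changes$gene_id[!is.na(changes$lfc) & abs(changes$lfc) < lfc_band &
                          changes$p > p_min]
  if (length(ok) <= n) {
    if (length(ok) < n) {
      message("only ", length(ok), " unaffected candidates for requested ", n)
    }
    return(ok)
  }
  set.seed(seed)
  sort(ok[sample.int(length(ok), n)])
}

#' Correlation of an epigenetic change with expression change
#'
#' Pearson correlation between a per-gene mark change and the expression
#' log2 fold change within a gene subset, with the usual t-transform
#' p-value (df = n - 2).
#'
#' @param records data.frame with `gene_id`, `lfc`, and mark-change columns.
#' @param subset gene ids to correlate over (>= 3).
#' @param mark name of the change column in `records`.
#' @return list with `r`, `p`, `n`.
#' @export
change_correlation <- function(records, subset, mark) {
  stopifnot(mark %in% names(records))
  d <- records[records$gene_id %in% subset, ]
  d <- d[stats::complete.cases(d[, c("lfc", mark)]), ]
  if (nrow(d) < 3) stop("subset has fewer than 3 genes with complete data")
  ct <- stats::cor.test(d[[mark]], d$lfc, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' TSS-centred profile of treatment changes
#'
#' Sliding-window (default 200/50 bp) profile of a per-probe change track
#' around the TSSs of a gene subset, strand-aware.
#'
#' @param probes probe table or `probe_track`.
#' @param delta_scores per-probe change vector (treated - control).
#' @param ann a `genome_annotation`.
#' @param gene_ids subset of genes (non-empty).
#' @param span,window,step profile parameters in bp.
#' @return A `meta_profile` data.frame.
#' @export
change_profile <- function(probes, delta_scores, ann, gene_ids,
                           span = 3000, window = 200, step = 50) {
  if (length(gene_ids) == 0) stop("gene subset is empty")
  anchors <- tss_table(ann)
  anchors <- anchors[anchors$gene_id %in% gene_ids, ]
  meta_profile(probes, delta_scores, anchors, span = span, window = window,
               step = step)
}

#' Gene-family region analysis of epigenetic changes
#'
#' For every region kind and mark, compares the family genes' changes with
#' the unaffected genes' changes: mean change, standard error, two-sided
#' Wilcoxon rank-sum p-value, a significance flag at `p_cutoff`, and the
#' fold enrichment of the family mean over the unaffected mean absolute
#' change.
#'
#' @param region_deltas long data.frame with `gene_id`, `region`, `mark`,
#'   `delta`.
#' @param family_ids,unaffected_ids gene-id sets (>= 3 genes each).
#' @param p_cutoff flag threshold on the raw Wilcoxon p-value.
#' @return data.frame with `region`, `mark`, `mean_change`, `se`,
#'   `unaffected_mean`, `p`, `flagged`, `fold_enrichment`.
#' @export
family_region_analysis <- function(region_deltas, family_ids, unaffected_ids,
                                   p_cutoff = 0.005) {
  stopifnot(all(c("gene_id", "region", "mark", "delta") %in%
                  names(region_deltas)))
  if (length(family_ids) < 3 || length(unaffected_ids) < 3) {
    stop("both gene sets need >= 3 genes")
  }
  cells <- unique(region_deltas[, c("region", "mark")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- region_deltas[region_deltas$region == cells$region[i] &
                         region_deltas$mark == cells$mark[i], ]
    x <- d$delta[d$gene_id %in% family_ids]
    y <- d$delta[d$gene_id %in% unaffected_ids]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) return(NULL)
    p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    data.frame(region = cells$region[i], mark = cells$mark[i],
               mean_change = mean(x), se = stats::sd(x) / sqrt(length(x)),
               unaffected_mean = mean(y), p = p, flagged = p < p_cutoff,
               fold_enrichment = if (mean(abs(y)) > 0)
                 mean(x) / mean(abs(y)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene region changes for all genic region kinds
#'
#' Computes, for a per-probe change track, the mean change over each gene's
#' upstream, promoter, exon, intron and downstream windows plus the PPR and
#' whole gene body, as a long table suitable for
#' [family_region_analysis()].
#'
#' @param probes probe table or `probe_track`.
#' @param delta_scores per-probe change vector.
#' @param ann a `genome_annotation`.
#' @param scheme a [category_scheme()].
#' @param ppr_halfwidth PPR half-width in bp.
#' @param mark label stored in the `mark` column.
#' @return long data.frame with `gene_id`, `region`, `mark`, `delta`.
#' @export
gene_region_deltas <- function(probes, delta_scores, ann,
                               scheme = category_scheme(),
                               ppr_halfwidth = 1000, mark = "5hmC") {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  wins <- .scheme_windows(ann, scheme)
  tt <- tss_table(ann)
  g <- ann$genes
  extra <- rbind(
    data.frame(category = "ppr", gene_id = tt$gene_id, chrom = tt$chrom,
               start = pmax(0, tt$tss - ppr_halfwidth),
               end = tt$tss + ppr_halfwidth, tss = tt$tss,
               stringsAsFactors = FALSE),
    data.frame(category = "gene_body", gene_id = g$gene_id, chrom = g$chrom,
               start = g$tx_start, end = g$tx_end,
               tss = tt$tss[match(g$gene_id, tt$gene_id)],
               stringsAsFactors = FALSE)
  )
  wins <- rbind(wins, extra)
  out <- lapply(split(wins, wins$category), function(wc) {
    v <- gene_window_means(probes, delta_scores,
                           wc[, c("gene_id", "chrom", "start", "end")])
    data.frame(gene_id = names(v), region = wc$category[1], mark = mark,
               delta = unname(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
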