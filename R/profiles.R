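# TSS-centred sliding-window meta-profiles, expression tiers, gene-body
# profiles and the promoter-proximal-region (PPR) heat map.

#' Quartile expression tiers
#'
#' Splits genes into low (bottom 25% of expression), high (top 25%) and
#' medium (the rest). Ties are broken by stable gene order, so the tier sizes
#' are always 25/50/25 up to rounding.
#'
#' @param expr named numeric vector of (mean) expression per gene (>= 4
#'   genes).
#' @return Named factor with levels `low < medium < high`.
#' @export
expression_tiers <- function(expr) {
  n <- length(expr)
  if (n < 4) stop("expression tiers need >= 4 genes")
  n_low <- round(n / 4)
  n_high <- round(n / 4)
  ord <- order(expr)                      # stable: ties keep input order
  tier <- rep("medium", n)
  tier[ord[seq_len(n_low)]] <- "low"
  tier[ord[seq(n - n_high + 1, n)]] <- "high"
  factor(stats::setNames(tier, names(expr)), levels = c("low", "medium", "high"))
}

# strand-aware TSS-relative probe offsets near a set of anchors; returns a
# data.frame(gene_id, rel, score)
.anchor_probes <- function(probes, scores, anchors, reach) {
  sl <- unique(c(as.character(probes$chrom), as.character(anchors$chrom)))
  mid <- .probe_mid(probes)
  win <- data.frame(chrom = anchors$chrom,
                    start = pmax(0, anchors$tss - reach),
                    end = anchors$tss + reach)
  hits <- GenomicRanges::findOverlaps(.as_granges(win, sl),
                                      .point_granges(probes$chrom, mid, sl))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh) == 0) return(NULL)
  rel <- ifelse(anchors$strand[qh] == "+",
                mid[sh] - anchors$tss[qh],
                anchors$tss[qh] - mid[sh])
  data.frame(gene_id = anchors$gene_id[qh], rel = rel, score = scores[sh],
             stringsAsFactors = FALSE)
}

#' TSS-centred sliding-window meta-profile
#'
#' For each offset (window centre) the probes whose midpoint falls inside
#' the `window`-bp window, in TSS-relative strand-flipped coordinates, are
#' averaged per gene; the profile value is the mean over genes. The number
#' of offsets is `(2 * span - window) / step + 1`.
#'
#' @param probes probe table or `probe_track`.
#' @param scores numeric probe score vector aligned with `probes` (a group
#'   mean or a change track).
#' @param anchors data.frame with `gene_id`, `chrom`, `tss`, `strand`
#'   (e.g. from [tss_table()]).
#' @param span profile half-width in bp (multiple of `step`).
#' @param window sliding window size in bp.
#' @param step window step in bp.
#' @return A `meta_profile` data.frame with `offset`, `mean`, `n_genes`.
#' @export
meta_profile <- function(probes, scores, anchors, span = 1500, window = 200,
                         step = 50) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  stopifnot(span > 0, window > 0, step > 0, span %% step == 0)
  ap <- .anchor_probes(probes, scores, anchors, reach = span + window)
  if (is.null(ap)) stop("no probes near any anchor")
  offsets <- seq(-(span - window / 2), span - window / 2, by = step)
  rows <- lapply(offsets, function(o) {
    sel <- ap$rel >= o - window / 2 & ap$rel < o + window / 2 & !is.na(ap$score)
    if (!any(sel)) {
      return(data.frame(offset = o, mean = NA_real_, n_genes = 0L))
    }
    gm <- tapply(ap$score[sel], ap$gene_id[sel], mean)
    data.frame(offset = o, mean = mean(gm), n_genes = length(gm))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("meta_profile", "data.frame")
  attr(out, "params") <- list(span = span, window = window, step = step,
                              membership = "probe midpoint")
  out
}

#' Gene-body profile of short genes, stratified by expression tier
#'
#' Profiles probe scores from the TSS through the body of fully tiled short
#' genes (plus flanks) in absolute bp, separately per expression tier.
#' Offsets past a gene's end simply stop receiving contributions from it (no
#' length scaling). Empty tiers are omitted with a message.
#'
#' @param probes probe table or `probe_track`.
#' @param scores probe score vector.
#' @param ann a `genome_annotation`.
#' @param gene_ids genes to profile (e.g. complete genes 2-3 kb long).
#' @param tiers named factor from [expression_tiers()].
#' @param flank flank size in bp on each side.
#' @param window,step sliding window parameters in bp.
#' @return data.frame with `tier`, `offset`, `mean`, `n_genes` (offset 0 =
#'   TSS, increasing toward the transcript end).
#' @export
gene_body_profile <- function(probes, scores, ann, gene_ids, tiers,
                              flank = 1000, window = 200, step = 50) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  g <- ann$genes[match(gene_ids, ann$genes$gene_id), ]
  if (any(is.na(g$gene_id))) stop("unknown gene id(s)")
  anchors <- tss_table(ann)
  anchors <- anchors[match(gene_ids, anchors$gene_id), ]
  reach <- max(g$length) + flank + window
  ap <- .anchor_probes(probes, scores, anchors, reach)
  if (is.null(ap)) stop("no probes near any anchor")
  ap$len <- g$length[match(ap$gene_id, g$gene_id)]
  ap <- ap[ap$rel >= -(flank + window) & ap$rel <= ap$len + flank + window, ]
  offsets <- seq(-flank, max(g$length) + flank, by = step)
  out <- NULL
  for (tr in levels(tiers)) {
    ids <- intersect(gene_ids, names(tiers)[tiers == tr])
    if (length(ids) == 0) {
      message("tier '", tr, "' is empty; omitted")
      next
    }
    sub <- ap[ap$gene_id %in% ids, ]
    rows <- lapply(offsets, function(o) {
      sel <- sub$rel >= o - window / 2 & sub$rel < o + window / 2 &
        !is.na(sub$score) & o <= sub$len + flank
      if (!any(sel)) return(NULL)
      gm <- tapply(sub$score[sel], sub$gene_id[sel], mean)
      data.frame(tier = tr, offset = o, mean = mean(gm), n_genes = length(gm),
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  out$tier <- factor(out$tier, levels = levels(tiers))
  out
}

#' Per-gene PPR mean scores
#'
#' Mean probe score (probe midpoint membership) over the promoter proximal
#' region, TSS +/- `halfwidth`, per gene and per sample column.
#'
#' @param probes probe table or `probe_track`.
#' @param scores numeric vector or probe x sample matrix.
#' @param ann a `genome_annotation`.
#' @param halfwidth PPR half-width in bp.
#' @return matrix (genes x samples) of PPR means, or a named vector when
#'   `scores` is a vector. Genes without probes get `NA`.
#' @export
ppr_means <- function(probes, scores, ann, halfwidth = 1000) {
  if (inherits(probes, "probe_track")) {
    if (missing(scores)) scores <- probes$scores
    probes <- probes$probes
  }
  tt <- tss_table(ann)
  wins <- data.frame(gene_id = tt$gene_id, chrom = tt$chrom,
                     start = pmax(0, tt$tss - halfwidth),
                     end = tt$tss + halfwidth, stringsAsFactors = FALSE)
  gene_window_means(probes, scores, wins)
}

#' Mean probe score over arbitrary per-gene windows
#' @param probes probe table.
#' @param scores vector or matrix of probe scores.
#' @param windows data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return matrix (or named vector) of per-gene means.
#' @export
gene_window_means <- function(probes, scores, windows) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  vec <- is.null(dim(scores))
  m <- if (vec) matrix(scores, ncol = 1, dimnames = list(NULL, "score")) else scores
  sl <- unique(c(as.character(probes$chrom), as.character(windows$chrom)))
  mid <- .probe_mid(probes)
  hits <- GenomicRanges::findOverlaps(.as_granges(windows, sl),
                                      .point_granges(probes$chrom, mid, sl))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  genes <- unique(windows$gene_id)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  if (length(qh)) {
    gid <- windows$gene_id[qh]
    for (j in seq_len(ncol(m))) {
      v <- tapply(m[sh, j], gid, mean, na.rm = TRUE)
      out[names(v), j] <- v
    }
  }
  if (vec) out[, 1] else out
}

# deterministic leaf order for an hclust merge matrix: at every junction the
# subtree with fewer leaves goes first; ties by smallest member index
.deterministic_leaf_order <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(list(order = -node, size = 1L, min = -node))
    a <- rec(merge[node, 1]); b <- rec(merge[node, 2])
    if (b$size < a$size || (b$size == a$size && b$min < a$min)) {
      tmp <- a; a <- b; b <- tmp
    }
    list(order = c(a$order, b$order), size = a$size + b$size,
         min = min(a$min, b$min))
  }
  rec(nrow(merge))$order
}

#' Clipped, Ward-clustered PPR heat-map matrix
#'
#' Clips per-animal PPR means to `[-clip, clip]` and orders rows by
#' agglomerative clustering with Euclidean distance and Ward linkage
#' (squared-Euclidean update). The leaf order is made deterministic: at each
#' merge the smaller subtree (ties: the one containing the smallest row
#' index) comes first.
#'
#' @param mat numeric matrix of PPR means, rows = PPRs, columns = animals
#'   (>= 2 rows).
#' @param clip clipping bound in log2 units.
#' @param cluster logical; order rows by clustering.
#' @return list with `matrix` (clipped, rows reordered), `row_order`,
#'   `hclust` (or `NULL`).
#' @export
ppr_heatmap <- function(mat, clip = 2.5, cluster = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  cm <- pmin(pmax(mat, -clip), clip)
  if (!cluster) {
    return(list(matrix = cm, row_order = seq_len(nrow(cm)), hclust = NULL))
  }
  keep <- rowSums(is.na(cm)) == 0
  hc <- stats::hclust(stats::dist(cm[keep, , drop = FALSE]), method = "ward.D2")
  ord_kept <- .deterministic_leaf_order(hc$merge)
  row_order <- c(which(keep)[ord_kept], which(!keep))
  list(matrix = cm[row_order, , drop = FALSE], row_order = row_order,
       hclust = hc)
}
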