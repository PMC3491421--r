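# Unique assignment of probes/peaks to six genic categories, distribution
# statistics, and feature (CGI / shore / enhancer) overlap.

#' Six-category genic classification scheme
#'
#' Windows are TSS-relative and strand-aware; the promoter is
#' TSS-1 kb..TSS+250 bp, upstream extends to the array's upstream tiling
#' reach, downstream 1 kb past the transcript end. Precedence resolves
#' intervals falling in several windows to exactly one category.
#'
#' @param promoter c(upstream, downstream) promoter window in bp relative to
#'   the TSS.
#' @param upstream c(from, to) upstream window in bp relative to the TSS.
#' @param downstream_len downstream window length past the transcript end, bp.
#' @param precedence category order used for unique assignment.
#' @return A `category_scheme` list.
#' @export
category_scheme <- function(promoter = c(-1000, 250),
                            upstream = c(-7250, -1000),
                            downstream_len = 1000,
                            precedence = c("promoter", "exon", "intron",
                                           "downstream", "upstream",
                                           "intergenic")) {
  stopifnot(promoter[1] < promoter[2], upstream[1] < upstream[2],
            downstream_len > 0,
            setequal(precedence, c("promoter", "exon", "intron", "downstream",
                                   "upstream", "intergenic")))
  structure(list(promoter = promoter, upstream = upstream,
                 downstream_len = downstream_len, precedence = precedence),
            class = "category_scheme")
}

# windows of one kind for all genes, strand-aware, as a data.frame
.scheme_windows <- function(ann, scheme) {
  g <- ann$genes
  tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  plus <- g$strand == "+"
  win <- function(category, lo_rel, hi_rel) {
    # lo_rel/hi_rel relative to TSS in transcript orientation
    start <- ifelse(plus, tss + lo_rel, tss - hi_rel)
    end <- ifelse(plus, tss + hi_rel, tss - lo_rel)
    data.frame(category = category, gene_id = g$gene_id, chrom = g$chrom,
               start = pmax(0, start), end = end, tss = tss,
               stringsAsFactors = FALSE)
  }
  promoter <- win("promoter", scheme$promoter[1], scheme$promoter[2])
  upstream <- win("upstream", scheme$upstream[1], scheme$upstream[2])
  dl <- scheme$downstream_len
  downstream <- data.frame(
    category = "downstream", gene_id = g$gene_id, chrom = g$chrom,
    start = pmax(0, ifelse(plus, g$tx_end, g$tx_start - dl)),
    end = ifelse(plus, g$tx_end + dl, g$tx_start), tss = tss,
    stringsAsFactors = FALSE
  )
  ex <- ann$exons
  ex$tss <- tss[match(ex$gene_id, g$gene_id)]
  exon <- data.frame(category = "exon", gene_id = ex$gene_id, chrom = ex$chrom,
                     start = ex$start, end = ex$end, tss = ex$tss,
                     stringsAsFactors = FALSE)
  # introns: gene body minus exons
  introns <- lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(category = "intron", gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1], tss = e$tss[1],
               stringsAsFactors = FALSE)
  })
  intron <- do.call(rbind, introns)
  out <- rbind(promoter, exon, intron, downstream, upstream)
  out[out$end > out$start, ]
}

#' Assign intervals uniquely to one of six genic categories
#'
#' The interval midpoint is tested against every gene's strand-aware windows;
#' among the windows containing it the category of highest precedence wins,
#' and the gene context is the gene whose TSS is nearest the midpoint among
#' the winning-category hits. Midpoints in no window are intergenic.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (peaks or
#'   probes).
#' @param ann A `genome_annotation`.
#' @param scheme a [category_scheme()].
#' @return data.frame with `category` (factor over the six labels) and
#'   `gene_id` (`NA` for intergenic), one row per interval.
#' @export
assign_category <- function(intervals, ann, scheme = category_scheme()) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (inherits(intervals, "peak_set")) intervals <- intervals$peaks
  if (!all(intervals$chrom %in% names(ann$chromosomes))) {
    stop("interval(s) on unknown chromosome")
  }
  n <- nrow(intervals)
  mid <- floor((intervals$start + intervals$end) / 2)
  wins <- .scheme_windows(ann, scheme)
  sl <- names(ann$chromosomes)
  hits <- GenomicRanges::findOverlaps(.point_granges(intervals$chrom, mid, sl),
                                      .as_granges(wins, sl))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  cat_out <- rep("intergenic", n)
  gene_out <- rep(NA_character_, n)
  if (length(qh)) {
    prec <- match(wins$category[sh], scheme$precedence)
    dist <- abs(mid[qh] - wins$tss[sh])
    o <- order(qh, prec, dist, wins$gene_id[sh])
    keep <- o[!duplicated(qh[o])]
    cat_out[qh[keep]] <- wins$category[sh[keep]]
    gene_out[qh[keep]] <- wins$gene_id[sh[keep]]
  }
  data.frame(category = factor(cat_out, levels = scheme$precedence),
             gene_id = gene_out, stringsAsFactors = FALSE)
}

#' Chi-square test of a category distribution against the array background
#'
#' Pearson chi-square of observed category counts (e.g. peak probes) with
#' expected proportions taken from the all-probe distribution. Categories
#' with zero expected count are collapsed into the smallest non-empty
#' category, with a warning.
#'
#' @param observed named vector of category counts for the tested set.
#' @param expected_counts named vector of category counts for the reference
#'   set (same names).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
distribution_chi2 <- function(observed, expected_counts) {
  stopifnot(length(observed) == length(expected_counts),
            setequal(names(observed), names(expected_counts)))
  expected_counts <- expected_counts[names(observed)]
  p <- expected_counts / sum(expected_counts)
  if (any(p == 0)) {
    warning("collapsing ", sum(p == 0),
            " categor(ies) with zero expected count")
    zero <- p == 0
    target <- names(which.min(replace(p, zero, Inf)))
    observed[target] <- observed[target] + sum(observed[zero])
    observed <- observed[!zero]
    p <- p[!zero] / sum(p[!zero])
  }
  E <- sum(observed) * p
  stat <- sum((observed - E)^2 / E)
  df <- length(observed) - 1
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}

#' Coverage-normalized category distribution
#'
#' Divides per-category peak counts by the number of probes covering each
#' category (removing the array's coverage bias) and rescales to proportions
#' summing to one.
#'
#' @param peak_counts named per-category counts of peaks (or peak probes).
#' @param probe_counts named per-category probe counts (> 0 wherever peaks
#'   are reported).
#' @return named vector of normalized proportions.
#' @export
coverage_normalized_distribution <- function(peak_counts, probe_counts) {
  stopifnot(setequal(names(peak_counts), names(probe_counts)))
  probe_counts <- probe_counts[names(peak_counts)]
  if (any(probe_counts == 0 & peak_counts > 0)) {
    stop("peaks reported in categories with zero probe coverage: ",
         paste(names(peak_counts)[probe_counts == 0 & peak_counts > 0],
               collapse = ", "))
  }
  ratio <- ifelse(probe_counts > 0, peak_counts / probe_counts, 0)
  if (sum(ratio) == 0) return(ratio)
  ratio / sum(ratio)
}

#' Overlap of peaks with a feature set, counted over probes
#'
#' A probe is a feature probe if its interval intersects any feature (e.g.
#' CGIs, CGI shores, 1 kb enhancer elements); the reported fraction is the
#' share of feature probes residing in peaks.
#'
#' @param peakset a `peak_set`.
#' @param features data.frame with `chrom`, `start`, `end`.
#' @param probes probe table or `probe_track` (the probe universe).
#' @return list with `n_feature_probes`, `n_in_peaks`, `fraction`.
#' @export
feature_overlap <- function(peakset, features, probes) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  if (is.null(features) || nrow(features) == 0) stop("empty feature set")
  sl <- unique(c(as.character(probes$chrom), as.character(features$chrom)))
  hits <- GenomicRanges::countOverlaps(.as_granges(probes, sl),
                                       .as_granges(features, sl))
  fp <- probes$probe_id[hits > 0]
  if (length(fp) == 0) stop("features cover no probes on the array")
  in_pk <- fp %in% peak_probes(peakset)
  list(n_feature_probes = length(fp), n_in_peaks = sum(in_pk),
       fraction = mean(in_pk))
}

#' CGI shores (1 kb regions upstream of CpG islands)
#'
#' @param ann a `genome_annotation`.
#' @param width shore width in bp.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
cgi_shores <- function(ann, width = 1000) {
  cg <- ann$cgis
  if (is.null(cg) || nrow(cg) == 0) stop("annotation has no CGIs")
  data.frame(chrom = cg$chrom, start = pmax(0, cg$start - width),
             end = cg$start, stringsAsFactors = FALSE)
}

#' Compare mean probe scores between two region sets
#'
#' Scores each region by the mean of the probes it overlaps and compares the
#' two sets with a two-sided Wilcoxon rank-sum test (e.g. 1 kb enhancer
#' regions versus 1 kb promoter regions). Regions covered by no probe are
#' dropped.
#'
#' @param probes probe table or `probe_track`.
#' @param scores numeric probe score vector aligned with `probes`.
#' @param regions_a,regions_b data.frames with `chrom`, `start`, `end`
#'   (>= 2 scoreable regions each).
#' @return list with `mean_a`, `mean_b`, `region_means_a`,
#'   `region_means_b`, `p_value`.
#' @export
region_level_compare <- function(probes, scores, regions_a, regions_b) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  region_means <- function(regions) {
    if (is.null(regions) || nrow(regions) < 2) {
      stop("each region set needs >= 2 regions")
    }
    sl <- unique(c(as.character(probes$chrom), as.character(regions$chrom)))
    hits <- GenomicRanges::findOverlaps(.as_granges(regions, sl),
                                        .as_granges(probes, sl))
    qh <- S4Vectors::queryHits(hits)
    vals <- scores[S4Vectors::subjectHits(hits)]
    out <- tapply(vals, qh, mean, na.rm = TRUE)
    as.numeric(out)
  }
  ma <- region_means(regions_a)
  mb <- region_means(regions_b)
  if (length(ma) < 2 || length(mb) < 2) stop("fewer than 2 scoreable regions in a set")
  wt <- stats::wilcox.test(ma, mb, exact = FALSE)
  list(mean_a = mean(ma), mean_b = mean(mb),
       region_means_a = ma, region_means_b = mb,
       p_value = wt$p.value)
}
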