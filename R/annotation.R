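# Genome annotation container and simulator.
#
# All public interval tables are 0-based, half-open [start, end), BED-style.
# GRanges objects used internally are converted with .as_granges().

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param seqlevels optional character vector of chromosome names fixing the
#'   seqlevel order.
#' @return A [GenomicRanges::GRanges] (1-based, closed).
#' @keywords internal
.as_granges <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(as.character(df$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L))
  )
}

.point_granges <- function(chrom, pos, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(as.character(chrom))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

#' Transcription start sites of an annotation
#'
#' The TSS of a plus-strand gene is `tx_start`; of a minus-strand gene,
#' `tx_end`. Coordinates are genomic (0-based).
#'
#' @param ann A `genome_annotation`.
#' @return data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
tss_table <- function(ann) {
  g <- ann$genes
  data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    tss = ifelse(g$strand == "+", g$tx_start, g$tx_end),
    strand = g$strand, stringsAsFactors = FALSE
  )
}

#' Simulate a promoter-array genome annotation
#'
#' Generates a small genome with non-overlapping genes on both strands,
#' exon/intron structure, CpG islands over a fraction of promoters (plus a few
#' intra-genic ones), intergenic enhancer elements, and the tiled regions a
#' promoter array would cover: a strand-aware window from `upstream_reach`
#' upstream of each TSS to `downstream_reach` downstream, which for genes
#' shorter than `downstream_reach` contains the entire gene body, plus a
#' window over each enhancer. Overlapping tiled windows are merged so tiled
#' regions are disjoint.
#'
#' Each gene also carries a latent baseline log2 expression level
#' (`base_expr`) used by the signal and expression simulators so that planted
#' epigenetic structure and expression tiers agree.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param short_gene_fraction fraction of genes drawn 2-3 kb long (fully
#'   covered by the array, used for gene-body profiles).
#' @param cgi_promoter_fraction fraction of promoters carrying a CpG island.
#' @param cgi_body_fraction fraction of genes with an intra-genic CpG island.
#' @param enhancers_per_chrom intergenic 1 kb enhancers placed per chromosome.
#' @param min_gap minimum intergenic gap in bp.
#' @param upstream_reach,downstream_reach extent of the tiled window around
#'   each TSS, in bp.
#' @param seed integer seed; identical seeds give identical annotations.
#' @return A `genome_annotation` list with elements `chromosomes` (named
#'   lengths), `genes`, `exons`, `cgis`, `enhancers`, `tiled_regions`, and
#'   `params`.
#' @examples
#' ann <- simulate_annotation(n_genes = 20, n_chrom = 1, chrom_length = 1e6)
#' head(ann$genes)
#' @export
simulate_annotation <- function(n_genes = 200, n_chrom = 2, chrom_length = 5e6,
                                short_gene_fraction = 0.2,
                                cgi_promoter_fraction = 0.4,
                                cgi_body_fraction = 0.1,
                                enhancers_per_chrom = 20,
                                min_gap = 10000,
                                upstream_reach = 7250,
                                downstream_reach = 3000,
                                seed = 1) {
  stopifnot(n_genes >= 1, n_chrom >= 1, chrom_length > 0, min_gap > 0)
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  chromosomes <- stats::setNames(rep(chrom_length, n_chrom), chrom_names)
  per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1)))

  genes <- list(); exons <- list(); cgis <- list(); enhancers <- list()
  gid <- 0L
  for (ci in seq_len(n_chrom)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    n_short <- round(short_gene_fraction * k)
    lens <- c(round(stats::runif(n_short, 2000, 3000)),
              round(exp(stats::runif(k - n_short, log(3000), log(15000)))))
    lens <- lens[sample.int(k)]
    slack <- chrom_length - sum(lens) - (k + 1) * min_gap
    if (slack < 0) {
      stop("cannot place ", k, " non-overlapping genes of total length ",
           sum(lens), " bp on a ", chrom_length, " bp chromosome")
    }
    u <- stats::runif(k + 1)
    gaps <- min_gap + floor(slack * u / sum(u))
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, lens[-k]))
    ends <- starts + lens
    strand <- sample(c("+", "-"), k, replace = TRUE)
    ids <- sprintf("g%04d", gid + seq_len(k))
    gid <- gid + k

    genes[[ci]] <- data.frame(
      gene_id = ids, chrom = chrom_names[ci], strand = strand,
      tx_start = starts, tx_end = ends, length = lens,
      base_expr = stats::rnorm(k, mean = 8, sd = 2),
      cgi_promoter = FALSE, stringsAsFactors = FALSE
    )

    # exon/intron structure: 1-8 exons; genes begin and end with an exon
    ex <- lapply(seq_len(k), function(i) {
      n_ex <- sample(1:8, 1)
      n_seg <- 2L * n_ex - 1L
      if (n_seg == 1L) {
        data.frame(gene_id = ids[i], chrom = chrom_names[ci],
                   start = starts[i], end = ends[i], stringsAsFactors = FALSE)
      } else {
        cuts <- sort(sample(seq_len(lens[i] - 1L), n_seg - 1L))
        bounds <- c(0L, cuts, lens[i])
        odd <- seq(1L, n_seg, by = 2L)
        data.frame(gene_id = ids[i], chrom = chrom_names[ci],
                   start = starts[i] + bounds[odd],
                   end = starts[i] + bounds[odd + 1L],
                   stringsAsFactors = FALSE)
      }
    })
    exons[[ci]] <- do.call(rbind, ex)

    # CpG islands: a fraction of promoters, plus a few intra-genic islands
    tss <- ifelse(strand == "+", starts, ends)
    n_pcgi <- round(cgi_promoter_fraction * k)
    pidx <- if (n_pcgi > 0) sample(seq_len(k), n_pcgi) else integer(0)
    genes[[ci]]$cgi_promoter[pidx] <- TRUE
    pc <- if (length(pidx)) {
      s <- pmax(0, tss[pidx] - round(stats::runif(length(pidx), 200, 800)))
      data.frame(chrom = chrom_names[ci], start = s,
                 end = pmin(chrom_length, s + round(stats::runif(length(pidx), 500, 1500))),
                 context = "promoter", stringsAsFactors = FALSE)
    } else NULL
    bidx <- setdiff(seq_len(k), pidx)
    bidx <- if (length(bidx)) {
      bidx[sample.int(length(bidx), min(length(bidx), round(cgi_body_fraction * k)))]
    } else integer(0)
    bc <- if (length(bidx)) {
      mid <- floor((starts[bidx] + ends[bidx]) / 2)
      data.frame(chrom = chrom_names[ci], start = pmax(starts[bidx], mid - 250),
                 end = pmin(ends[bidx], mid + 250), context = "intragenic",
                 stringsAsFactors = FALSE)
    } else NULL
    cgis[[ci]] <- rbind(pc, bc)

    # enhancers: 1 kb elements in intergenic gaps clear of any gene window
    blocked <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, starts - upstream_reach - 500L),
      end = ends + upstream_reach + 500L
    ))
    free <- IRanges::gaps(blocked, start = 1L, end = chrom_length)
    free <- free[IRanges::width(free) >= 4000]
    if (length(free) > 0 && enhancers_per_chrom > 0) {
      pick <- sample(seq_along(free), min(length(free), enhancers_per_chrom))
      es <- vapply(pick, function(j) {
        lo <- IRanges::start(free)[j] + 1500L
        hi <- IRanges::end(free)[j] - 2500L
        as.integer(round(stats::runif(1, lo, max(lo, hi))))
      }, integer(1))
      enhancers[[ci]] <- data.frame(chrom = chrom_names[ci],
                                    start = es, end = es + 1000L,
                                    stringsAsFactors = FALSE)
    }
  }

  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  cgis <- do.call(rbind, cgis)
  enhancers <- do.call(rbind, enhancers)
  if (!is.null(cgis)) cgis$cgi_id <- sprintf("cgi%04d", seq_len(nrow(cgis)))
  if (!is.null(enhancers)) enhancers$enhancer_id <- sprintf("enh%04d", seq_len(nrow(enhancers)))

  # tiled regions: strand-aware TSS window per gene + each enhancer, merged
  tssv <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  t_start <- ifelse(genes$strand == "+", tssv - upstream_reach, tssv - downstream_reach)
  t_end <- ifelse(genes$strand == "+", tssv + downstream_reach, tssv + upstream_reach)
  tiles <- data.frame(chrom = genes$chrom, start = pmax(0, t_start),
                      end = pmin(chrom_length, t_end), stringsAsFactors = FALSE)
  if (!is.null(enhancers)) {
    tiles <- rbind(tiles, data.frame(chrom = enhancers$chrom,
                                     start = pmax(0, enhancers$start - 500L),
                                     end = pmin(chrom_length, enhancers$end + 500L),
                                     stringsAsFactors = FALSE))
  }
  tiled <- do.call(rbind, lapply(chrom_names, function(cn) {
    tc <- tiles[tiles$chrom == cn, , drop = FALSE]
    if (nrow(tc) == 0) return(NULL)
    red <- IRanges::reduce(IRanges::IRanges(start = tc$start + 1L, end = tc$end))
    data.frame(chrom = cn, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  }))
  tiled$region_id <- sprintf("tr_%s_%04d", tiled$chrom,
                             stats::ave(seq_len(nrow(tiled)), tiled$chrom, FUN = seq_along))

  ann <- structure(list(
    chromosomes = chromosomes, genes = genes, exons = exons,
    cgis = cgis, enhancers = enhancers, tiled_regions = tiled,
    params = list(n_genes = n_genes, n_chrom = n_chrom,
                  chrom_length = chrom_length, min_gap = min_gap,
                  upstream_reach = upstream_reach,
                  downstream_reach = downstream_reach, seed = seed)
  ), class = "genome_annotation")
  .validate_annotation(ann)
  ann
}

.validate_annotation <- function(ann) {
  g <- ann$genes
  stopifnot(!anyDuplicated(g$gene_id), all(g$tx_start < g$tx_end))
  for (cn in unique(g$chrom)) {
    gc <- g[g$chrom == cn, ]
    gc <- gc[order(gc$tx_start), ]
    if (nrow(gc) > 1 && any(gc$tx_start[-1] < gc$tx_end[-nrow(gc)])) {
      stop("overlapping genes generated on ", cn)
    }
  }
  ex <- merge(ann$exons, g[, c("gene_id", "tx_start", "tx_end")], by = "gene_id")
  stopifnot(all(ex$start >= ex$tx_start), all(ex$end <= ex$tx_end),
            all(ex$start < ex$end))
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "genes,",
      if (is.null(x$cgis)) 0 else nrow(x$cgis), "CGIs,",
      if (is.null(x$enhancers)) 0 else nrow(x$enhancers), "enhancers,",
      nrow(x$tiled_regions), "tiled regions\n")
  invisible(x)
}

#' Simulate promoter sequences with controlled CpG density
#'
#' Generates one sequence per gene spanning the promoter classification
#' window (TSS-1000..TSS+250 in transcript orientation). Promoters flagged as
#' CGI-associated in the annotation receive a high CpG density (> 6 per
#' 100 bp); the remainder are split between intermediate (1-5) and low (< 1)
#' densities. The background sequence is CpG-free so the realised density
#' equals the planted one up to rounding.
#'
#' @param ann A `genome_annotation`.
#' @param icp_fraction fraction of non-CGI promoters given intermediate
#'   density.
#' @param seed integer seed.
#' @return Named character vector of sequences (names = gene ids), with the
#'   planted density per 100 bp in attribute `"density"`.
#' @export
simulate_promoter_sequences <- function(ann, icp_fraction = 0.6, seed = 1) {
  set.seed(seed)
  g <- ann$genes
  len <- 1250L
  n <- nrow(g)
  dens <- numeric(n)
  dens[g$cgi_promoter] <- stats::runif(sum(g$cgi_promoter), 6, 10)
  rest <- which(!g$cgi_promoter)
  icp <- sample(rest, round(icp_fraction * length(rest)))
  dens[icp] <- stats::runif(length(icp), 1.2, 5)
  lcp <- setdiff(rest, icp)
  dens[lcp] <- stats::runif(length(lcp), 0.05, 0.9)

  seqs <- vapply(seq_len(n), function(i) {
    x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # strip accidental CpGs so density is fully controlled
    idx <- which(x[-len] == "C" & x[-1] == "G")
    if (length(idx)) x[idx + 1L] <- sample(c("A", "T"), length(idx), replace = TRUE)
    n_cpg <- round(dens[i] * len / 100)
    if (n_cpg > 0) {
      slots <- sample(seq(1L, len - 1L, by = 2L), n_cpg)
      x[slots] <- "C"; x[slots + 1L] <- "G"
    }
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- g$gene_id
  attr(seqs, "density") <- stats::setNames(dens, g$gene_id)
  seqs
}
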