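# Plain-text readers/writers for the pipeline's tables: probe tracks and
# per-sample bedGraph, peaks as BED6+, annotation as GFF3 + BED, truth
# ledger and manifest as JSON.

#' Write a probe track as TSV
#'
#' Column layout: probe columns, then one `score.<sample>.<group>` column
#' per sample and (if present) one `A.<sample>` intensity column, so the
#' file round-trips through [read_probe_track()].
#'
#' @param track a `probe_track`.
#' @param path output file.
#' @export
write_probe_track <- function(track, path) {
  stopifnot(inherits(track, "probe_track"))
  df <- track$probes
  for (s in colnames(track$scores)) {
    df[[paste("score", s, track$groups[[s]], sep = ".")]] <- track$scores[, s]
  }
  if (!is.null(track$intensity)) {
    for (s in colnames(track$intensity)) {
      df[[paste0("A.", s)]] <- track$intensity[, s]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe track written by [write_probe_track()]
#' @param path TSV file.
#' @param mark mark label to attach.
#' @return a `probe_track`.
#' @export
read_probe_track <- function(path, mark = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sc <- grep("^score\\.", names(df), value = TRUE)
  parts <- strsplit(sub("^score\\.", "", sc), ".", fixed = TRUE)
  samples <- vapply(parts, `[`, character(1), 1)
  groups <- stats::setNames(vapply(parts, `[`, character(1), 2), samples)
  scores <- as.matrix(df[, sc, drop = FALSE])
  colnames(scores) <- samples
  ac <- grep("^A\\.", names(df), value = TRUE)
  intensity <- NULL
  if (length(ac)) {
    intensity <- as.matrix(df[, ac, drop = FALSE])
    colnames(intensity) <- sub("^A\\.", "", ac)
    intensity <- intensity[, samples, drop = FALSE]
  }
  probes <- df[, c("chrom", "start", "end", "probe_id",
                   intersect("region_id", names(df))), drop = FALSE]
  probe_track(probes, scores, groups, intensity = intensity, mark = mark)
}

#' Write one sample of a probe track as bedGraph
#' @param track a `probe_track`.
#' @param sample sample name.
#' @param path output file.
#' @export
write_bedgraph <- function(track, sample, path) {
  stopifnot(sample %in% colnames(track$scores))
  df <- data.frame(track$probes$chrom, track$probes$start, track$probes$end,
                   round(track$scores[, sample], 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s.%s", track$mark, sample), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a peak set as BED6+
#'
#' Columns: chrom, start, end, peak id, mean log2 score, strand (`.`),
#' number of member probes, max score. The threshold and calling parameters
#' go into a `#` header line.
#'
#' @param peakset a `peak_set`.
#' @param path output file.
#' @export
write_peaks_bed <- function(peakset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%.6g q=%g k=%d w=%d max_gap=%d exceedance=%s",
                     peakset$threshold, peakset$params$q, peakset$params$k,
                     peakset$params$w, peakset$params$max_gap,
                     peakset$params$exceedance), con)
  p <- peakset$peaks
  if (nrow(p)) {
    utils::write.table(
      data.frame(p$chrom, p$start, p$end, p$peak_id,
                 round(p$mean_score, 4), ".", p$n_probes,
                 round(p$max_score, 4)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write an annotation as GFF3 + BED files
#'
#' Genes and exons go to `genes.gff3`; CGIs, enhancers and tiled regions to
#' BED files, all in `dir`.
#'
#' @param ann a `genome_annotation`.
#' @param dir output directory (created if missing).
#' @return invisible vector of written paths.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sl <- names(ann$chromosomes)
  g <- ann$genes
  gr_gene <- GenomicRanges::GRanges(
    seqnames = factor(g$chrom, sl),
    ranges = IRanges::IRanges(g$tx_start + 1L, g$tx_end),
    strand = g$strand, type = "gene", ID = g$gene_id
  )
  ex <- ann$exons
  gr_ex <- GenomicRanges::GRanges(
    seqnames = factor(ex$chrom, sl),
    ranges = IRanges::IRanges(ex$start + 1L, ex$end),
    strand = g$strand[match(ex$gene_id, g$gene_id)],
    type = "exon", Parent = ex$gene_id
  )
  paths <- file.path(dir, c("genes.gff3", "cgis.bed", "enhancers.bed",
                            "tiled_regions.bed"))
  rtracklayer::export.gff3(c(gr_gene, gr_ex), paths[1])
  bed <- function(df, name_col, path) {
    gr <- .as_granges(df, sl)
    names(gr) <- df[[name_col]]
    rtracklayer::export.bed(gr, path)
  }
  if (!is.null(ann$cgis)) bed(ann$cgis, "cgi_id", paths[2])
  if (!is.null(ann$enhancers)) bed(ann$enhancers, "enhancer_id", paths[3])
  bed(ann$tiled_regions, "region_id", paths[4])
  invisible(paths)
}

#' Write fragment libraries as BED
#' @param fragments fragment table (`chrom`, `start`, `end`).
#' @param path output file.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals as a 0-based half-open table
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (and `name` if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(names(gr))) out$name <- names(gr)
  out
}

#' Write a truth ledger as JSON
#' @param truth a `truth_ledger`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
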