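test_that("midpoints near a TSS classify as promoter on both strands", {
  s <- shared_sim()
  g <- s$ann$genes
  plus <- g[g$strand == "+", ][1, ]
  minus <- g[g$strand == "-", ][1, ]
  iv <- data.frame(
    chrom = c(plus$chrom, minus$chrom),
    start = c(plus$tx_start + 100 - 30, minus$tx_end - 100 - 30),
    end = c(plus$tx_start + 100 + 30, minus$tx_end - 100 + 30)
  )
  res <- assign_category(iv, s$ann)
  # plus strand: midpoint at TSS+100 is inside -1kb..+250
  expect_equal(as.character(res$category[1]), "promoter")
  expect_equal(res$gene_id[1], plus$gene_id)
  # minus strand: 100 bp before tx_end in genome coordinates is TSS+100 in
  # transcript orientation, hence promoter
  expect_equal(as.character(res$category[2]), "promoter")
  expect_equal(res$gene_id[2], minus$gene_id)
})

test_that("midpoints far from all genes are intergenic", {
  s <- shared_sim()
  g <- s$ann$genes
  ord <- order(g$tx_start)
  gs <- g[ord, ]
  gap_lo <- gs$tx_end[-nrow(gs)] + 9000
  gap_hi <- gs$tx_start[-1] - 9000
  ok <- which(gap_hi - gap_lo > 2000)[1]
  expect_false(is.na(ok))
  mid <- floor((gap_lo[ok] + gap_hi[ok]) / 2)
  # keep clear of enhancer-covered probes (enhancers carry no gene windows
  # anyway, so any such midpoint is intergenic)
  res <- assign_category(data.frame(chrom = gs$chrom[1], start = mid - 30,
                                    end = mid + 30), s$ann)
  expect_equal(as.character(res$category), "intergenic")
  expect_true(is.na(res$gene_id))
})

test_that("category assignment is total and conserves probe counts", {
  s <- shared_sim()
  res <- assign_category(s$hmc$probes, s$ann)
  expect_equal(nrow(res), nrow(s$hmc$probes))
  expect_false(any(is.na(res$category)))
  expect_equal(sum(table(res$category)), nrow(s$hmc$probes))
})

test_that("category assignment is invariant under genome mirroring", {
  s <- shared_sim()
  ann2 <- mirror_annotation(s$ann)
  L <- unname(s$ann$chromosomes[1])
  probes <- s$hmc$probes
  # even-span intervals map midpoints exactly under mirroring
  iv <- data.frame(chrom = probes$chrom, start = probes$start,
                   end = probes$start + 60)
  mid <- floor((iv$start + iv$end) / 2)
  # drop midpoints sitting exactly on a window boundary, where the half-open
  # convention necessarily flips side under mirroring
  g <- s$ann$genes
  tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  offs <- c(-7250, -1000, -250, 0, 250, 1000, 7250)
  B <- unique(c(outer(tss, offs, `+`),
                outer(g$tx_start, c(-1000, 0, 1000), `+`),
                outer(g$tx_end, c(-1000, 0, 1000), `+`),
                s$ann$exons$start, s$ann$exons$end))
  keep <- !(mid %in% B)
  iv <- iv[keep, ]
  res1 <- assign_category(iv, s$ann)
  iv2 <- data.frame(chrom = iv$chrom, start = L - iv$end, end = L - iv$start)
  res2 <- assign_category(iv2, ann2)
  expect_equal(as.character(res1$category), as.character(res2$category))
})

test_that("chi-square against the array background matches hand computation", {
  even <- c(a = 50, b = 50)
  res <- distribution_chi2(c(a = 90, b = 10), even)
  expect_equal(res$statistic, 64)         # (40^2/50) * 2
  expect_equal(res$df, 1)
  ref <- suppressWarnings(stats::chisq.test(c(90, 10), p = c(0.5, 0.5)))
  expect_equal(res$p_value, ref$p.value)
  same <- distribution_chi2(c(a = 30, b = 70), c(a = 3, b = 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(distribution_chi2(c(a = 5, b = 5, c = 0),
                                   c(a = 5, b = 5, c = 0)), "collapsing")
})

test_that("planted gene-body peaks skew the genic distribution", {
  s <- shared_sim()
  cats <- assign_category(s$hmc$probes, s$ann)
  ids <- peak_probes(s$peaks_hmc)
  obs <- table(cats$category[match(ids, s$hmc$probes$probe_id)])
  res <- distribution_chi2(c(obs), c(table(cats$category)))
  expect_lt(res$p_value, 0.001)
  # most 5hmC peak probes are genic (exon + intron), as planted
  genic <- (obs[["exon"]] + obs[["intron"]]) / sum(obs)
  expect_gt(genic, 0.5)
})

test_that("coverage normalization removes the array's coverage bias", {
  expect_equal(unname(coverage_normalized_distribution(
    c(a = 10, b = 20, c = 40), c(a = 100, b = 200, c = 400))),
    rep(1 / 3, 3))
  only_b <- coverage_normalized_distribution(c(a = 0, b = 9, c = 0),
                                             c(a = 10, b = 10, c = 10))
  expect_equal(unname(only_b), c(0, 1, 0))
  expect_error(coverage_normalized_distribution(c(a = 1), c(a = 0)),
               "zero probe coverage")
  # peak probes drawn proportionally to coverage come out uniform
  set.seed(7)
  cov <- c(a = 5000, b = 2000, c = 500)
  draw <- table(sample(names(cov), 800, TRUE, prob = cov / sum(cov)))
  norm <- coverage_normalized_distribution(c(draw)[names(cov)], cov)
  expect_true(all(abs(norm - 1 / 3) < 0.1))
})

test_that("feature overlap fractions behave at the extremes", {
  s <- shared_sim()
  expect_error(feature_overlap(s$peaks_hmc, s$ann$enhancers[0, ], s$hmc),
               "empty feature set")
  beyond <- max(s$ann$tiled_regions$end)
  far <- data.frame(chrom = "chr1", start = beyond + 1000, end = beyond + 2000)
  expect_error(feature_overlap(s$peaks_hmc, far, s$hmc), "cover no probes")
  # features equal to a called peak give fraction 1
  pk1 <- s$peaks_hmc$peaks[1, c("chrom", "start", "end")]
  pk1$start <- pk1$start + 40          # clip edge probes half outside
  pk1$end <- pk1$end - 40
  ov <- feature_overlap(s$peaks_hmc, pk1, s$hmc)
  expect_equal(ov$fraction, 1)
})

test_that("enhancers are 5hmC- but not 5mC-enriched in the default scenario", {
  s <- shared_sim()
  hm <- feature_overlap(s$peaks_hmc, s$ann$enhancers, s$hmc)
  mc <- feature_overlap(s$peaks_mc, s$ann$enhancers, s$mc)
  expect_gt(hm$fraction, mc$fraction)
})

test_that("region-level comparisons use rank-sum tests over region means", {
  set.seed(8)
  n <- 100
  starts_a <- seq(0, by = 5000, length.out = n)
  regions_a <- data.frame(chrom = "chr1", start = starts_a, end = starts_a + 1000)
  regions_b <- data.frame(chrom = "chr1", start = starts_a + 2000,
                          end = starts_a + 3000)
  m <- 5 * n
  starts_p <- seq(0, by = 1000, length.out = m)
  probes <- data.frame(chrom = "chr1", start = starts_p, end = starts_p + 60,
                       probe_id = sprintf("p%04d", 1:m), region_id = "tr1")
  base <- stats::rnorm(m, 0, 0.3)
  res_same <- region_level_compare(probes, base, regions_a, regions_a)
  expect_gte(res_same$p_value, 0.99)
  in_a <- probes$start %in% starts_a
  shifted <- base + ifelse(in_a, 1, 0)
  res_shift <- region_level_compare(probes, shifted, regions_a, regions_b)
  expect_lt(res_shift$p_value, 0.001)
  expect_gt(res_shift$mean_a - res_shift$mean_b, 0.5)
  expect_error(region_level_compare(probes, base, regions_a[1, , drop = FALSE],
                                    regions_b), ">= 2 regions")
})
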