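test_that("expression tiers cut 25/50/25 with stable tie-breaks", {
  e <- stats::setNames(c(5, 1, 3, 8, 2, 7, 4, 6), paste0("g", 1:8))
  tiers <- expression_tiers(e)
  expect_equal(as.integer(table(tiers)), c(2L, 4L, 2L))
  expect_equal(names(tiers)[tiers == "low"], c("g2", "g5"))
  expect_equal(names(tiers)[tiers == "high"], c("g4", "g6"))
  # all-equal values still split 25/50/25, deterministically by input order
  same <- stats::setNames(rep(1, 8), paste0("g", 1:8))
  t2 <- expression_tiers(same)
  expect_equal(as.integer(table(t2)), c(2L, 4L, 2L))
  expect_identical(expression_tiers(same), t2)
  expect_error(expression_tiers(c(a = 1, b = 2, c = 3)), ">= 4 genes")
})

test_that("genes planted with high expression land in the high tier", {
  s <- shared_sim()
  tiers <- s$truth$tiers
  top <- names(sort(stats::setNames(s$ann$genes$base_expr,
                                    s$ann$genes$gene_id),
                    decreasing = TRUE))[1:5]
  expect_true(all(tiers[top] == "high"))
})

test_that("meta-profiles have the expected offsets and reproduce flat tracks", {
  anchors <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                        tss = c(5000, 15000), strand = c("+", "-"))
  tr <- synth_track(rep(1.25, 200))
  prof <- meta_profile(tr$probes, tr$scores[, 1], anchors)
  expect_equal(nrow(prof), 57)      # (2*1500 - 200)/50 + 1
  expect_equal(range(prof$offset), c(-1400, 1400))
  expect_true(all(prof$mean == 1.25))
  expect_true(all(prof$n_genes == 2))
  expect_error(meta_profile(tr$probes, tr$scores[, 1],
                            data.frame(gene_id = "g", chrom = "chr9",
                                       tss = 1e7, strand = "+")),
               "no probes")
  expect_error(meta_profile(tr$probes, tr$scores[, 1], anchors, span = 1501),
               "span")
})

test_that("a planted TSS-core dip localizes to |offset| < 250", {
  anchors <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                        tss = c(5000, 10000, 15000, 20000),
                        strand = c("+", "-", "+", "-"))
  n <- 250
  starts <- 100 * (seq_len(n) - 1)
  mids <- starts + 30
  dip <- vapply(mids, function(m) any(abs(m - anchors$tss) < 250), logical(1))
  tr <- synth_track(ifelse(dip, -0.5, 0))
  prof <- meta_profile(tr$probes, tr$scores[, 1], anchors)
  expect_lt(abs(prof$offset[which.min(prof$mean)]), 250)
  expect_true(all(prof$mean[abs(prof$offset) > 600] == 0))
})

test_that("profile weighted means conserve the flat-track level exactly", {
  anchors <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
                        strand = "+")
  tr <- synth_track(rep(0.5, 400))
  prof <- meta_profile(tr$probes, tr$scores[, 1], anchors)
  expect_equal(sum(prof$mean * prof$n_genes) / sum(prof$n_genes), 0.5)
})

test_that("gene-body profiles order expression tiers as planted", {
  ann <- simulate_annotation(n_genes = 40, n_chrom = 1, chrom_length = 1.4e6,
                             short_gene_fraction = 1, seed = 31)
  sim <- simulate_probe_signals(ann, peak_gene_fraction = 1, peak_effect = 2,
                                noise_sd = 0.3, n_induced = 0,
                                peak_width_range = c(1200, 1800),
                                enhancer_5hmc_effect = 0, seed = 32)
  tiers <- sim$truth$tiers
  cm <- group_mean(sim$hmc, "control")
  prof <- gene_body_profile(sim$hmc$probes, cm, ann, ann$genes$gene_id, tiers)
  body <- prof[prof$offset >= 200 & prof$offset <= 1800, ]
  m <- tapply(body$mean, body$tier, mean)
  expect_gt(m[["high"]], m[["medium"]])
  expect_gt(m[["medium"]], m[["low"]])
})

test_that("gene-body profiles are invariant under genome mirroring", {
  ann <- simulate_annotation(n_genes = 30, n_chrom = 1, chrom_length = 1.1e6,
                             short_gene_fraction = 1, seed = 33)
  set.seed(34)
  tr <- ann$tiled_regions
  probes <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    starts <- seq(tr$start[i], tr$end[i] - 60, by = 100)
    data.frame(chrom = tr$chrom[i], start = starts, end = starts + 60,
               region_id = tr$region_id[i], stringsAsFactors = FALSE)
  }))
  probes$probe_id <- sprintf("p%05d", seq_len(nrow(probes)))
  scores <- stats::setNames(stats::rnorm(nrow(probes)), probes$probe_id)
  tiers <- expression_tiers(stats::setNames(ann$genes$base_expr,
                                            ann$genes$gene_id))
  prof1 <- gene_body_profile(probes, scores, ann, ann$genes$gene_id, tiers)
  L <- unname(ann$chromosomes[1])
  probes2 <- probes
  probes2$start <- L - probes$end
  probes2$end <- L - probes$start
  ord <- order(probes2$start)
  probes2 <- probes2[ord, ]
  prof2 <- gene_body_profile(probes2, scores[ord], mirror_annotation(ann),
                             ann$genes$gene_id, tiers)
  expect_equal(prof1, prof2, tolerance = 1e-12)
})

test_that("empty tiers are omitted from gene-body profiles with a notice", {
  ann <- simulate_annotation(n_genes = 12, n_chrom = 1, chrom_length = 5e5,
                             short_gene_fraction = 1, seed = 35)
  sim <- simulate_probe_signals(ann, n_induced = 0, seed = 36)
  tiers <- sim$truth$tiers
  short <- ann$genes$gene_id[tiers != "high"]
  expect_message(
    prof <- gene_body_profile(sim$hmc$probes,
                              group_mean(sim$hmc, "control"),
                              ann, short, tiers[short]),
    "empty"
  )
  expect_false("high" %in% prof$tier)
})

test_that("heat-map rows clip at the stated bound and cluster sensibly", {
  m <- rbind(a = c(0, 0.05), b = c(0.1, 0), c = c(10, 10), d = c(0, 0.05))
  hm <- ppr_heatmap(m, clip = 2.5)
  expect_equal(max(hm$matrix), 2.5)       # 10 stored as 2.5
  ord <- rownames(hm$matrix)
  # identical rows a and d are adjacent leaves
  expect_equal(abs(which(ord == "a") - which(ord == "d")), 1)
  expect_error(ppr_heatmap(m[1, , drop = FALSE]), "nrow")
})

test_that("three-row Ward clustering reproduces the hand-built dendrogram", {
  m <- rbind(r1 = c(0, 0), r2 = c(0.6, 0), r3 = c(8, 8))
  hm <- ppr_heatmap(m)
  hc <- hm$hclust
  # first merge joins r1 and r2 (distance 0.6); r3 joins last
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_equal(hc$height[1], 0.6)
  # Ward (squared-Euclidean update) height for merging r3 with {r1, r2} via
  # Lance-Williams with n1 = n2 = n3 = 1:
  # d({12},3)^2 = (2*d13^2 + 2*d23^2 - d12^2) / 3
  # distances are computed on the clipped matrix
  mc <- pmin(pmax(m, -2.5), 2.5)
  d13 <- sqrt(sum((mc[1, ] - mc[3, ])^2))
  d23 <- sqrt(sum((mc[2, ] - mc[3, ])^2))
  expected <- sqrt((2 * d13^2 + 2 * d23^2 - 0.6^2) / 3)
  expect_equal(hc$height[2], expected)
  # deterministic leaf order: singleton r3 (size 1) precedes the pair
  expect_equal(rownames(hm$matrix), c("r3", "r1", "r2"))
})
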