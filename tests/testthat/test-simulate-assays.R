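test_that("uniform fragment sampling gives length-proportional region counts", {
  ann <- simulate_annotation(n_genes = 40, n_chrom = 1, chrom_length = 1.3e6,
                             seed = 5)
  lib <- simulate_fragments(ann, mark = "H3K36me3", enrichment = NULL,
                            n_fragments = 20000, dup_rate = 0.1, seed = 21)
  frags <- dedup_fragments(lib$ip)
  counts <- count_in_regions(frags, lib$regions)
  # under any-overlap counting the expected weight per region is its length
  # plus the mean fragment length
  w <- (lib$regions$end - lib$regions$start) + 200
  gof <- suppressWarnings(stats::chisq.test(counts, p = w / sum(w)))
  expect_gt(gof$p.value, 0.001)
})

test_that("an enriched gene body scores highest after normalization", {
  ann <- simulate_annotation(n_genes = 40, n_chrom = 1, chrom_length = 1.3e6,
                             seed = 5)
  target <- ann$genes$gene_id[7]
  e <- stats::setNames(rep(1, nrow(ann$genes)), ann$genes$gene_id)
  e[target] <- 10
  lib <- simulate_fragments(ann, mark = "H3K36me3", enrichment = e,
                            n_fragments = 30000, seed = 22)
  counts <- count_in_regions(dedup_fragments(lib$ip), lib$regions)
  dens <- counts / (lib$regions$end - lib$regions$start)
  expect_equal(names(which.max(dens)), target)
})

test_that("an empty fragment library flows through with all-zero counts", {
  ann <- simulate_annotation(n_genes = 10, n_chrom = 1, chrom_length = 4e5,
                             seed = 2)
  lib <- simulate_fragments(ann, n_fragments = 0, seed = 1)
  expect_equal(nrow(lib$ip), 0)
  counts <- count_in_regions(lib$ip, lib$regions)
  expect_true(all(counts == 0))
})

test_that("injected duplicates are recorded and removed exactly", {
  ann <- simulate_annotation(n_genes = 20, n_chrom = 1, chrom_length = 7e5,
                             seed = 3)
  lib <- simulate_fragments(ann, n_fragments = 10000, dup_rate = 0.1, seed = 13)
  expect_equal(nrow(lib$ip), 10000)
  dd <- suppressMessages(dedup_fragments(lib$ip))
  expect_equal(nrow(dd), lib$n_unique_ip)
  expect_lte(lib$n_unique_ip, 9000)
})

test_that("fragment simulation is seed-deterministic", {
  ann <- simulate_annotation(n_genes = 10, n_chrom = 1, chrom_length = 4e5,
                             seed = 2)
  a <- simulate_fragments(ann, n_fragments = 5000, seed = 31)
  b <- simulate_fragments(ann, n_fragments = 5000, seed = 31)
  expect_identical(a, b)
})

test_that("expression fold changes are planted and recoverable", {
  ann <- simulate_annotation(n_genes = 40, n_chrom = 1, chrom_length = 1.3e6,
                             seed = 5)
  induced <- data.frame(gene_id = ann$genes$gene_id[1:5], true_lfc = 2)
  ex <- simulate_expression(ann, induced = induced, noise_sd = 0.2, seed = 14)
  ch <- expression_change(ex$expr, ex$groups)
  est <- ch$lfc[match(induced$gene_id, ch$gene_id)]
  expect_true(all(abs(est - 2) < 0.3))
  # without planting, estimated changes stay small
  ex0 <- simulate_expression(ann, induced = NULL, noise_sd = 0.2, seed = 15)
  ch0 <- expression_change(ex0$expr, ex0$groups)
  expect_true(all(abs(ch0$lfc) < 0.6))
})

test_that("designed tissue-panel genes behave as designed", {
  ann <- simulate_annotation(n_genes = 40, n_chrom = 1, chrom_length = 1.3e6,
                             seed = 5)
  ex <- simulate_expression(ann, tissue_count = 6, seed = 16)
  des <- ex$tissue_design
  for (i in which(des$design == "single_tissue")) {
    row <- ex$tissue[des$gene_id[i], ]
    expect_equal(sum(row > 0), 1)
    expect_gt(row[des$tissue[i]], 0)
  }
  for (i in which(des$design == "uniform")) {
    row <- ex$tissue[des$gene_id[i], ]
    expect_equal(stats::sd(row), 0)
  }
})

test_that("unknown induced gene ids are rejected", {
  ann <- simulate_annotation(n_genes = 10, n_chrom = 1, chrom_length = 4e5,
                             seed = 2)
  expect_error(
    simulate_expression(ann, induced = data.frame(gene_id = "nope", true_lfc = 2)),
    "not in annotation"
  )
})

test_that("Cq tables are seed-deterministic and respect the ceiling", {
  tf <- data.frame(locus = c("a", "b"), f_5hmc = c(0, 0.2),
                   f_5mc = c(0, 0.3), f_c = c(1, 0.5))
  a <- simulate_epimark_cq(tf, noise_sd = 0.2, seed = 3)
  b <- simulate_epimark_cq(tf, noise_sd = 0.2, seed = 3)
  expect_identical(a, b)
  noisefree <- simulate_epimark_cq(tf, noise_sd = 0)
  # fully unmodified site: both digests run to the ceiling
  cqa <- noisefree[noisefree$locus == "a", ]
  expect_true(all(cqa$cq[cqa$digest != "uncut"] == 40))
  expect_true(all(noisefree$cq <= 40))
})
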