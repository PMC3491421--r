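test_that("expression changes are zero on identical groups and antisymmetric", {
  m <- matrix(stats::rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), c("C1", "C2", "T1", "T2")))
  m[, 3:4] <- m[, 1:2]
  groups <- c(C1 = "control", C2 = "control", T1 = "treated", T2 = "treated")
  ch <- expression_change(m, groups)
  expect_true(all(ch$lfc == 0))
  m2 <- matrix(stats::rnorm(40), 10, 4, dimnames = dimnames(m))
  fwd <- expression_change(m2, groups)
  rev <- expression_change(m2, groups, control = "treated", treated = "control")
  expect_equal(fwd$lfc, -rev$lfc)
  expect_equal(fwd$p, rev$p)
  expect_error(expression_change(m2[, 1:3],
                                 groups[1:3]), ">= 2 samples")
})

test_that("induction selection is strict at the log2 1.5 boundary", {
  ch <- data.frame(gene_id = c("a", "b", "c"), lfc = c(1.5, 1.5001, -2),
                   p = 0.01)
  expect_equal(select_induced(ch), "b")
  expect_equal(select_induced(ch[0, ]), character(0))
})

test_that("all planted induced genes are recovered at low noise", {
  ann <- simulate_annotation(n_genes = 80, n_chrom = 1, chrom_length = 2.4e6,
                             seed = 71)
  induced <- data.frame(gene_id = sample(ann$genes$gene_id, 30),
                        true_lfc = stats::runif(30, 2, 4))
  ex <- simulate_expression(ann, induced = induced, noise_sd = 0.1, seed = 72)
  ch <- expression_change(ex$expr, ex$groups)
  expect_setequal(select_induced(ch, 1.5), induced$gene_id)
})

test_that("unaffected genes are sampled from the stated null band", {
  ch <- data.frame(gene_id = paste0("g", 1:100),
                   lfc = c(rep(0.01, 60), rep(2, 40)),
                   p = c(rep(0.9, 60), rep(0.001, 40)))
  un <- select_unaffected(ch, n = 20, seed = 5)
  expect_length(un, 20)
  expect_true(all(un %in% paste0("g", 1:60)))
  expect_identical(un, select_unaffected(ch, n = 20, seed = 5))
})

test_that("change correlations reproduce exact and null cases", {
  rec <- data.frame(gene_id = paste0("g", 1:30), lfc = stats::rnorm(30, 2))
  rec$dmark <- 2 * rec$lfc
  out <- change_correlation(rec, rec$gene_id, "dmark")
  expect_equal(out$r, 1)
  set.seed(73)
  rec$dnull <- stats::rnorm(30)
  expect_lt(abs(change_correlation(rec, rec$gene_id, "dnull")$r), 0.5)
  expect_error(change_correlation(rec, rec$gene_id[1:2], "dmark"),
               "fewer than 3")
})

test_that("reciprocal planting yields opposite correlations with expression", {
  s <- shared_sim()
  truth <- s$truth$induced_genes
  rec <- data.frame(gene_id = truth$gene_id, lfc = truth$true_lfc)
  rec$d5hmc <- ppr_means(s$hmc$probes, s$delta_hmc, s$ann)[rec$gene_id]
  rec$d5mc <- ppr_means(s$mc$probes, s$delta_mc, s$ann)[rec$gene_id]
  hm <- change_correlation(rec, rec$gene_id, "d5hmc")
  mc <- change_correlation(rec, rec$gene_id, "d5mc")
  expect_gt(hm$r, 0); expect_lt(hm$p, 0.05)
  expect_lt(mc$r, 0); expect_lt(mc$p, 0.05)
})

test_that("change profiles show flank gains and the TSS-core double loss", {
  s <- shared_sim()
  ind <- s$truth$induced_genes$gene_id
  p_hmc <- change_profile(s$hmc$probes, s$delta_hmc, s$ann, ind)
  p_mc <- change_profile(s$mc$probes, s$delta_mc, s$ann, ind)
  expect_equal(nrow(p_hmc), (2 * 3000 - 200) / 50 + 1)
  flank <- abs(p_hmc$offset) > 500 & abs(p_hmc$offset) < 2500
  expect_gt(mean(p_hmc$mean[flank]), 0.5)
  expect_lt(mean(p_mc$mean[flank]), -0.5)
  # both marks dip at the core
  expect_lt(abs(p_hmc$offset[which.min(p_hmc$mean)]), 300)
  expect_lt(abs(p_mc$offset[which.min(p_mc$mean)]), 3000) # 5mC loses everywhere
  core <- abs(p_mc$offset) < 150
  expect_lt(mean(p_hmc$mean[core]), 0)
  # unaffected genes stay flat
  other <- setdiff(s$ann$genes$gene_id, ind)[1:20]
  p0 <- change_profile(s$hmc$probes, s$delta_hmc, s$ann, other)
  expect_lt(max(abs(p0$mean)), 0.5)
  expect_error(change_profile(s$hmc$probes, s$delta_hmc, s$ann, character(0)),
               "empty")
})

test_that("family region analysis flags only real deviations", {
  set.seed(74)
  genes <- paste0("g", 1:40)
  fam <- genes[1:10]; un <- genes[11:40]
  base <- expand.grid(gene_id = genes,
                      region = c("upstream", "promoter", "gene_body"),
                      mark = c("5hmC", "5mC"), stringsAsFactors = FALSE)
  base$delta <- stats::rnorm(nrow(base), 0, 0.3)
  plant <- base$region == "gene_body" & base$mark == "5hmC" &
    base$gene_id %in% fam
  base$delta[plant] <- base$delta[plant] + 2
  res <- family_region_analysis(base, fam, un)
  hit <- res[res$region == "gene_body" & res$mark == "5hmC", ]
  expect_true(hit$flagged)
  expect_gt(hit$fold_enrichment, 3)
  expect_false(any(res$flagged[!(res$region == "gene_body" &
                                   res$mark == "5hmC")]))
  # family identical to the unaffected set can never be flagged
  res_same <- family_region_analysis(base, un, un)
  expect_false(any(res_same$flagged))
  expect_error(family_region_analysis(base, fam[1:2], un), ">= 3 genes")
})

test_that("swapping group labels negates every delta downstream", {
  s <- shared_sim()
  d_rev <- delta_track(s$hmc_treated, s$hmc_control)
  expect_equal(d_rev, -s$delta_hmc)
  rd <- gene_region_deltas(s$hmc$probes, s$delta_hmc, s$ann)
  rd_rev <- gene_region_deltas(s$hmc$probes, d_rev, s$ann)
  expect_equal(rd$delta, -rd_rev$delta)
})
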