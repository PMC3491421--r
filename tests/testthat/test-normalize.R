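test_that("loess normalization leaves trend-free scores almost unchanged", {
  set.seed(101)
  n <- 10000
  y <- stats::rnorm(n, 0, 0.5)
  A <- matrix(stats::runif(n, 8, 14), ncol = 1, dimnames = list(NULL, "S1"))
  tr <- synth_track(y, intensity = A)
  out <- loess_normalize(tr, span = 0.3)
  expect_lt(max(abs(out$scores[, 1] - tr$scores[, 1])), 0.05)
})

test_that("loess normalization removes a planted intensity trend", {
  set.seed(102)
  n <- 5000
  A <- matrix(stats::runif(n, 8, 14), ncol = 1, dimnames = list(NULL, "S1"))
  y <- 0.8 * A[, 1] + stats::rnorm(n, 0, 0.3)
  tr <- synth_track(y, intensity = A)
  out <- loess_normalize(tr, span = 0.3)
  slope <- unname(stats::coef(stats::lm(out$scores[, 1] ~ A[, 1]))[2])
  expect_lt(abs(slope), 0.01)
})

test_that("loess normalization enforces its preconditions and fallbacks", {
  A <- matrix(1, 49, 1, dimnames = list(NULL, "S1"))
  tr <- synth_track(stats::rnorm(49), intensity = A)
  expect_error(loess_normalize(tr), "at least 50 probes")
  A2 <- matrix(5, 100, 1, dimnames = list(NULL, "S1"))
  tr2 <- synth_track(stats::rnorm(100, 2), intensity = A2)
  expect_message(out <- loess_normalize(tr2), "constant intensity")
  expect_equal(stats::median(out$scores[, 1]), 0)
})

test_that("scale normalization equalizes MADs at their geometric mean", {
  set.seed(103)
  base <- stats::rnorm(2001)
  base <- base - stats::median(base)         # symmetric-ish, median zero
  scores <- cbind(S1 = base, S2 = 4 * base + 0)
  tr <- synth_track(scores)
  mads_pre <- apply(tr$scores, 2, stats::mad)
  out <- scale_normalize(tr)
  mads_post <- apply(out$scores, 2, stats::mad)
  gm <- sqrt(prod(mads_pre))
  expect_equal(unname(mads_post), rep(gm, 2), tolerance = 1e-12)
  # ratio of the two pre-normalization MADs was 4, so both land at 2x col1
  expect_equal(mads_post[["S2"]] / mads_pre[["S1"]], 2, tolerance = 1e-10)
})

test_that("scale normalization agrees with the median-abs-value reference", {
  skip_if_not_installed("limma")
  set.seed(104)
  # symmetric, zero-median columns: MAD-based and median-|x|-based scaling
  # coincide, so limma's normalizeMedianAbsValues is an exact oracle
  z <- stats::rnorm(1501)
  z <- c(z, -z, 0)
  scores <- cbind(S1 = z, S2 = 2.5 * z, S3 = 0.4 * z)
  tr <- synth_track(scores)
  out <- scale_normalize(tr)
  ref <- limma::normalizeMedianAbsValues(scores)
  expect_equal(unname(out$scores), unname(ref), tolerance = 1e-10)
})

test_that("scale normalization is idempotent and guards degenerate input", {
  set.seed(105)
  tr <- synth_track(matrix(stats::rnorm(3000), ncol = 3,
                           dimnames = list(NULL, c("a", "b", "c"))))
  once <- scale_normalize(tr)
  twice <- scale_normalize(once)
  expect_lt(max(abs(once$scores - twice$scores)), 1e-12)
  expect_error(scale_normalize(synth_track(stats::rnorm(100))), ">= 2 samples")
  bad <- synth_track(cbind(S1 = stats::rnorm(100), S2 = rep(1, 100)))
  expect_error(scale_normalize(bad), "S2")
})

test_that("group means average the group's samples per probe", {
  scores <- cbind(C1 = c(1, 0), C2 = c(2, NA), C3 = c(3, 4))
  groups <- c(C1 = "control", C2 = "control", C3 = "control")
  tr <- synth_track(scores, groups = groups)
  m <- suppressMessages(group_mean(tr, "control"))
  expect_equal(unname(m[1]), 2)          # mean(1, 2, 3)
  expect_equal(unname(m[2]), 2)          # mean(0, 4) with NA excluded
  expect_error(group_mean(tr, "exposed"), "unknown group")
  # group of one is the identity
  tr1 <- synth_track(cbind(T1 = c(5, 6)), groups = c(T1 = "treated"))
  expect_equal(unname(group_mean(tr1, "treated")), c(5, 6))
})

test_that("change tracks subtract control from treated with probe checks", {
  a <- stats::setNames(c(1, 2, 3), c("p1", "p2", "p3"))
  b <- stats::setNames(c(1, 3, 2), c("p1", "p2", "p3"))
  expect_equal(unname(delta_track(a, a)), c(0, 0, 0))
  expect_equal(delta_track(a, b), -delta_track(b, a))
  names(b)[3] <- "p9"
  expect_error(delta_track(a, b), "p9")
})
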