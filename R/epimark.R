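# Absolute 5hmC / 5mC / unmodified-C quantification from
# glucosylation/restriction qPCR Cq values.
#
# Enzymology: T4-BGT glucosylation protects 5hmC from MspI; HpaII is blocked
# by any CpG modification; MspI without glucosylation cuts everything.
# The fractions below are the unique linear solution under that enzymology,
# with the non-glucosylated MspI reaction as background.

#' Surviving template fraction from a digested/uncut Cq pair
#'
#' Assumes doubling per cycle: `f = 2^(cq_uncut - cq_digested)`, clamped to
#' \[0, 1\].
#'
#' @param cq_digested,cq_uncut Cq values (cycles, > 0).
#' @return fraction of template surviving digestion.
#' @examples
#' surviving_fraction(21, 20) # 0.5
#' @export
surviving_fraction <- function(cq_digested, cq_uncut) {
  stopifnot(all(cq_digested > 0), all(cq_uncut > 0))
  pmin(pmax(2^(cq_uncut - cq_digested), 0), 1)
}

#' Absolute CpG modification fractions from an EpiMark-style Cq table
#'
#' Solves the assay per locus:
#' `f_5hmC = f(MspI | glucosylated) - f(MspI | non-glucosylated)` (the second
#' term is the kit's background correction),
#' `f_5mC = f(HpaII | non-glucosylated) - f(MspI | glucosylated)`, and
#' `f_C = 1 - f(HpaII | non-glucosylated)`, each clamped to \[0, 1\].
#' Reactions at or above the Cq ceiling are treated as complete digestion
#' (zero surviving template), which makes the noise-free inversion of the
#' forward model exact. Replicates are solved independently, then averaged;
#' the standard error across replicates is reported.
#'
#' @param assay data.frame with `locus`, `glucosylated` (logical), `digest`
#'   (`MspI`/`HpaII`/`uncut`), `replicate`, `cq` (e.g. from
#'   [simulate_epimark_cq()]).
#' @param cq_ceiling Cq value encoding complete digestion.
#' @param tolerance pre-clamp violations of \[0,1\] larger than this trigger
#'   a warning with the magnitude.
#' @return data.frame with one row per locus: `f_5hmc`, `f_5mc`, `f_c`,
#'   `residual` (1 - sum), `se_f_5hmc`, `se_f_5mc`, `se_f_c`,
#'   `n_replicates`.
#' @export
epimark_fractions <- function(assay, cq_ceiling = 40, tolerance = 0.05) {
  need <- c("locus", "glucosylated", "digest", "replicate", "cq")
  stopifnot(all(need %in% names(assay)))
  if (any(assay$cq <= 0 | assay$cq > cq_ceiling + 1e-9)) {
    stop("Cq values must lie in (0, ", cq_ceiling, "]")
  }
  solve_one <- function(d) {
    get_cq <- function(gluc, digest) {
      v <- d$cq[d$glucosylated == gluc & d$digest == digest]
      if (length(v) != 1) {
        stop("locus ", d$locus[1], " replicate ", d$replicate[1],
             ": expected exactly one ", digest, " reaction per glucosylation state")
      }
      v
    }
    frac <- function(gluc, digest) {
      cq_d <- get_cq(gluc, digest)
      if (cq_d >= cq_ceiling - 1e-9) return(0)
      surviving_fraction(cq_d, get_cq(gluc, "uncut"))
    }
    f_msp_g <- frac(TRUE, "MspI")
    f_msp_n <- frac(FALSE, "MspI")
    f_hpa_n <- frac(FALSE, "HpaII")
    raw <- c(f_5hmc = f_msp_g - f_msp_n,
             f_5mc = f_hpa_n - f_msp_g,
             f_c = 1 - f_hpa_n)
    viol <- pmax(-raw, raw - 1, 0)
    if (any(viol > tolerance)) {
      warning("locus ", d$locus[1], ": fraction outside [0,1] by ",
              signif(max(viol), 3), " before clamping")
    }
    pmin(pmax(raw, 0), 1)
  }
  out <- lapply(split(assay, assay$locus), function(dl) {
    reps <- lapply(split(dl, dl$replicate), solve_one)
    m <- do.call(rbind, reps)
    est <- colMeans(m)
    se <- if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m)) else
      rep(NA_real_, 3)
    data.frame(locus = dl$locus[1],
               f_5hmc = est[1], f_5mc = est[2], f_c = est[3],
               residual = 1 - sum(est),
               se_f_5hmc = se[1], se_f_5mc = se[2], se_f_c = se[3],
               n_replicates = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
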