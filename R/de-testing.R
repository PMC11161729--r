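# Beta-binomial differential expression testing between response groups
# and assignment of the nested significance tiers T1-T3.
#
# The test is a likelihood-ratio test on the beta-binomial model: the null
# fits a single success proportion (and overdispersion) shared by both
# sample groups; the alternative gives each group its own proportion while
# sharing the overdispersion. Counts are spectral counts, trials are the
# per-sample totals, so the model captures both within-sample (binomial)
# and between-sample (beta) variation.

# beta-binomial log-likelihood, combinatorial constant dropped (cancels in
# every likelihood ratio formed here); parameterized by mean proportion pi
# and overdispersion phi = 1 / (alpha + beta + 1)
bb_loglik <- function(y, n, pi, phi) {
  ab <- 1 / phi - 1
  a <- pi * ab
  b <- (1 - pi) * ab
  sum(lbeta(y + a, n - y + b) - lbeta(a, b))
}

PI_LO <- 1e-9
PI_HI <- 1 - 1e-9
PHI_LO <- 1e-9
PHI_HI <- 0.999

# method-of-moments start for the overdispersion phi = 1/(alpha+beta+1)
phi_moment <- function(y, n) {
  p <- y / n
  pbar <- mean(p)
  if (pbar <= 0 || pbar >= 1) return(0.01)
  extra <- stats::var(p) - pbar * (1 - pbar) / mean(n)
  min(max(extra / (pbar * (1 - pbar)), 1e-4), 0.9)
}

# maximize bb_loglik over (pi, phi) for pooled data; multi-start (moment
# estimate plus two spread starts) to dodge flat likelihood regions at
# small counts
bb_fit_null <- function(y, n, phi_starts = NULL) {
  pi0 <- min(max(sum(y) / sum(n), PI_LO), PI_HI)
  if (is.null(phi_starts)) phi_starts <- c(phi_moment(y, n), 0.01, 0.3)
  best <- NULL
  for (phi0 in phi_starts) {
    fit <- stats::optim(c(pi0, phi0),
                        fn = function(p) -bb_loglik(y, n, p[1], p[2]),
                        method = "L-BFGS-B",
                        lower = c(PI_LO, PHI_LO),
                        upper = c(PI_HI, PHI_HI),
                        control = list(factr = 1e5))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(loglik = -best$value, pi = best$par[1], phi = best$par[2])
}

# the alternative is seeded from the null solution (plus moment and spread
# starts), so its maximized likelihood can never fall below the null's and
# identical groups give a statistic of exactly zero
bb_fit_alt <- function(ya, na, yb, nb, null_fit = NULL) {
  pa0 <- min(max(sum(ya) / sum(na), PI_LO), PI_HI)
  pb0 <- min(max(sum(yb) / sum(nb), PI_LO), PI_HI)
  nll <- function(p) -(bb_loglik(ya, na, p[1], p[3]) +
                         bb_loglik(yb, nb, p[2], p[3]))
  starts <- list(c(pa0, pb0, phi_moment(c(ya, yb), c(na, nb))),
                 c(pa0, pb0, 0.01), c(pa0, pb0, 0.3))
  if (!is.null(null_fit))
    starts <- c(starts, list(c(null_fit$pi, null_fit$pi, null_fit$phi)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, fn = nll, method = "L-BFGS-B",
                        lower = c(PI_LO, PI_LO, PHI_LO),
                        upper = c(PI_HI, PI_HI, PHI_HI),
                        control = list(factr = 1e5))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(null_fit) && -best$value < null_fit$loglik) {
    # numerical guard: the null is nested in the alternative
    best$value <- -null_fit$loglik
    best$par <- c(null_fit$pi, null_fit$pi, null_fit$phi)
  }
  list(loglik = -best$value, pi_a = best$par[1], pi_b = best$par[2],
       phi = best$par[3])
}

bb_fit_alt_pgphi <- function(ya, na, yb, nb) {
  fa <- bb_fit_null(ya, na)
  fb <- bb_fit_null(yb, nb)
  list(loglik = fa$loglik + fb$loglik, pi_a = fa$pi, pi_b = fb$pi)
}

#' Beta-binomial likelihood-ratio test for two groups of counts
#'
#' Tests whether the underlying count proportion differs between groups A
#' and B under a beta-binomial model with shared overdispersion. The
#' statistic 2 (l_alt - l_null) is referred to a chi-square with 1 degree
#' of freedom (2 df when `per_group_phi = TRUE`), giving a two-sided p.
#'
#' @param counts_a,counts_b integer count vectors per group.
#' @param totals_a,totals_b matching per-sample totals (trial counts).
#' @param per_group_phi if `TRUE`, the alternative fits a separate
#'   overdispersion per group (2 df test).
#' @return two-sided p-value in [0, 1].
#' @export
beta_binomial_test <- function(counts_a, totals_a, counts_b, totals_b,
                               per_group_phi = FALSE) {
  stopifnot(length(counts_a) == length(totals_a),
            length(counts_b) == length(totals_b))
  drop_a <- totals_a == 0
  drop_b <- totals_b == 0
  if (any(drop_a) || any(drop_b)) {
    warning("excluding ", sum(drop_a) + sum(drop_b),
            " sample(s) with zero totals")
    counts_a <- counts_a[!drop_a]; totals_a <- totals_a[!drop_a]
    counts_b <- counts_b[!drop_b]; totals_b <- totals_b[!drop_b]
  }
  if (length(counts_a) < 2 || length(counts_b) < 2)
    stop("at least 2 samples per group are required")
  if (any(counts_a > totals_a) || any(counts_b > totals_b))
    stop("counts cannot exceed totals")
  if (sum(counts_a) + sum(counts_b) == 0) {
    message("all counts zero in both groups; degenerate p = 1")
    return(1)
  }
  y <- c(counts_a, counts_b)
  n <- c(totals_a, totals_b)
  null <- bb_fit_null(y, n)
  if (per_group_phi) {
    alt <- bb_fit_alt_pgphi(counts_a, totals_a, counts_b, totals_b)
    df <- 2
  } else {
    alt <- bb_fit_alt(counts_a, totals_a, counts_b, totals_b,
                      null_fit = null)
    df <- 1
  }
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  # differences below the optimizer's likelihood tolerance are zero
  if (stat < 1e-6) stat <- 0
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Assign the nested significance tier
#'
#' Tiers: T1 = p < 0.05; T2 = T1 plus data presence >= 60% in the
#' upregulated group; T3 = T2 plus fold-change > 1.5 (in either
#' direction; fold-changes are ratios >= 1 with a direction flag).
#'
#' @param p_value p-value in [0, 1].
#' @param presence_up data presence in the upregulated group, [0, 1].
#' @param fold_change ratio >= 1 (direction carried separately).
#' @return one of `"none"`, `"T1"`, `"T2"`, `"T3"`.
#' @export
assign_tier <- function(p_value, presence_up, fold_change) {
  stopifnot(p_value >= 0, p_value <= 1,
            presence_up >= 0, presence_up <= 1, fold_change > 0)
  if (p_value >= 0.05) return("none")
  if (presence_up < 0.60) return("T1")
  if (fold_change <= 1.5) return("T2")
  "T3"
}

tier_rank <- function(tier) {
  unname(c(none = 0L, T1 = 1L, T2 = 2L, T3 = 3L)[tier])
}

# sample subset for a (comparison, cohort) contrast
select_contrast_samples <- function(annotation, comparison, cohort) {
  ann <- annotation
  ann <- switch(cohort,
                discovery = ann[ann$cohort == "discovery" &
                                  ann$treatment == "ACT", ],
                validation = ann[ann$cohort == "validation" &
                                   ann$treatment == "ACT", ],
                untreated = ann[ann$treatment == "UT", ],
                stop("unknown cohort: ", cohort))
  if (comparison %in% c("LUAD", "LUSC")) ann <- ann[ann$subtype == comparison, ]
  else if (comparison != "panNSCLC") stop("unknown comparison: ", comparison)
  ann
}

#' Run differential expression for one comparison and cohort
#'
#' Compares poor- vs good-response samples (PRG: RFS <= 16 months, GRG:
#' RFS > 24 months; intermediate samples excluded) for a histology subtype
#' or the pooled pan-NSCLC set, using the beta-binomial likelihood-ratio
#' test on rounded normalized counts with the equalized sample total as
#' trial count.
#'
#' @param norm normalized-count `ptx_matrix`.
#' @param annotation sample annotation data.frame (needs `sample_id`,
#'   `cohort`, `subtype`, `treatment`, `rfs_months`).
#' @param comparison `"LUAD"`, `"LUSC"` or `"panNSCLC"`.
#' @param cohort `"discovery"`, `"validation"` (treated arm) or
#'   `"untreated"`.
#' @param intensities optional intensity layer for the count:intensity
#'   correlation column.
#' @param pseudocount pseudocount for the fold-change ratio.
#' @param per_group_phi passed to [beta_binomial_test()].
#' @return data.frame with one row per protein: `protein_id`,
#'   `comparison`, `cohort`, `p_value`, `fold_change`, `direction`
#'   (`PRG_up`/`GRG_up`), `presence_up`, `mean_up`, `mean_prg`, `mean_grg`,
#'   `sc_intensity_r`, `tier`, `bh_fdr`.
#' @export
run_differential <- function(norm, annotation, comparison, cohort,
                             intensities = NULL, pseudocount = 0.5,
                             per_group_phi = FALSE) {
  ann <- select_contrast_samples(annotation, comparison, cohort)
  ann <- assign_response_groups(ann)
  prg <- ann$sample_id[ann$response_group == "PRG"]
  grg <- ann$sample_id[ann$response_group == "GRG"]
  if (length(prg) < 2 || length(grg) < 2)
    stop(sprintf(
      "underpowered contrast %s/%s: %d PRG vs %d GRG samples (need >= 2 each)",
      comparison, cohort, length(prg), length(grg)))
  check_samples_known(c(prg, grg), norm)

  stats_tab <- group_stats(norm, intensities, prg, grg,
                           pseudocount = pseudocount)

  counts <- round(unclass(norm))
  totals <- round(colSums(unclass(norm)))
  ya <- counts[, prg, drop = FALSE]
  yb <- counts[, grg, drop = FALSE]
  na <- totals[prg]
  nb <- totals[grg]
  p <- vapply(seq_len(nrow(counts)), function(i) {
    beta_binomial_test(ya[i, ], na, yb[i, ], nb,
                       per_group_phi = per_group_phi)
  }, numeric(1))

  direction <- ifelse(stats_tab$upregulated_group == "A", "PRG_up", "GRG_up")
  presence_up <- ifelse(direction == "PRG_up",
                        stats_tab$presence_a, stats_tab$presence_b)
  mean_up <- ifelse(direction == "PRG_up",
                    stats_tab$mean_a, stats_tab$mean_b)
  tier <- mapply(assign_tier, p, presence_up, stats_tab$fold_change)

  data.frame(protein_id = stats_tab$protein_id,
             comparison = comparison, cohort = cohort,
             p_value = p, fold_change = stats_tab$fold_change,
             direction = direction, presence_up = presence_up,
             mean_up = mean_up,
             mean_prg = stats_tab$mean_a, mean_grg = stats_tab$mean_b,
             sc_intensity_r = stats_tab$sc_intensity_r,
             tier = tier,
             bh_fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
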