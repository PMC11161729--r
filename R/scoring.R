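# Cumulative robustness rubric and signature scoring for cross-cohort
# biomarker candidates, plus the composite ranking.
#
# Robustness components (each evaluated on both cohorts):
#   (a) count:intensity correlation, binned on the weaker cohort:
#       < 0.75 -> 0; [0.75, 0.85) -> 1; [0.85, 0.95) -> 2; >= 0.95 -> 3.
#   (b) mean abundance in the upregulated group:
#       both >= 30 -> 3; both >= 15 -> 2; both <= 5 -> 0; otherwise 1.
#   (c) significance tier pair: T3:T3 -> 3; T2:T3 or T3:T2 -> 2;
#       T2:T2 -> 1; anything weaker -> 0.
#   (d) unique peptides per kDa of molecular weight:
#       both > 0.2 -> 2; both >= 0.1 -> 1; < 0.1 in either -> 0.
# Touching bin edges are resolved half-open from below with the top bin
# closed, keeping every component monotone in its inputs.

bin_correlation <- function(r) {
  ifelse(r < 0.75, 0L, ifelse(r < 0.85, 1L, ifelse(r < 0.95, 2L, 3L)))
}

bin_abundance <- function(lo, hi) {
  ifelse(lo >= 30, 3L, ifelse(lo >= 15, 2L, ifelse(hi <= 5, 0L, 1L)))
}

bin_tiers <- function(tier_d, tier_v) {
  rd <- tier_rank(tier_d)
  rv <- tier_rank(tier_v)
  lo <- pmin(rd, rv)
  hi <- pmax(rd, rv)
  ifelse(lo >= 3, 3L, ifelse(lo >= 2 & hi >= 3, 2L,
                             ifelse(lo >= 2, 1L, 0L)))
}

bin_pepratio <- function(lo) {
  ifelse(lo > 0.2, 2L, ifelse(lo >= 0.1, 1L, 0L))
}

#' Robustness components of a biomarker candidate
#'
#' Applies the four-part cumulative robustness rubric. All arguments are
#' vectorized; per-cohort values are supplied pairwise (discovery,
#' validation).
#'
#' @param corr_d,corr_v count:intensity Pearson correlation per cohort;
#'   `NA` (undefined correlation) scores 0 on component (a).
#' @param abund_d,abund_v mean normalized abundance in the upregulated
#'   group per cohort (spectral counts).
#' @param tier_d,tier_v significance tiers (`"none"`/`"T1"`/`"T2"`/`"T3"`).
#' @param pepratio_d,pepratio_v unique peptides divided by molecular
#'   weight in kDa, per cohort.
#' @param protein_id optional ids carried into the result.
#' @return data.frame with columns `comp_a` (0-3), `comp_b` (0-3),
#'   `comp_c` (0-3), `comp_d` (0-2) and `robustness_total` (0-11).
#' @export
robustness_components <- function(corr_d, corr_v, abund_d, abund_v,
                                  tier_d, tier_v, pepratio_d, pepratio_v,
                                  protein_id = NULL) {
  stopifnot(all(abund_d >= 0), all(abund_v >= 0),
            all(pepratio_d >= 0), all(pepratio_v >= 0))
  if (any(is.na(corr_d)) || any(is.na(corr_v)))
    message("missing count:intensity correlation(s); component (a) set to 0")
  corr_min <- pmin(corr_d, corr_v)
  comp_a <- ifelse(is.na(corr_min), 0L, bin_correlation(corr_min))
  comp_b <- bin_abundance(pmin(abund_d, abund_v), pmax(abund_d, abund_v))
  comp_c <- bin_tiers(tier_d, tier_v)
  comp_d <- bin_pepratio(pmin(pepratio_d, pepratio_v))
  out <- data.frame(comp_a = comp_a, comp_b = comp_b, comp_c = comp_c,
                    comp_d = comp_d,
                    robustness_total = comp_a + comp_b + comp_c + comp_d)
  if (!is.null(protein_id)) out <- cbind(protein_id = protein_id, out)
  out
}

#' Signature score of a protein
#'
#' Positional part: the protein's best rank across the top-30 lists of the
#' 4- and 5-protein combination searches, mapped ranks 1-10 to 3, 11-20 to
#' 2, 21-30 to 1, absent to 0. Plus 1 if the protein features in any
#' stepwise signature. Range 0-4.
#'
#' @param protein_id protein id (vectorized).
#' @param report a `ptx_signature_report` from [signature_report()].
#' @return integer score(s) in 0-4.
#' @export
signature_score <- function(protein_id, report) {
  stopifnot(inherits(report, "ptx_signature_report"))
  best_rank <- function(p) {
    r <- Inf
    for (tab in report$top30) {
      if (is.null(tab)) next
      hit <- tab$best_rank[tab$protein_id == p]
      if (length(hit)) r <- min(r, hit)
    }
    r
  }
  stepwise_members <- unique(unlist(lapply(report$stepwise, `[[`, "proteins")))
  vapply(protein_id, function(p) {
    r <- best_rank(p)
    positional <- if (r <= 10) 3L else if (r <= 20) 2L else if (r <= 30) 1L
    else 0L
    positional + as.integer(p %in% stepwise_members)
  }, integer(1), USE.NAMES = FALSE)
}

#' Composite ranking of scored candidates
#'
#' Sorts candidates by composite score (robustness + signature)
#' descending; ties are broken by robustness total, then by the product of
#' the two cohorts' p-values ascending, then by protein id. The rows with
#' robustness total at or above `threshold` form the reported "most
#' robust" subset.
#'
#' @param records data.frame with columns `protein_id`,
#'   `robustness_total`, `signature_score` and (optionally) `p_discovery`,
#'   `p_validation`.
#' @param threshold robustness cut-off for the reported subset.
#' @return `records` with `composite` and `rank` columns, ordered; the
#'   subset passing the threshold carries `robust = TRUE`.
#' @export
composite_rank <- function(records, threshold = 7) {
  records$composite <- records$robustness_total + records$signature_score
  p_prod <- if (all(c("p_discovery", "p_validation") %in% names(records)))
    records$p_discovery * records$p_validation else rep(0, nrow(records))
  ord <- order(-records$composite, -records$robustness_total, p_prod,
               records$protein_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  records$robust <- records$robustness_total >= threshold
  rownames(records) <- NULL
  records
}
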