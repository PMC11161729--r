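# Cross-cohort intersection of differential expression results, overlap
# significance, and prognostic-only flagging via the untreated arm.

#' Intersect discovery and validation DE results into validated candidates
#'
#' A protein becomes a candidate when it reaches `min_tier` in at least one
#' of the supplied comparisons in the discovery tables AND in at least one
#' comparison in the validation tables, with the same direction everywhere
#' it is significant. Discordant-direction proteins are excluded and
#' recorded in the `"discordant"` attribute.
#'
#' @param disc,val DE result data.frames (possibly stacked over the LUAD
#'   and panNSCLC comparisons) from [run_differential()].
#' @param min_tier `"T1"`, `"T2"` or `"T3"`.
#' @return data.frame of candidate records: `protein_id`, `direction`,
#'   `comparisons` (comma-joined comparisons in which the protein was
#'   significant in either cohort), `tier_discovery`, `tier_validation`
#'   (best tier across comparisons), `p_discovery`, `p_validation`
#'   (smallest p among significant rows). Attribute `"discordant"` lists
#'   excluded proteins.
#' @export
overlap_candidates <- function(disc, val, min_tier = "T1") {
  min_rank <- tier_rank(min_tier)
  if (is.na(min_rank) || min_rank < 1) stop("`min_tier` must be T1, T2 or T3")
  universe <- intersect(unique(disc$protein_id), unique(val$protein_id))
  if (length(universe) == 0)
    stop("discovery and validation tables share no proteins")

  sig_rows <- function(tab) tab[tier_rank(tab$tier) >= min_rank &
                                  tab$protein_id %in% universe, ]
  sd <- sig_rows(disc)
  sv <- sig_rows(val)
  hits <- intersect(unique(sd$protein_id), unique(sv$protein_id))

  records <- list()
  discordant <- character()
  for (p in sort(hits)) {
    rows_d <- sd[sd$protein_id == p, ]
    rows_v <- sv[sv$protein_id == p, ]
    dirs <- unique(c(rows_d$direction, rows_v$direction))
    if (length(dirs) > 1) {
      discordant <- c(discordant, p)
      next
    }
    records[[p]] <- data.frame(
      protein_id = p,
      direction = dirs,
      comparisons = paste(sort(unique(c(rows_d$comparison,
                                        rows_v$comparison))),
                          collapse = ","),
      tier_discovery = rows_d$tier[which.max(tier_rank(rows_d$tier))],
      tier_validation = rows_v$tier[which.max(tier_rank(rows_v$tier))],
      p_discovery = min(rows_d$p_value),
      p_validation = min(rows_v$p_value),
      stringsAsFactors = FALSE)
  }
  out <- if (length(records)) do.call(rbind, c(records, make.row.names = FALSE))
  else data.frame(protein_id = character(), direction = character(),
                  comparisons = character(), tier_discovery = character(),
                  tier_validation = character(), p_discovery = numeric(),
                  p_validation = numeric(), stringsAsFactors = FALSE)
  attr(out, "discordant") <- discordant
  out
}

#' Hypergeometric significance of a cross-cohort overlap
#'
#' Upper-tail probability of observing at least `n_overlap` shared hits
#' when `n_val` proteins are drawn from a universe containing `n_disc`
#' successes.
#'
#' @param n_disc number of discovery hits (successes in the universe).
#' @param n_val number of validation hits (draws).
#' @param n_overlap observed overlap.
#' @param universe number of proteins testable in both cohorts.
#' @return P(X >= n_overlap) under the hypergeometric null.
#' @export
overlap_significance <- function(n_disc, n_val, n_overlap, universe) {
  if (n_overlap > min(n_disc, n_val) || max(n_disc, n_val) > universe ||
      any(c(n_disc, n_val, n_overlap, universe) < 0))
    stop("inconsistent overlap counts")
  stats::phyper(n_overlap - 1, n_disc, universe - n_disc, n_val,
                lower.tail = FALSE)
}

#' Flag candidates that are prognostic rather than predictive
#'
#' A candidate is flagged when it is also differentially expressed (tier
#' T1 or better, concordant direction) in the untreated sub-cohort: its
#' association with outcome then does not depend on receiving chemotherapy.
#'
#' @param candidates candidate data.frame from [overlap_candidates()].
#' @param ut_results DE table computed on the untreated subset.
#' @return `candidates` with a logical `prognostic_flag` column.
#' @export
flag_prognostic <- function(candidates, ut_results) {
  sig <- ut_results[tier_rank(ut_results$tier) >= 1, ]
  key <- paste(sig$protein_id, sig$direction)
  candidates$prognostic_flag <-
    paste(candidates$protein_id, candidates$direction) %in% key
  candidates
}
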