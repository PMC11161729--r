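# Reproduction of the published candidate counts from deposited per-cohort
# differential expression tables.
#
# The study's deposited supplementary tables (per-cohort beta-binomial
# statistics and the robustness-score input table; ProteomeXchange
# PXD043078) are not redistributed with this package. When a user exports
# them to TSV in the layout documented below, this function recomputes the
# headline candidate counts from scratch with the package's own selection
# logic.

#' Recompute published candidate counts from deposited DE tables
#'
#' Expects a directory containing TSV exports of the deposited per-cohort
#' statistics:
#' \describe{
#'   \item{de_discovery.tsv / de_validation.tsv / de_untreated.tsv}{one row
#'     per protein per comparison with columns `protein_id`, `comparison`
#'     (`LUAD`/`LUSC`/`panNSCLC`), `p_value`, `direction`
#'     (`PRG_up`/`GRG_up`), `presence_up`, `fold_change`, `tier`.}
#'   \item{robustness_inputs.tsv}{one row per pan-NSCLC candidate with
#'     columns `protein_id`, `corr_d`, `corr_v`, `abund_d`, `abund_v`,
#'     `tier_d`, `tier_v`, `pepratio_d`, `pepratio_v`.}
#' }
#'
#' @param dir directory holding the TSV exports.
#' @return named list of recomputed counts: per-comparison discovery DEP
#'   counts (`dep_luad`, `dep_lusc`, `dep_pan`), `dep_multi` (proteins
#'   significant in more than one discovery comparison), `n_candidates`,
#'   `n_prg_up`, `n_ut_flagged`, and `n_robust` (robustness total >= 7).
#' @export
reproduce_published_counts <- function(dir) {
  need <- c("de_discovery.tsv", "de_validation.tsv", "de_untreated.tsv",
            "robustness_inputs.tsv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("deposited-table export(s) not found in `", dir, "`: ",
         paste(missing, collapse = ", "))
  disc <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
  val <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  ut <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  rob_in <- utils::read.delim(paths[4], stringsAsFactors = FALSE)

  sig <- function(tab, comp) tab[tab$comparison == comp & tab$p_value < 0.05, ]
  dep_luad <- nrow(sig(disc, "LUAD"))
  dep_lusc <- nrow(sig(disc, "LUSC"))
  dep_pan <- nrow(sig(disc, "panNSCLC"))
  sig_any <- disc[disc$p_value < 0.05, ]
  dep_multi <- sum(table(sig_any$protein_id) > 1)

  cand <- overlap_candidates(
    disc[disc$comparison %in% c("LUAD", "panNSCLC"), ],
    val[val$comparison %in% c("LUAD", "panNSCLC"), ],
    min_tier = "T1")
  cand <- flag_prognostic(cand, ut)

  rob <- robustness_components(rob_in$corr_d, rob_in$corr_v,
                               rob_in$abund_d, rob_in$abund_v,
                               rob_in$tier_d, rob_in$tier_v,
                               rob_in$pepratio_d, rob_in$pepratio_v,
                               protein_id = rob_in$protein_id)

  list(dep_luad = dep_luad, dep_lusc = dep_lusc, dep_pan = dep_pan,
       dep_multi = dep_multi,
       n_candidates = nrow(cand),
       n_prg_up = sum(cand$direction == "PRG_up"),
       n_ut_flagged = sum(cand$prognostic_flag),
       n_robust = sum(rob$robustness_total >= 7))
}
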