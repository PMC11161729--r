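# Spectral-count normalization, protein filtering and per-group summary
# statistics.

#' Normalize spectral counts on the sample sum
#'
#' Each sample's counts are scaled by (average sample total / that sample's
#' total), so all samples end up with the same total count equal to the
#' pre-normalization mean sample sum.
#'
#' @param raw a `ptx_matrix` with layer `"raw_sc"` (any non-negative matrix
#'   is accepted).
#' @return a `ptx_matrix` with layer `"normalized_sc"`, same dimnames.
#' @export
normalize_counts <- function(raw) {
  totals <- colSums(raw)
  if (any(totals == 0)) {
    bad <- colnames(raw)[totals == 0]
    stop("sample(s) with zero total counts cannot be normalized: ",
         paste(bad, collapse = ", "))
  }
  factors <- mean(totals) / totals
  out <- sweep(unclass(raw), 2, factors, `*`)
  attr(out, "layer") <- NULL
  class(out) <- NULL
  ptx_matrix(out, "normalized_sc")
}

presence_fraction <- function(matrix, sample_ids) {
  rowMeans(matrix[, sample_ids, drop = FALSE] > 0)
}

#' Filter proteins on group-wise data presence
#'
#' Retains proteins whose data presence (fraction of samples with a nonzero
#' count) reaches `min_presence` in at least one of the supplied sample
#' groups.
#'
#' @param matrix a `ptx_matrix`.
#' @param min_presence required presence fraction in [0, 1].
#' @param groups list of sample-id character vectors defining the annotated
#'   groups; defaults to a single group of all samples.
#' @return the filtered `ptx_matrix`; removed protein ids are attached as
#'   attribute `"removed"`.
#' @export
filter_proteins <- function(matrix, min_presence, groups = NULL) {
  if (min_presence < 0 || min_presence > 1)
    stop("`min_presence` must lie in [0, 1]")
  if (is.null(groups)) groups <- list(colnames(matrix))
  for (g in groups) check_samples_known(g, matrix)
  pres <- vapply(groups, function(g) presence_fraction(matrix, g),
                 numeric(nrow(matrix)))
  pres <- matrix(pres, nrow = nrow(matrix))
  keep <- apply(pres, 1, max) >= min_presence
  removed <- rownames(matrix)[!keep]
  out <- subset_matrix(matrix, i = which(keep))
  attr(out, "removed") <- removed
  out
}

#' Build per-cohort/subtype sample groups from an annotation table
#'
#' Convenience for [filter_proteins()]: one group per cohort x subtype
#' combination present among the given samples.
#'
#' @param annotation sample annotation data.frame.
#' @param sample_ids optional restriction to a sample subset.
#' @return named list of sample-id vectors.
#' @export
annotation_groups <- function(annotation, sample_ids = NULL) {
  ann <- annotation
  if (!is.null(sample_ids)) ann <- ann[ann$sample_id %in% sample_ids, ]
  split(ann$sample_id, interaction(ann$cohort, ann$subtype, drop = TRUE))
}

#' Per-protein two-group summary statistics
#'
#' For each protein: group means on normalized counts, data presence per
#' group, the upregulated group, a fold-change ratio (>= 1 by convention,
#' with the direction given by `upregulated_group`), and the Pearson
#' correlation between spectral counts and MS1 intensities across all
#' samples of the cohort.
#'
#' @param norm normalized-count `ptx_matrix`.
#' @param intensities intensity-layer `ptx_matrix` with identical dimnames
#'   (may be `NULL` to skip the correlation).
#' @param group_a,group_b disjoint, non-empty sample-id vectors.
#' @param pseudocount added to both means before forming the ratio; avoids
#'   division by zero for presence-asymmetric proteins.
#' @return data.frame with one row per protein: `protein_id`, `mean_a`,
#'   `mean_b`, `presence_a`, `presence_b`, `upregulated_group` ("A"/"B"),
#'   `fold_change`, `sc_intensity_r` (NA when either vector is constant).
#' @export
group_stats <- function(norm, intensities, group_a, group_b,
                        pseudocount = 0.5) {
  check_samples_known(group_a, norm)
  check_samples_known(group_b, norm)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")

  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  pres_a <- presence_fraction(norm, group_a)
  pres_b <- presence_fraction(norm, group_b)
  # ties go to group A (logged through the value itself)
  up_a <- mean_a >= mean_b
  fc <- ifelse(up_a,
               (mean_a + pseudocount) / (mean_b + pseudocount),
               (mean_b + pseudocount) / (mean_a + pseudocount))

  r <- rep(NA_real_, nrow(norm))
  if (!is.null(intensities)) {
    stopifnot(identical(rownames(norm), rownames(intensities)))
    cols <- colnames(norm)
    r <- sc_intensity_correlation(norm, intensities, cols)
  }

  data.frame(protein_id = rownames(norm),
             mean_a = mean_a, mean_b = mean_b,
             presence_a = pres_a, presence_b = pres_b,
             upregulated_group = ifelse(up_a, "A", "B"),
             fold_change = fc,
             sc_intensity_r = r,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-protein Pearson correlation between counts and intensities
#'
#' @param counts,intensities matrices with matching dimnames.
#' @param sample_ids samples over which to correlate (default: all).
#' @return named numeric vector; NA where either vector is constant.
#' @export
sc_intensity_correlation <- function(counts, intensities,
                                     sample_ids = colnames(counts)) {
  x <- counts[, sample_ids, drop = FALSE]
  y <- intensities[, sample_ids, drop = FALSE]
  out <- vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]; yi <- y[i, ]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) return(NA_real_)
    stats::cor(xi, yi)
  }, numeric(1))
  names(out) <- rownames(x)
  out
}
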