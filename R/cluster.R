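# Unsupervised sample clustering and association of the flagged cluster
# with outcome (poor-response/survival sub-cluster detection).

#' Hierarchical clustering of samples
#'
#' Samples are clustered on log2(x + 1)-transformed, per-protein
#' standardized (relative-expression) normalized counts with correlation
#' distance (1 - Pearson correlation between sample profiles) and average
#' linkage, and the tree is cut at `k` clusters. Row standardization stops
#' the shared abundance spectrum from dominating every between-sample
#' correlation. Deterministic; invariant to protein order and global
#' scaling.
#'
#' @param norm normalized-count `ptx_matrix`.
#' @param k number of clusters to cut (default 3: the two
#'   histology-dominated clusters plus a mixed sub-cluster).
#' @param annotation optional sample annotation; if given, per-cluster
#'   subtype composition is tabulated.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return a `ptx_clustering`: `tree` (hclust), `assignment` (named
#'   integer vector), `k`, `n_identified` (per-sample nonzero protein
#'   count), and `subtype_composition` when annotation is supplied.
#' @export
cluster_samples <- function(norm, k = 3, annotation = NULL,
                            distance = c("correlation", "euclidean"),
                            linkage = "average") {
  distance <- match.arg(distance)
  if (k > ncol(norm)) stop("k exceeds the number of samples")
  x <- log2(unclass(norm) + 1)
  keep <- apply(x, 1, stats::sd) > 0
  x <- t(scale(t(x[keep, , drop = FALSE])))
  d <- if (distance == "correlation") stats::as.dist(1 - stats::cor(x))
  else stats::dist(t(x))
  tree <- stats::hclust(d, method = linkage)
  assignment <- stats::cutree(tree, k = k)
  out <- list(tree = tree, assignment = assignment, k = k,
              n_identified = colSums(unclass(norm) > 0))
  if (!is.null(annotation)) {
    ann <- annotation[match(names(assignment), annotation$sample_id), ]
    out$subtype_composition <- table(cluster = assignment,
                                     subtype = ann$subtype)
  }
  class(out) <- "ptx_clustering"
  out
}

#' @export
print.ptx_clustering <- function(x, ...) {
  cat(sprintf("<ptx_clustering> %d samples in %d clusters (sizes: %s)\n",
              length(x$assignment), x$k,
              paste(table(x$assignment), collapse = ", ")))
  invisible(x)
}

#' Export a clustering dendrogram as Newick text
#'
#' @param clustering a `ptx_clustering`.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(clustering) {
  ape::write.tree(ape::as.phylo(clustering$tree))
}

#' Associate the poorest-outcome cluster with response and survival
#'
#' Flags the cluster with the highest fraction of poor-response (PRG)
#' samples, tests its PRG enrichment with a one-sided Fisher exact test
#' (equivalently the hypergeometric upper tail), and compares its RFS to
#' all other samples with a log-rank test.
#'
#' @param clustering a `ptx_clustering`.
#' @param annotation sample annotation with `rfs_months` and `event`.
#' @return list with `flagged_cluster`, `fisher_p`, `logrank` (from
#'   [logrank_test()]), and the per-cluster PRG fractions.
#' @export
cluster_outcome_association <- function(clustering, annotation) {
  ann <- assign_response_groups(annotation)
  ann <- ann[match(names(clustering$assignment), ann$sample_id), ]
  if (any(is.na(ann$sample_id)))
    stop("clustering and annotation do not share all samples")
  keep <- !is.na(ann$rfs_months)
  if (!all(keep)) warning("excluding samples without outcome data")
  cl <- clustering$assignment[keep]
  ann <- ann[keep, ]
  prg <- ann$response_group == "PRG"
  frac <- tapply(prg, cl, mean)
  flagged <- as.integer(names(frac)[which.max(frac)])
  inside <- cl == flagged
  tab <- matrix(c(sum(inside & prg), sum(inside & !prg),
                  sum(!inside & prg), sum(!inside & !prg)), nrow = 2)
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  lr <- logrank_test(ann$rfs_months[inside], ann$event[inside],
                     ann$rfs_months[!inside], ann$event[!inside])
  list(flagged_cluster = flagged, fisher_p = fisher_p, logrank = lr,
       prg_fraction = frac)
}
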