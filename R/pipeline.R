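# End-to-end orchestration: simulate -> preprocess -> differential testing
# -> cross-cohort candidates -> signature search -> scoring -> survival and
# cluster structure, with TSV/JSON artifact output and a provenance
# manifest. All randomness flows from the single pipeline seed through
# fixed per-stage offsets.

#' Pipeline configuration
#'
#' @param generation a `ptx_config` for the synthetic-cohort stage (its
#'   seed is overridden by the pipeline seed).
#' @param min_presence protein-filter presence threshold within at least
#'   one cohort x subtype group.
#' @param pseudocount fold-change pseudocount.
#' @param tier minimum tier for cross-cohort candidate intersection.
#' @param pool_correlation_gate combined-dataset count:intensity
#'   correlation required for a candidate to enter the signature search.
#' @param k_exhaustive,k_random subset sizes of the exhaustive and random
#'   searches.
#' @param n_draws random-probe draw count.
#' @param top_f top-combination count for frequency tables.
#' @param epsilon stepwise-selection improvement threshold.
#' @param robustness_threshold robustness cut-off for the reported subset.
#' @param quantile abundance-split quantile.
#' @param max_pool cap on the signature-search pool size (candidates are
#'   prioritized by cross-cohort p-value product).
#' @param seed global pipeline seed.
#' @param out_dir artifact directory, or `NULL` to skip writing.
#' @return a `ptx_pipeline_config` list.
#' @export
pipeline_config <- function(generation = generation_config(),
                            min_presence = 0.5,
                            pseudocount = 0.5,
                            tier = "T1",
                            pool_correlation_gate = 0.75,
                            k_exhaustive = 4,
                            k_random = 5,
                            n_draws = 500,
                            top_f = 100,
                            epsilon = 0.005,
                            robustness_threshold = 7,
                            quantile = 0.75,
                            max_pool = 12,
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "ptx_pipeline_config"
  cfg
}

# choose the per-cohort DE row used for a candidate's rubric inputs:
# prefer the pan-NSCLC comparison, fall back to LUAD
candidate_row <- function(tab, protein) {
  rows <- tab[tab$protein_id == protein, ]
  if (nrow(rows) == 0) return(NULL)
  pan <- rows[rows$comparison == "panNSCLC", ]
  if (nrow(pan)) pan[1, ] else rows[1, ]
}

#' Run the full biomarker-discovery pipeline on a synthetic cohort pair
#'
#' Executes all stages in order and returns the result bundle. Stages that
#' cannot run on the realized data (e.g. an underpowered validation LUSC
#' contrast) are skipped and recorded in `log` rather than aborting,
#' mirroring how such contrasts are excluded in practice.
#'
#' @param config a `ptx_pipeline_config`.
#' @return a `ptx_pipeline_result` list: `cohorts`, `norm`, `de` (list of
#'   DE tables), `overlap` (hypergeometric overlap of the pan-NSCLC
#'   contrast), `candidates`, `scored` (composite-ranked table), `search`
#'   (signature reports), `clustering` and `survival` summaries, `log`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ptx_pipeline_config"))
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  gen_cfg <- config$generation
  gen_cfg$seed <- as.integer(config$seed + 1L)
  cohorts <- generate_cohorts(gen_cfg)
  ann <- cohorts$samples

  norm <- lapply(cohorts$counts, normalize_counts)
  filtered <- list()
  for (co in names(norm)) {
    groups <- annotation_groups(ann, colnames(norm[[co]]))
    filtered[[co]] <- filter_proteins(norm[[co]], config$min_presence, groups)
  }

  de <- list()
  contrasts <- rbind(
    expand.grid(comparison = c("panNSCLC", "LUAD", "LUSC"),
                cohort = c("discovery", "validation"),
                stringsAsFactors = FALSE),
    data.frame(comparison = "panNSCLC", cohort = "untreated"))
  for (i in seq_len(nrow(contrasts))) {
    comp <- contrasts$comparison[i]
    coh <- contrasts$cohort[i]
    mat_name <- if (coh == "discovery") "discovery" else "validation"
    mat <- filtered[[mat_name]]
    intens <- subset_matrix(cohorts$intensities[[mat_name]],
                            i = rownames(mat))
    res <- tryCatch(
      run_differential(mat, ann, comp, coh, intensities = intens,
                       pseudocount = config$pseudocount),
      error = function(e) {
        note(sprintf("skipped %s/%s: %s", comp, coh, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) de[[paste(coh, comp, sep = "_")]] <- res
  }

  # hypergeometric overlap of the pan-NSCLC T1 hit lists
  overlap <- NULL
  if (!is.null(de$discovery_panNSCLC) && !is.null(de$validation_panNSCLC)) {
    dtab <- de$discovery_panNSCLC
    vtab <- de$validation_panNSCLC
    shared <- intersect(dtab$protein_id, vtab$protein_id)
    hd <- dtab$protein_id[dtab$p_value < 0.05 & dtab$protein_id %in% shared]
    hv <- vtab$protein_id[vtab$p_value < 0.05 & vtab$protein_id %in% shared]
    overlap <- list(n_disc = length(hd), n_val = length(hv),
                    n_overlap = length(intersect(hd, hv)),
                    universe = length(shared))
    overlap$p_value <- overlap_significance(overlap$n_disc, overlap$n_val,
                                            overlap$n_overlap,
                                            overlap$universe)
  }

  disc_stack <- do.call(rbind, de[grepl("^discovery_(panNSCLC|LUAD)$",
                                        names(de))])
  val_stack <- do.call(rbind, de[grepl("^validation_(panNSCLC|LUAD)$",
                                       names(de))])
  candidates <- overlap_candidates(disc_stack, val_stack,
                                   min_tier = config$tier)
  if (!is.null(de$untreated_panNSCLC)) {
    candidates <- flag_prognostic(candidates, de$untreated_panNSCLC)
  } else {
    candidates$prognostic_flag <- NA
    note("untreated contrast unavailable; prognostic flag not set")
  }

  # robustness rubric inputs per cohort
  meta <- cohorts$protein_meta
  scored <- NULL
  search <- NULL
  if (nrow(candidates) > 0) {
    pick <- function(tab, proteins, col) {
      vapply(proteins, function(p) {
        row <- candidate_row(tab, p)
        if (is.null(row)) NA_real_ else as.numeric(row[[col]])
      }, numeric(1))
    }
    pid <- candidates$protein_id
    mi <- match(pid, meta$protein_id)
    rob <- robustness_components(
      corr_d = pick(disc_stack, pid, "sc_intensity_r"),
      corr_v = pick(val_stack, pid, "sc_intensity_r"),
      abund_d = pick(disc_stack, pid, "mean_up"),
      abund_v = pick(val_stack, pid, "mean_up"),
      tier_d = candidates$tier_discovery,
      tier_v = candidates$tier_validation,
      pepratio_d = meta$peptides_discovery[mi] / meta$mw_kda[mi],
      pepratio_v = meta$peptides_validation[mi] / meta$mw_kda[mi],
      protein_id = pid)

    search <- run_signature_search(config, cohorts, norm, candidates, note)
    sig <- if (is.null(search$report)) rep(0L, length(pid))
    else signature_score(pid, search$report)

    scored <- cbind(candidates, rob[, -1], signature_score = sig)
    scored <- composite_rank(scored, threshold = config$robustness_threshold)
  } else {
    note("no cross-cohort candidates; scoring skipped")
  }

  # cohort structure: clustering and outcome association per cohort
  clustering <- list()
  for (co in names(filtered)) {
    cl <- cluster_samples(filtered[[co]], k = 3, annotation = ann)
    assoc <- tryCatch(cluster_outcome_association(cl, ann),
                      error = function(e) {
                        note(sprintf("cluster association (%s): %s", co,
                                     conditionMessage(e)))
                        NULL
                      })
    clustering[[co]] <- list(clustering = cl, association = assoc)
  }

  # abundance-quartile survival split of the top-ranked candidate in the
  # validation treated arm
  surv <- NULL
  if (!is.null(scored) && nrow(scored) > 0) {
    top <- scored$protein_id[1]
    act_val <- ann$sample_id[ann$cohort == "validation" &
                               ann$treatment == "ACT"]
    vmat <- subset_matrix(filtered$validation, j = act_val)
    surv <- tryCatch({
      split <- abundance_split(vmat, top, config$quantile)
      sub <- ann[match(colnames(vmat), ann$sample_id), ]
      hi <- sub$sample_id %in% split$high
      lr <- logrank_test(sub$rfs_months[hi], sub$event[hi],
                         sub$rfs_months[!hi], sub$event[!hi])
      list(protein = top, n_high = sum(hi), n_low = sum(!hi), logrank = lr)
    }, error = function(e) {
      note(sprintf("abundance split: %s", conditionMessage(e)))
      NULL
    })
  }

  manifest <- list(
    package = "ptxrank",
    version = as.character(utils::packageVersion("ptxrank")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("generation", "out_dir"))],
    generation = unclass(config$generation),
    n_candidates = nrow(candidates),
    log = log)

  result <- list(cohorts = cohorts, norm = norm, filtered = filtered,
                 de = de, overlap = overlap, candidates = candidates,
                 scored = scored, search = search, clustering = clustering,
                 survival = surv, log = log, manifest = manifest)
  class(result) <- "ptx_pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

run_signature_search <- function(config, cohorts, norm, candidates, note) {
  # pool gate: combined-dataset count:intensity correlation
  shared <- intersect(rownames(norm$discovery), rownames(norm$validation))
  comb_counts <- cbind(unclass(norm$discovery)[shared, , drop = FALSE],
                       unclass(norm$validation)[shared, , drop = FALSE])
  comb_intens <- cbind(
    unclass(cohorts$intensities$discovery)[shared, , drop = FALSE],
    unclass(cohorts$intensities$validation)[shared, , drop = FALSE])
  comb_r <- sc_intensity_correlation(comb_counts, comb_intens)

  pid <- intersect(candidates$protein_id, shared)
  gate <- pid[!is.na(comb_r[pid]) &
                comb_r[pid] > config$pool_correlation_gate]
  if (length(gate) > config$max_pool) {
    pp <- candidates$p_discovery * candidates$p_validation
    names(pp) <- candidates$protein_id
    gate <- gate[order(pp[gate])][seq_len(config$max_pool)]
  }
  if (length(gate) < config$k_exhaustive) {
    note(sprintf("signature search skipped: pool of %d below k=%d",
                 length(gate), config$k_exhaustive))
    return(list(pool = gate, report = NULL))
  }

  # classifier data: combined treated PRG/GRG samples, log-scale features
  ann <- assign_response_groups(cohorts$samples)
  use <- ann$sample_id[ann$treatment == "ACT" &
                         ann$response_group %in% c("PRG", "GRG")]
  use <- intersect(use, colnames(comb_counts))
  feats <- t(log2(comb_counts[gate, use, drop = FALSE] + 1))
  labels <- ann$response_group[match(use, ann$sample_id)]

  rep4 <- exhaustive_search(gate, k = config$k_exhaustive, data = feats,
                            labels = labels, top_f = config$top_f)
  rep5 <- if (length(gate) >= config$k_random)
    random_probe(gate, k = config$k_random, n_draws = config$n_draws,
                 data = feats, labels = labels,
                 seed = as.integer(config$seed + 2L), top_f = config$top_f)
  else NULL
  sw_auc <- stepwise_signature(gate, feats, labels, start = "highest_auc",
                               epsilon = config$epsilon)
  sw_rob <- NULL
  # most-robust start: highest preliminary robustness-relevant evidence;
  # approximated before scoring by the smallest cross-cohort p product
  pp <- candidates$p_discovery * candidates$p_validation
  names(pp) <- candidates$protein_id
  most_robust <- gate[order(pp[gate])][1]
  if (!identical(most_robust, sw_auc$start)) {
    sw_rob <- stepwise_signature(gate, feats, labels, start = most_robust,
                                 epsilon = config$epsilon)
  }
  stepwise <- Filter(Negate(is.null), list(sw_auc, sw_rob))
  list(pool = gate, features = feats, labels = labels,
       exhaustive = rep4, random = rep5, stepwise = stepwise,
       report = signature_report(rep4, rep5, stepwise))
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohorts(result$cohorts, file.path(dir, "input"))
  for (nm in names(result$de)) {
    utils::write.table(result$de[[nm]],
                       file.path(dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$scored))
    utils::write.table(result$scored,
                       file.path(dir, "ranked_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- result$clustering
  clusters <- do.call(rbind, lapply(names(cl), function(co) {
    a <- cl[[co]]$clustering$assignment
    data.frame(sample_id = names(a), cohort = co, cluster = unname(a))
  }))
  utils::write.table(clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (co in names(cl)) {
    writeLines(dendrogram_newick(cl[[co]]$clustering),
               file.path(dir, paste0("dendrogram_", co, ".nwk")))
  }
  if (!is.null(result$search) && !is.null(result$search$report)) {
    rep <- result$search
    jsonlite::write_json(
      list(pool = rep$pool,
           exhaustive_top = utils::head(rep$exhaustive$ranked, 30),
           random_top = if (!is.null(rep$random))
             utils::head(rep$random$ranked, 30),
           stepwise = lapply(rep$stepwise, function(s)
             list(proteins = s$proteins, loocv_auc = s$loocv_auc))),
      file.path(dir, "search_report.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$survival)) {
    jsonlite::write_json(
      list(protein = result$survival$protein,
           n_high = result$survival$n_high, n_low = result$survival$n_low,
           chisq = result$survival$logrank$chisq,
           p_value = result$survival$logrank$p_value),
      file.path(dir, "survival_report.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$overlap))
    jsonlite::write_json(result$overlap, file.path(dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.ptx_pipeline_result <- function(x, ...) {
  cat("<ptx_pipeline_result>\n")
  cat(sprintf("  DE contrasts run: %s\n", paste(names(x$de), collapse = ", ")))
  cat(sprintf("  candidates: %d", nrow(x$candidates)))
  if (!is.null(x$scored))
    cat(sprintf(" (robust subset: %d)", sum(x$scored$robust)))
  cat("\n")
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}
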