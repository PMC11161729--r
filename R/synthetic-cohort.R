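# Synthetic paired-cohort generator with planted ground truth.
#
# The generator emulates the statistical structure of two-cohort FFPE
# spectral-count proteomics of platinum-treated NSCLC: overdispersed
# (beta-binomial) counts with zero inflation, a poor-response/survival
# (PR/S) sample block with an up-shifted stromal protein module and fewer
# protein identifications, planted differentially expressed proteins with a
# fixed fold-change in both cohorts, a parallel MS1-intensity layer
# correlated with counts, and recurrence-free survival with
# response-group-dependent hazards.

# fraction of the proteome designated "stromal" and its up-shift in PR/S
# member samples; extra dropout applied to the remaining proteins there
PRS_STROMAL_FRACTION <- 0.10
PRS_STROMAL_SHIFT <- 3
PRS_EXTRA_DROPOUT <- 0.10

# histology block: a fixed protein module elevated in squamous samples
# (keratin-like), so unsupervised clustering is dominated by subtype
# biology and resolves LUAD-enriched, LUSC-enriched and mixed clusters
SUBTYPE_FRACTION <- 0.10
SUBTYPE_SHIFT <- 3

# the simulated panel is treated as a subsample of a ~4000-protein FFPE
# proteome, so per-protein depth averages ~25 spectral counts and spans the
# abundance bins used by the robustness rubric
REFERENCE_PROTEOME_SIZE <- 4000
ADMIN_CENSOR_MONTHS <- 36

#' Default synthetic-cohort configuration
#'
#' Mirrors the clinical study design the package targets: a 45-patient
#' discovery cohort, a validation cohort of 22 treated plus 10 untreated
#' patients, roughly 58% adenocarcinoma, and a poor-response/survival
#' sub-cluster comprising ~26% of samples.
#'
#' @param ... named overrides for any configuration field.
#' @return a `ptx_config` list; see [generation_config()] for fields.
#' @export
default_config <- function(...) generation_config(...)

#' Synthetic-cohort configuration
#'
#' @param n_proteins number of simulated proteins.
#' @param n_samples_discovery discovery-cohort size (treated arm).
#' @param n_samples_validation_act validation-cohort treated-arm size.
#' @param n_samples_validation_ut validation-cohort untreated-arm size.
#' @param luad_fraction fraction of adenocarcinoma (vs squamous) samples in
#'   the treated arms; the untreated arm is all adenocarcinoma.
#' @param prs_cluster_fraction fraction of samples forming the planted
#'   poor-response/survival (PR/S) sub-cluster.
#' @param n_planted_de number of planted differentially expressed proteins
#'   (half up in the poor-response group, half up in the good-response group).
#' @param planted_fc true group-mean fold-change of planted proteins (> 1).
#' @param dispersion beta-binomial overdispersion in [0, 1): the squared
#'   between-sample (biological) coefficient of variation of a protein's
#'   underlying proportion; 0 degenerates to pure binomial sampling.
#' @param zero_inflation baseline dropout probability applied to counts.
#' @param sc_intensity_noise lognormal sigma of the intensity layer's
#'   multiplicative noise around counts.
#' @param rfs_hazard_prg,rfs_hazard_grg recurrence hazards (events/month)
#'   for poor- and good-response samples.
#' @param censor_rate probability that an observed time is non-event
#'   (censored) beyond the administrative 36-month cut-off.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return a `ptx_config` list.
#' @export
generation_config <- function(n_proteins = 500,
                              n_samples_discovery = 45,
                              n_samples_validation_act = 22,
                              n_samples_validation_ut = 10,
                              luad_fraction = 0.58,
                              prs_cluster_fraction = 0.26,
                              n_planted_de = 50,
                              planted_fc = 2,
                              dispersion = 0.05,
                              zero_inflation = 0.2,
                              sc_intensity_noise = 0.1,
                              rfs_hazard_prg = 0.12,
                              rfs_hazard_grg = 0.04,
                              censor_rate = 0.1,
                              seed = 1L) {
  cfg <- list(n_proteins = n_proteins,
              n_samples_discovery = n_samples_discovery,
              n_samples_validation_act = n_samples_validation_act,
              n_samples_validation_ut = n_samples_validation_ut,
              luad_fraction = luad_fraction,
              prs_cluster_fraction = prs_cluster_fraction,
              n_planted_de = n_planted_de,
              planted_fc = planted_fc,
              dispersion = dispersion,
              zero_inflation = zero_inflation,
              sc_intensity_noise = sc_intensity_noise,
              rfs_hazard_prg = rfs_hazard_prg,
              rfs_hazard_grg = rfs_hazard_grg,
              censor_rate = censor_rate,
              seed = as.integer(seed))
  class(cfg) <- "ptx_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c("n_proteins", "n_samples_discovery", "n_samples_validation_act",
              "n_samples_validation_ut", "n_planted_de")
  for (f in counts) {
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("`", f, "` must be a non-negative integer")
  }
  if (cfg$n_proteins < 1) stop("`n_proteins` must be positive")
  fracs <- c("luad_fraction", "prs_cluster_fraction", "zero_inflation",
             "censor_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("`", f, "` must lie in [0, 1]")
  }
  if (cfg$planted_fc <= 1) stop("`planted_fc` must exceed 1")
  if (cfg$dispersion < 0 || cfg$dispersion >= 1)
    stop("`dispersion` must lie in [0, 1)")
  if (cfg$rfs_hazard_prg <= 0 || cfg$rfs_hazard_grg <= 0)
    stop("hazards must be positive")
  if (cfg$n_planted_de > cfg$n_proteins)
    stop("impossible configuration: n_planted_de > n_proteins")
  n_blocks <- ceiling(PRS_STROMAL_FRACTION * cfg$n_proteins) +
    ceiling(SUBTYPE_FRACTION * cfg$n_proteins)
  if (cfg$n_planted_de > cfg$n_proteins - n_blocks)
    stop("impossible configuration: not enough unreserved proteins to plant")
  invisible(cfg)
}

#' @export
print.ptx_config <- function(x, ...) {
  cat("<ptx_config>\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}

# run expr with a private RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate paired synthetic discovery/validation cohorts
#'
#' Draws protein-by-sample spectral-count matrices for a discovery cohort
#' and a validation cohort (treated + untreated arms), parallel intensity
#' layers, per-protein metadata, per-sample annotations, and the planted
#' ground truth. Counts are beta-binomial given a per-sample library size;
#' planted proteins have group mean proportion ratio equal to
#' `planted_fc` between response groups in both cohorts; PR/S member
#' samples carry a 3x up-shifted stromal protein block and extra dropout
#' elsewhere; recurrence-free survival is exponential with response-group
#' hazards, administratively censored at 36 months.
#'
#' @param config a `ptx_config` from [generation_config()].
#' @return a `ptx_cohorts` list with elements `counts` (list of
#'   `discovery`/`validation` raw-count matrices), `intensities` (same
#'   shape), `protein_meta`, `samples` (annotation data.frame), `truth`
#'   (planted ground truth), and `config`.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "ptx_config"))
  validate_config(config)
  with_seed(config$seed, generate_cohorts_impl(config))
}

generate_cohorts_impl <- function(cfg) {
  n_p <- cfg$n_proteins
  protein_ids <- sprintf("P%04d", seq_len(n_p))
  n_stromal <- ceiling(PRS_STROMAL_FRACTION * n_p)
  stromal <- protein_ids[seq_len(n_stromal)]
  n_subtype <- ceiling(SUBTYPE_FRACTION * n_p)
  subtype_block <- protein_ids[n_stromal + seq_len(n_subtype)]

  # base relative abundances: lognormal spectrum scaled so the panel
  # behaves like a subsample of a larger proteome (~25 counts/protein)
  w <- stats::rlnorm(n_p, meanlog = 0, sdlog = 1.2)
  pi_base <- w / sum(w) * (n_p / REFERENCE_PROTEOME_SIZE)
  names(pi_base) <- protein_ids

  # plant DE proteins outside the stromal and subtype blocks, among
  # proteins that are quantifiable (expected depth >= 10 counts): planted
  # effects emulate validated biomarker candidates, which are
  # well-measured by design
  plantable <- setdiff(protein_ids, c(stromal, subtype_block))
  expected <- pi_base[plantable] * 1e5
  quantifiable <- plantable[expected >= 10]
  if (length(quantifiable) < cfg$n_planted_de) {
    quantifiable <- plantable[order(-expected)][seq_len(cfg$n_planted_de)]
  }
  planted_ids <- sort(sample(quantifiable, cfg$n_planted_de))
  n_up <- ceiling(cfg$n_planted_de / 2)
  direction <- rep(c("PRG_up", "GRG_up"),
                   c(n_up, cfg$n_planted_de - n_up))
  # ~10% of planted effects are treatment-independent (prognostic: present
  # in treated and untreated arms alike); the rest are predictive,
  # separating responders only among chemotherapy-treated samples
  n_prog <- floor(cfg$n_planted_de / 10)
  type <- rep("predictive", cfg$n_planted_de)
  if (n_prog > 0)
    type[sample(cfg$n_planted_de, n_prog)] <- "prognostic"
  planted <- data.frame(protein_id = planted_ids, direction = direction,
                        type = type,
                        true_fc = rep(cfg$planted_fc, cfg$n_planted_de),
                        stringsAsFactors = FALSE)

  samples <- build_sample_frame(cfg)
  prs_members <- samples$sample_id[samples$prs_member]

  mats <- lapply(split(samples, samples$cohort), function(ann) {
    draw_cohort_counts(cfg, pi_base, stromal, subtype_block, planted, ann)
  })
  counts <- lapply(mats, `[[`, "counts")
  intensities <- lapply(mats, `[[`, "intensity")

  protein_meta <- draw_protein_meta(protein_ids, pi_base)

  truth <- list(planted = planted,
                prs_members = prs_members,
                response_label = stats::setNames(samples$response_group,
                                                 samples$sample_id),
                stromal_proteins = stromal,
                subtype_proteins = subtype_block)
  class(truth) <- "ptx_truth"

  ann <- samples[, c("sample_id", "cohort", "subtype", "treatment",
                     "rfs_months", "event", "tcp")]
  out <- list(counts = counts[c("discovery", "validation")],
              intensities = intensities[c("discovery", "validation")],
              protein_meta = protein_meta,
              samples = ann,
              truth = truth,
              config = cfg)
  class(out) <- "ptx_cohorts"
  out
}

build_sample_frame <- function(cfg) {
  mk <- function(prefix, n, cohort, treatment) {
    if (n == 0) return(NULL)
    data.frame(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
               cohort = cohort, treatment = treatment,
               stringsAsFactors = FALSE)
  }
  samples <- rbind(mk("D", cfg$n_samples_discovery, "discovery", "ACT"),
                   mk("V", cfg$n_samples_validation_act, "validation", "ACT"),
                   mk("U", cfg$n_samples_validation_ut, "validation", "UT"))

  # subtype: treated arms mixed, untreated arm all LUAD (study design)
  samples$subtype <- ifelse(
    samples$treatment == "UT", "LUAD",
    ifelse(stats::runif(nrow(samples)) < cfg$luad_fraction, "LUAD", "LUSC"))

  # PR/S members drawn per cohort among treated samples
  samples$prs_member <- FALSE
  for (co in unique(samples$cohort)) {
    idx <- which(samples$cohort == co & samples$treatment == "ACT")
    n_prs <- round(cfg$prs_cluster_fraction *
                     sum(samples$cohort == co))
    n_prs <- min(n_prs, length(idx))
    samples$prs_member[sample(idx, n_prs)] <- TRUE
  }

  # response labels: PR/S members are poor responders; remaining treated
  # samples mostly respond well; the small untreated arm is balanced more
  # evenly so the prognostic contrast stays estimable
  lab <- character(nrow(samples))
  lab[samples$prs_member] <- "PRG"
  rest <- !samples$prs_member
  ut <- samples$treatment == "UT"
  lab[rest & !ut] <- sample(c("PRG", "intermediate", "GRG"),
                            sum(rest & !ut), replace = TRUE,
                            prob = c(0.15, 0.15, 0.70))
  lab[rest & ut] <- sample(c("PRG", "intermediate", "GRG"),
                           sum(rest & ut), replace = TRUE,
                           prob = c(0.35, 0.10, 0.55))
  samples$response_group <- lab
  samples <- ensure_min_groups(samples)

  # RFS consistent with the label thresholds (PRG <= 16, GRG > 24 months)
  n <- nrow(samples)
  rfs <- numeric(n)
  prg <- samples$response_group == "PRG"
  grg <- samples$response_group == "GRG"
  mid <- samples$response_group == "intermediate"
  # truncated exponential on (0, 16]
  u <- stats::runif(sum(prg))
  rfs[prg] <- -log(1 - u * (1 - exp(-cfg$rfs_hazard_prg * 16))) /
    cfg$rfs_hazard_prg
  # memoryless: exponential conditioned on > 24 is 24 + exponential
  rfs[grg] <- 24 + stats::rexp(sum(grg), rate = cfg$rfs_hazard_grg)
  rfs[mid] <- stats::runif(sum(mid), 16, 24)
  event <- rep(1L, n)
  over <- rfs > ADMIN_CENSOR_MONTHS
  rfs[over] <- ADMIN_CENSOR_MONTHS
  event[over] <- 0L
  event[stats::runif(n) < cfg$censor_rate] <- 0L
  samples$rfs_months <- round(rfs, 2)
  samples$event <- event
  samples$tcp <- round(stats::runif(n, 30, 80))
  samples
}

# guarantee at least `k` PRG and GRG per cohort (and per LUAD subset of
# treated arms) so the differential comparisons the study runs are defined
ensure_min_groups <- function(samples, k = 3) {
  flip <- function(idx, to, n_needed) {
    from <- if (to == "PRG") c("GRG", "intermediate") else
      c("intermediate", "PRG")
    cand <- idx[samples$response_group[idx] %in% from &
                  !samples$prs_member[idx]]
    take <- utils::head(cand, n_needed)
    samples$response_group[take] <<- to
  }
  strata <- list()
  for (co in unique(samples$cohort)) {
    strata <- c(strata,
                list(which(samples$cohort == co & samples$treatment == "ACT")),
                list(which(samples$cohort == co & samples$treatment == "ACT" &
                             samples$subtype == "LUAD")))
  }
  if (any(samples$treatment == "UT"))
    strata <- c(strata, list(which(samples$treatment == "UT")))
  for (idx in strata) {
    if (length(idx) < 2 * k) next
    for (to in c("PRG", "GRG")) {
      have <- sum(samples$response_group[idx] == to)
      if (have < k) flip(idx, to, k - have)
    }
  }
  samples
}

draw_cohort_counts <- function(cfg, pi_base, stromal, subtype_block,
                               planted, ann) {
  n_p <- length(pi_base)
  n_s <- nrow(ann)
  protein_ids <- names(pi_base)
  lib <- round(stats::rlnorm(n_s, meanlog = log(1e5), sdlog = 0.25))

  prop <- matrix(pi_base, nrow = n_p, ncol = n_s,
                 dimnames = list(protein_ids, ann$sample_id))
  prg <- ann$response_group == "PRG"
  grg <- ann$response_group == "GRG"
  act <- ann$treatment == "ACT"
  for (ty in unique(planted$type)) {
    # predictive effects only manifest under treatment
    in_arm <- if (ty == "predictive") act else rep(TRUE, n_s)
    up_prg <- planted$protein_id[planted$direction == "PRG_up" &
                                   planted$type == ty]
    up_grg <- planted$protein_id[planted$direction == "GRG_up" &
                                   planted$type == ty]
    prop[up_prg, prg & in_arm] <- prop[up_prg, prg & in_arm] * cfg$planted_fc
    prop[up_grg, grg & in_arm] <- prop[up_grg, grg & in_arm] * cfg$planted_fc
  }
  prs <- ann$prs_member
  prop[stromal, prs] <- prop[stromal, prs] * PRS_STROMAL_SHIFT
  lusc <- ann$subtype == "LUSC"
  prop[subtype_block, lusc] <- prop[subtype_block, lusc] * SUBTYPE_SHIFT

  # beta-binomial draw: theta ~ Beta with mean prop and between-sample
  # squared CV equal to `dispersion` (so Var(theta) = dispersion * prop^2,
  # a biological CV shared across the abundance spectrum rather than a
  # shared intra-class correlation, which would swamp low-proportion
  # proteins); y ~ Binomial(library size, theta); dispersion = 0
  # degenerates to binomial
  nt <- matrix(rep(lib, each = n_p), nrow = n_p)
  if (cfg$dispersion > 0) {
    ab <- pmax((1 - prop) / (prop * cfg$dispersion) - 1, 2)
    theta <- matrix(stats::rbeta(n_p * n_s, prop * ab, (1 - prop) * ab),
                    nrow = n_p)
  } else {
    theta <- prop
  }
  y <- matrix(stats::rbinom(n_p * n_s, size = as.vector(nt),
                            prob = as.vector(theta)), nrow = n_p)
  dimnames(y) <- list(protein_ids, ann$sample_id)

  # zero inflation: dropout concentrates at low abundance (missingness at
  # the detection limit), decaying with the expected count; PR/S members
  # get extra dropout on non-stromal proteins with a slower decay, which
  # lowers their identified-protein counts
  mu <- prop * nt
  if (cfg$zero_inflation > 0) {
    p_drop <- cfg$zero_inflation * exp(-mu / 4)
    drop <- matrix(stats::runif(n_p * n_s) < p_drop, nrow = n_p)
    y[drop] <- 0L
    if (any(prs)) {
      non_stromal <- which(!protein_ids %in% stromal)
      sub <- y[non_stromal, prs, drop = FALSE]
      p2 <- PRS_EXTRA_DROPOUT * exp(-mu[non_stromal, prs, drop = FALSE] / 30)
      drop2 <- matrix(stats::runif(length(sub)) < p2, nrow = nrow(sub))
      sub[drop2] <- 0L
      y[non_stromal, prs] <- sub
    }
  }
  storage.mode(y) <- "integer"

  # intensity layer: counts times a protein-specific response factor with
  # multiplicative lognormal noise
  fct <- stats::rlnorm(n_p, meanlog = log(5e4), sdlog = 0.5)
  noise <- matrix(stats::rlnorm(n_p * n_s, 0, cfg$sc_intensity_noise),
                  nrow = n_p)
  intensity <- y * fct * noise
  dimnames(intensity) <- dimnames(y)

  list(counts = ptx_matrix(y, "raw_sc"),
       intensity = ptx_matrix(intensity, "intensity"))
}

draw_protein_meta <- function(protein_ids, pi_base) {
  n_p <- length(protein_ids)
  mw <- round(stats::rlnorm(n_p, meanlog = log(40), sdlog = 0.5), 1)
  # abundant proteins tend to be identified with more unique peptides;
  # the peptide/MW ratio then spans the rubric's 0.1 / 0.2 bins
  q <- rank(pi_base) / n_p
  rate <- 0.05 + 0.35 * q
  pep_d <- stats::rpois(n_p, lambda = mw * rate)
  pep_v <- stats::rpois(n_p, lambda = mw * rate)
  data.frame(protein_id = protein_ids, mw_kda = mw,
             peptides_discovery = pep_d, peptides_validation = pep_v,
             stringsAsFactors = FALSE)
}

#' Write a generated cohort bundle to disk
#'
#' Emits the TSV/JSON artifact set: `counts_<cohort>.tsv`,
#' `intensities_<cohort>.tsv`, `samples.tsv`, `proteins.tsv`, `truth.json`.
#'
#' @param cohorts a `ptx_cohorts` bundle from [generate_cohorts()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(cohorts, dir) {
  stopifnot(inherits(cohorts, "ptx_cohorts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in names(cohorts$counts)) {
    write_matrix_tsv(cohorts$counts[[co]],
                     file.path(dir, paste0("counts_", co, ".tsv")))
    write_matrix_tsv(cohorts$intensities[[co]],
                     file.path(dir, paste0("intensities_", co, ".tsv")))
  }
  write_samples_tsv(cohorts$samples, file.path(dir, "samples.tsv"))
  utils::write.table(cohorts$protein_meta, file.path(dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohorts$truth
  jsonlite::write_json(
    list(planted = truth$planted,
         prs_members = truth$prs_members,
         response_label = as.list(truth$response_label),
         stromal_proteins = truth$stromal_proteins,
         subtype_proteins = truth$subtype_proteins),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.ptx_cohorts <- function(x, ...) {
  cat(sprintf("<ptx_cohorts> %d proteins; discovery n=%d, validation n=%d\n",
              nrow(x$counts$discovery), ncol(x$counts$discovery),
              ncol(x$counts$validation)))
  cat(sprintf("  planted DE: %d at fc=%.2f; PR/S members: %d\n",
              nrow(x$truth$planted), x$config$planted_fc,
              length(x$truth$prs_members)))
  invisible(x)
}
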