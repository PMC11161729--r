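test_that("generation is deterministic and respects the shape contract", {
  cfg <- tiny_config(seed = 7)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$planted, b$truth$planted)

  cfg2 <- default_config(n_proteins = 200, seed = 3)
  ch <- generate_cohorts(cfg2)
  expect_equal(dim(ch$counts$discovery), c(200, 45))
  expect_equal(dim(ch$counts$validation), c(200, 22 + 10))
  expect_identical(dim(ch$intensities$discovery), dim(ch$counts$discovery))
  expect_true(is.integer(ch$counts$discovery))
})

test_that("default configuration mirrors the study cohort design", {
  cfg <- default_config()
  expect_equal(cfg$n_samples_discovery, 45)
  expect_equal(cfg$n_samples_validation_act, 22)
  expect_equal(cfg$n_samples_validation_ut, 10)
  expect_equal(cfg$prs_cluster_fraction, 0.26)
  ch <- generate_cohorts(tiny_config(seed = 2))
  ann <- ch$samples
  expect_true(all(ann$subtype[ann$treatment == "UT"] == "LUAD"))
  # generated labels agree with the RFS-threshold definition
  derived <- assign_response_groups(ann)
  expect_identical(unname(ch$truth$response_label[derived$sample_id]),
                   derived$response_group)
})

test_that("impossible configurations are rejected", {
  expect_error(default_config(n_planted_de = 600, n_proteins = 500),
               "n_planted_de")
  expect_error(default_config(planted_fc = 0.8), "planted_fc")
  expect_error(default_config(dispersion = 1.2), "dispersion")
  expect_error(default_config(prs_cluster_fraction = 1.4), "0, 1")
  expect_error(default_config(rfs_hazard_prg = 0), "hazards")
})

test_that("counts are overdispersed relative to binomial when dispersion > 0", {
  ch <- generate_cohorts(default_config(n_proteins = 250, zero_inflation = 0,
                                        prs_cluster_fraction = 0,
                                        dispersion = 0.1, seed = 11))
  y <- unclass(ch$counts$discovery)
  totals <- colSums(y)
  # compare per-protein empirical variance of proportions against the
  # binomial variance implied by the mean proportion
  p <- sweep(y, 2, totals, `/`)
  phat <- rowMeans(p)
  v_emp <- apply(p, 1, var)
  v_bin <- phat * (1 - phat) / mean(totals)
  keep <- phat > 1e-5
  expect_gt(sum(keep), 200)
  expect_gt(mean(v_emp[keep] > v_bin[keep]), 0.9)
})

test_that("PR/S members carry fewer identified proteins", {
  for (seed in 1:3) {
    ch <- generate_cohorts(tiny_config(seed = seed))
    nz <- colSums(ch$counts$discovery > 0)
    prs <- names(nz) %in% ch$truth$prs_members
    expect_lt(mean(nz[prs]), mean(nz[!prs]))
  }
})

test_that("planted fold-changes are recovered by preprocessing", {
  # planted group-mean ratios on normalized counts should sit near the
  # true fold-change; tolerance +/- 25% on the log scale
  errs <- c()
  for (seed in 1:3) {
    ch <- generate_cohorts(tiny_config(seed = seed, planted_fc = 2))
    norm <- normalize_counts(ch$counts$discovery)
    ann <- assign_response_groups(ch$samples)
    ann <- ann[ann$cohort == "discovery", ]
    prg <- ann$sample_id[ann$response_group == "PRG"]
    grg <- ann$sample_id[ann$response_group == "GRG"]
    gs <- group_stats(norm, NULL, prg, grg, pseudocount = 0.5)
    pl <- merge(gs, ch$truth$planted, by = "protein_id")
    pl <- pl[pl$type == "predictive", ]
    concordant <- (pl$direction == "PRG_up") == (pl$upregulated_group == "A")
    expect_gt(mean(concordant), 0.85)
    errs <- c(errs, abs(log(pl$fold_change) - log(2)) / log(2))
  }
  expect_lt(median(errs), 0.25)
})

test_that("planted group-mean ratio concentrates near the planted value", {
  # replicate generations at reduced size; the median recovered ratio of
  # planted proteins must fall in the stated band
  ratios <- c()
  for (seed in 1:20) {
    ch <- generate_cohorts(default_config(
      n_proteins = 60, n_planted_de = 6, n_samples_discovery = 45,
      n_samples_validation_act = 0, n_samples_validation_ut = 0,
      planted_fc = 2, dispersion = 0.05, seed = 100 + seed))
    norm <- normalize_counts(ch$counts$discovery)
    ann <- assign_response_groups(ch$samples)
    prg <- ann$sample_id[ann$response_group == "PRG"]
    grg <- ann$sample_id[ann$response_group == "GRG"]
    pl <- ch$truth$planted
    up <- pl$protein_id[pl$direction == "PRG_up" & pl$type == "predictive"]
    m1 <- rowMeans(norm[up, prg, drop = FALSE])
    m2 <- rowMeans(norm[up, grg, drop = FALSE])
    ratios <- c(ratios, (m1 + 0.5) / (m2 + 0.5))
  }
  expect_gt(median(ratios), 1.6)
  expect_lt(median(ratios), 2.5)
})

test_that("cohort bundles round-trip through the TSV/JSON writers", {
  dir <- withr::local_tempdir()
  ch <- generate_cohorts(tiny_config(seed = 5))
  write_cohorts(ch, dir)
  m <- read_matrix_tsv(file.path(dir, "counts_discovery.tsv"))
  expect_equal(unclass(m)[, ], unclass(ch$counts$discovery)[, ],
               ignore_attr = TRUE)
  ann <- read_samples_tsv(file.path(dir, "samples.tsv"))
  expect_equal(ann$sample_id, ch$samples$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$prs_members, ch$truth$prs_members)
})
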