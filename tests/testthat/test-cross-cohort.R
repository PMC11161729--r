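test_that("candidate intersection keeps concordant proteins only", {
  disc <- make_de_table(c("A", "B", "C"), c("PRG_up", "PRG_up", "GRG_up"),
                        c(0.01, 0.02, 0.03), c("T1", "T1", "T1"))
  val <- make_de_table(c("A", "C", "D"), c("PRG_up", "GRG_up", "PRG_up"),
                       c(0.02, 0.01, 0.04), c("T1", "T1", "T1"),
                       cohort = "validation")
  cand <- overlap_candidates(disc, val, "T1")
  expect_setequal(cand$protein_id, c("A", "C"))
  expect_equal(cand$direction[cand$protein_id == "A"], "PRG_up")
  expect_equal(cand$direction[cand$protein_id == "C"], "GRG_up")

  # discordant direction excluded and logged
  val2 <- make_de_table("A", "GRG_up", 0.01, "T1", cohort = "validation")
  cand2 <- overlap_candidates(disc, val2, "T1")
  expect_false("A" %in% cand2$protein_id)
  expect_identical(attr(cand2, "discordant"), "A")
})

test_that("tier thresholds nest: T3 candidates are T2 candidates are T1", {
  set.seed(6)
  ids <- sprintf("P%03d", 1:60)
  rand_table <- function(cohort) {
    tiers <- sample(c("none", "T1", "T2", "T3"), 60, replace = TRUE)
    make_de_table(ids, sample(c("PRG_up", "GRG_up"), 60, TRUE),
                  ifelse(tiers == "none", 0.5, 0.01), tiers,
                  cohort = cohort)
  }
  for (rep in 1:5) {
    d <- rand_table("discovery")
    v <- rand_table("validation")
    c1 <- overlap_candidates(d, v, "T1")$protein_id
    c2 <- overlap_candidates(d, v, "T2")$protein_id
    c3 <- overlap_candidates(d, v, "T3")$protein_id
    expect_true(all(c3 %in% c2))
    expect_true(all(c2 %in% c1))
  }
  expect_error(overlap_candidates(make_de_table("X", "PRG_up", 0.01, "T1"),
                                  make_de_table("Y", "PRG_up", 0.01, "T1")),
               "no proteins")
})

test_that("overlap significance equals the exact hypergeometric tail", {
  expect_equal(overlap_significance(5, 4, 4, 10), 5 / 210)
  expect_equal(overlap_significance(6, 9, 0, 20), 1)

  # exact enumeration oracle over small universes
  set.seed(7)
  for (i in 1:25) {
    universe <- sample(5:20, 1)
    n_disc <- sample(1:universe, 1)
    n_val <- sample(1:universe, 1)
    n_overlap <- sample(0:min(n_disc, n_val), 1)
    if (n_val - n_overlap > universe - n_disc) next
    expect_equal(overlap_significance(n_disc, n_val, n_overlap, universe),
                 oracle_hyper_tail(n_disc, n_val, n_overlap, universe),
                 tolerance = 1e-12)
  }
  # an overlap at its expected value is unremarkable
  p_mid <- overlap_significance(10, 8, 4, 20)
  expect_gt(p_mid, 0.3)
  expect_lt(p_mid, 0.9)
  expect_error(overlap_significance(5, 4, 5, 10), "inconsistent")
})

test_that("prognostic flagging requires concordant untreated significance", {
  cand <- data.frame(protein_id = c("A", "B", "C"),
                     direction = c("PRG_up", "GRG_up", "PRG_up"),
                     stringsAsFactors = FALSE)
  ut <- make_de_table(c("A", "B", "C"),
                      c("PRG_up", "PRG_up", "PRG_up"),
                      c(0.03, 0.03, 0.5),
                      c("T1", "T1", "none"), cohort = "untreated")
  out <- flag_prognostic(cand, ut)
  expect_true(out$prognostic_flag[out$protein_id == "A"])
  expect_false(out$prognostic_flag[out$protein_id == "B"])  # discordant
  expect_false(out$prognostic_flag[out$protein_id == "C"])  # not significant
})

test_that("untreated flagging separates prognostic from predictive effects", {
  prog_rates <- pred_rates <- c()
  for (seed in 1:3) {
    ch <- generate_cohorts(tiny_config(seed = 20 + seed))
    norm <- normalize_counts(ch$counts$validation)
    ut <- suppressMessages(
      run_differential(norm, ch$samples, "panNSCLC", "untreated"))
    pl <- ch$truth$planted
    sig <- ut$protein_id[ut$p_value < 0.05]
    prog <- pl$protein_id[pl$type == "prognostic"]
    pred <- pl$protein_id[pl$type == "predictive"]
    prog_rates <- c(prog_rates, prog %in% sig)
    pred_rates <- c(pred_rates, pred %in% sig)
  }
  expect_gt(mean(prog_rates), 0.5)
  expect_lt(mean(pred_rates), 0.2)
})

test_that("planted proteins are recovered as cross-cohort candidates", {
  # isolated planted-recovery experiment: no PR/S block, so candidate
  # lists reflect the planted effects alone
  rec <- unpl <- c()
  for (seed in 1:2) {
    ch <- generate_cohorts(default_config(n_proteins = 250,
                                          n_planted_de = 30,
                                          prs_cluster_fraction = 0,
                                          seed = 30 + seed))
    des <- lapply(c(discovery = "discovery", validation = "validation"),
                  function(co) {
      norm <- normalize_counts(ch$counts[[co]])
      suppressMessages(run_differential(norm, ch$samples, "panNSCLC", co))
    })
    cand <- overlap_candidates(des$discovery, des$validation, "T1")
    planted <- ch$truth$planted$protein_id
    rec <- c(rec, mean(planted %in% cand$protein_id))
    unpl <- c(unpl, mean(!cand$protein_id %in% planted))
  }
  expect_gt(mean(rec), 0.7)
  expect_lt(mean(unpl), 0.15)
})
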