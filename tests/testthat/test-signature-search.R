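test_that("LOOCV AUC behaves at the extremes", {
  toy <- make_toy_features(n_per_class = 8, n_proteins = 3,
                           n_informative = 1, shift = 8, seed = 1)
  auc <- loocv_auc(toy$X[, 1, drop = FALSE], toy$labels)
  expect_equal(auc, 1.0)

  # the ridge fit is sign-symmetric: relabelling negates every linear
  # score, so the refit AUC for the swapped positive class is unchanged
  flipped <- ifelse(toy$labels == "PRG", "GRG", "PRG")
  toy2 <- make_toy_features(n_per_class = 8, n_proteins = 3,
                            n_informative = 1, shift = 1, seed = 2)
  flipped2 <- ifelse(toy2$labels == "PRG", "GRG", "PRG")
  expect_equal(loocv_auc(toy$X[, 1, drop = FALSE], flipped), auc)
  expect_equal(loocv_auc(toy2$X, flipped2), loocv_auc(toy2$X, toy2$labels),
               tolerance = 1e-8)

  expect_error(loocv_auc(toy$X, rep("PRG", 16)), "two classes")
  expect_error(loocv_auc(toy$X[1:4, ], toy$labels[c(1, 2, 3, 9)]),
               "at least 3")
})

test_that("label-independent features never look informative", {
  # pooled LOOCV probabilities are pessimistic under the null (each
  # held-out sample pulls the training means away from itself), so null
  # AUCs centre at or below 0.5 and must not drift into apparent signal
  aucs <- vapply(1:10, function(seed) {
    toy <- make_toy_features(n_per_class = 20, n_proteins = 1,
                             n_informative = 0, seed = seed)
    loocv_auc(toy$X, toy$labels)
  }, numeric(1))
  expect_gte(median(aucs), 0.3)
  expect_lte(median(aucs), 0.7)
  expect_true(all(aucs < 0.8))
})

test_that("exhaustive search enumerates exactly choose(n, k) subsets", {
  toy <- make_toy_features(n_per_class = 6, n_proteins = 5, seed = 2)
  rep5 <- exhaustive_search(colnames(toy$X), k = 4, data = toy$X,
                            labels = toy$labels)
  expect_equal(rep5$n_evaluated, 5)
  expect_equal(nrow(rep5$ranked), choose(5, 4))

  for (np in c(6, 7)) {
    expect_equal(exhaustive_search(sprintf("p%d", 1:np), k = 3,
                                   count_only = TRUE)$n_evaluated,
                 choose(np, 3))
  }
  expect_error(exhaustive_search(c("a", "b"), k = 4, count_only = TRUE),
               "smaller than k")
})

test_that("exhaustive ranking matches an independent brute-force oracle", {
  toy <- make_toy_features(n_per_class = 7, n_proteins = 8,
                           n_informative = 2, shift = 1.5, seed = 3)
  rep8 <- exhaustive_search(colnames(toy$X), k = 4, data = toy$X,
                            labels = toy$labels)
  expect_equal(rep8$n_evaluated, 70)

  combos <- combn(sort(colnames(toy$X)), 4, simplify = FALSE)
  keys <- vapply(combos, paste, character(1), collapse = "+")
  aucs <- vapply(combos, function(ids)
    oracle_loocv_auc(toy$X[, ids, drop = FALSE], toy$labels), numeric(1))
  ord <- order(-aucs, keys)
  expect_equal(rep8$ranked$combo, keys[ord])
  expect_equal(rep8$ranked$auc, aucs[ord], tolerance = 1e-5)
})

test_that("pool order does not change the ranking", {
  toy <- make_toy_features(n_per_class = 6, n_proteins = 6,
                           n_informative = 1, seed = 4)
  pool <- colnames(toy$X)
  r1 <- exhaustive_search(pool, k = 3, data = toy$X, labels = toy$labels)
  r2 <- exhaustive_search(rev(pool), k = 3, data = toy$X,
                          labels = toy$labels)
  expect_identical(r1$ranked, r2$ranked)
})

test_that("random probing is seed-deterministic and saturates small pools", {
  toy <- make_toy_features(n_per_class = 6, n_proteins = 7,
                           n_informative = 2, seed = 5)
  pool <- colnames(toy$X)
  a <- random_probe(pool, k = 5, n_draws = 100, data = toy$X,
                    labels = toy$labels, seed = 42)
  b <- random_probe(pool, k = 5, n_draws = 100, data = toy$X,
                    labels = toy$labels, seed = 42)
  expect_identical(a$ranked, b$ranked)
  expect_equal(a$n_evaluated, 100)

  # enough draws cover all C(7,5) = 21 subsets: top combo equals the
  # exhaustive winner
  sat <- random_probe(pool, k = 5, n_draws = 600, data = toy$X,
                      labels = toy$labels, seed = 1)
  exh <- exhaustive_search(pool, k = 5, data = toy$X, labels = toy$labels)
  expect_equal(nrow(sat$ranked), choose(7, 5))
  expect_equal(sat$ranked$combo[1], exh$ranked$combo[1])

  # frequency table counts are bounded by k x F
  expect_lte(sum(a$frequency), 5 * min(100, nrow(a$ranked)))
})

test_that("stepwise construction finds informative proteins and stops", {
  found <- vapply(1:5, function(seed) {
    toy <- make_toy_features(n_per_class = 10, n_proteins = 10,
                             n_informative = 1, shift = 2.5, seed = seed)
    sig <- stepwise_signature(colnames(toy$X), toy$X, toy$labels)
    "P01" %in% sig$proteins
  }, logical(1))
  expect_gte(mean(found), 0.8)

  # an impossible improvement threshold stops at the start protein
  toy <- make_toy_features(n_per_class = 8, n_proteins = 6,
                           n_informative = 2, seed = 11)
  solo <- stepwise_signature(colnames(toy$X), toy$X, toy$labels,
                             epsilon = 1)
  expect_equal(solo$k, 1)

  # two complementary half-informative proteins are both selected
  set.seed(12)
  n <- 30
  labels <- rep(c("PRG", "GRG"), each = n / 2)
  z <- ifelse(labels == "PRG", 1.6, -1.6)
  X <- cbind(h1 = z + rnorm(n, sd = 1.6), h2 = z + rnorm(n, sd = 1.6),
             n1 = rnorm(n), n2 = rnorm(n))
  both <- stepwise_signature(colnames(X), X, labels)
  expect_true(all(c("h1", "h2") %in% both$proteins))

  # caller-chosen start protein is honoured
  st <- stepwise_signature(colnames(X), X, labels, start = "n1")
  expect_equal(st$proteins[1], "n1")
  expect_error(stepwise_signature(colnames(X), X, labels, start = "zz"),
               "not in pool")
})
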