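make_matrix <- function(values, layer = "raw_sc") {
  ptx_matrix(values, layer)
}

test_that("normalization scales every sample to the average total", {
  m <- make_matrix(matrix(c(5, 95, 30, 270), nrow = 2,
                          dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  norm <- normalize_counts(m)
  # totals 100 and 300 -> factors 2 and 2/3
  expect_equal(norm["p1", "s1"], 10)
  expect_equal(unname(colSums(norm)), c(200, 200))

  # equal totals: identity
  eq <- make_matrix(matrix(c(1, 9, 4, 6), nrow = 2,
                           dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  expect_equal(unclass(normalize_counts(eq))[, ], unclass(eq)[, ],
               ignore_attr = TRUE)

  # random matrix: all post-normalization column sums equal the
  # pre-normalization mean column sum
  set.seed(1)
  r <- make_matrix(matrix(rpois(500, 20), 50, 10,
                          dimnames = list(sprintf("p%02d", 1:50),
                                          sprintf("s%02d", 1:10))))
  rn <- normalize_counts(r)
  expect_true(all(abs(colSums(rn) - mean(colSums(r))) < 1e-9))
})

test_that("normalization is idempotent and commutes with protein order", {
  set.seed(2)
  r <- make_matrix(matrix(rpois(300, 15), 30, 10,
                          dimnames = list(sprintf("p%02d", 1:30),
                                          sprintf("s%02d", 1:10))))
  n1 <- normalize_counts(r)
  n2 <- normalize_counts(n1)
  expect_lt(max(abs(unclass(n2) - unclass(n1))), 1e-12)

  perm <- sample(nrow(r))
  np <- normalize_counts(subset_matrix <- ptx_matrix(unclass(r)[perm, ],
                                                     "raw_sc"))
  expect_equal(unclass(np)[rownames(r), ], unclass(n1)[, ],
               ignore_attr = TRUE)
})

test_that("zero-total samples are reported by name", {
  m <- make_matrix(matrix(c(1, 2, 0, 0), nrow = 2,
                          dimnames = list(c("p1", "p2"), c("ok", "empty"))))
  expect_error(normalize_counts(m), "empty")
})

test_that("presence filtering matches a brute-force oracle", {
  set.seed(3)
  vals <- matrix(rbinom(200 * 12, 1, 0.4) * rpois(200 * 12, 8), 200, 12,
                 dimnames = list(sprintf("p%03d", 1:200),
                                 sprintf("s%02d", 1:12)))
  m <- make_matrix(vals)
  groups <- list(g1 = sprintf("s%02d", 1:5), g2 = sprintf("s%02d", 6:12))

  out <- filter_proteins(m, 0.5, groups)
  oracle_keep <- vapply(rownames(m), function(p) {
    any(vapply(groups, function(g) mean(vals[p, g] > 0) >= 0.5, logical(1)))
  }, logical(1))
  expect_identical(rownames(out), rownames(m)[oracle_keep])
  expect_identical(attr(out, "removed"), rownames(m)[!oracle_keep])

  # min_presence 0 keeps everything
  all_kept <- filter_proteins(m, 0, groups)
  expect_identical(rownames(all_kept), rownames(m))

  # a protein present in 1/12 samples is removed at 0.3 with one group
  one <- make_matrix(matrix(c(rep(0, 11), 3), nrow = 1,
                            dimnames = list("lonely", sprintf("s%02d", 1:12))))
  expect_identical(nrow(filter_proteins(one, 0.3)), 0L)
})

test_that("group statistics follow their definitions", {
  vals <- rbind(a = c(0, 2, 3, 0, 1, 10, 12, 8, 11, 9),
                b = c(10, 10, 10, 10, 10, 5, 5, 5, 5, 5))
  colnames(vals) <- sprintf("s%02d", 1:10)
  m <- ptx_matrix(vals, "normalized_sc")
  g1 <- sprintf("s%02d", 1:5)
  g2 <- sprintf("s%02d", 6:10)
  gs <- group_stats(m, NULL, g1, g2, pseudocount = 0)
  expect_equal(gs$presence_a[gs$protein_id == "a"], 0.6)
  expect_equal(gs$fold_change[gs$protein_id == "b"], 2)
  expect_equal(gs$upregulated_group[gs$protein_id == "b"], "A")

  # intensities exactly proportional to counts -> r = 1
  intens <- ptx_matrix(vals * 1000, "intensity")
  gsi <- group_stats(m, intens, g1, g2)
  expect_equal(gsi$sc_intensity_r, c(1, 1))

  # constant count vector -> correlation undefined
  cvals <- rbind(const = rep(4, 10))
  colnames(cvals) <- colnames(vals)
  gsc <- group_stats(ptx_matrix(cvals, "normalized_sc"),
                     ptx_matrix(cvals * runif(10), "intensity"), g1, g2)
  expect_true(is.na(gsc$sc_intensity_r))
})

test_that("group statistics are symmetric under group swap", {
  set.seed(4)
  vals <- matrix(rpois(40 * 10, 12), 40, 10,
                 dimnames = list(sprintf("p%02d", 1:40),
                                 sprintf("s%02d", 1:10)))
  m <- ptx_matrix(vals, "normalized_sc")
  g1 <- sprintf("s%02d", 1:4)
  g2 <- sprintf("s%02d", 5:10)
  ab <- group_stats(m, NULL, g1, g2)
  ba <- group_stats(m, NULL, g2, g1)
  # fold-change magnitude is invariant; the upregulated side flips except
  # at exact ties, which resolve to the first group by convention
  expect_equal(ab$fold_change, ba$fold_change)
  ties <- ab$mean_a == ab$mean_b
  expect_true(all((ab$upregulated_group != ba$upregulated_group)[!ties]))

  expect_error(group_stats(m, NULL, g1, c(g2, "nope")), "unknown sample")
  expect_error(group_stats(m, NULL, g1, g1), "disjoint")
})
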