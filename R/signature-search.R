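# Combinatorial search for small multi-protein classifiers: exhaustive
# k-subset enumeration, random probing, and forward stepwise construction,
# all scored by the AUC of pooled leave-one-out held-out probabilities of a
# ridge-stabilized logistic model. The small L2 penalty guarantees
# convergence under the perfect separation that routinely occurs for
# 4-protein subsets at n ~ 60.

RIDGE_LAMBDA <- 1e-3

# ridge-penalized logistic regression by iteratively reweighted least
# squares; X must already be standardized, intercept unpenalized
fit_ridge_logistic <- function(X, y, lambda = RIDGE_LAMBDA,
                               maxit = 50, tol = 1e-8) {
  Xa <- cbind(1, X)
  p <- ncol(Xa)
  pen <- diag(c(0, rep(lambda, p - 1)), nrow = p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xa, Xa * w) + pen
    beta_new <- drop(solve(H, crossprod(Xa, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# rank-based AUC of scores for the positive class
auc_from_scores <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC undefined for single-class data")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# normalize labels to logical "is positive class" (PRG by convention)
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- unique(as.character(labels))
  if (length(u) != 2) stop("labels must contain exactly two classes")
  pos <- if ("PRG" %in% u) "PRG" else sort(u)[2]
  as.character(labels) == pos
}

#' Leave-one-out cross-validated AUC of a ridge-logistic classifier
#'
#' For each sample, a ridge-stabilized logistic model is fitted on the
#' remaining samples (features standardized inside the training fold) and
#' the held-out predicted probability recorded; the AUC is computed once on
#' the pooled held-out predictions. Exactly n model fits are performed.
#'
#' @param features numeric matrix, samples in rows, proteins in columns.
#' @param labels two-class labels; class `"PRG"` (if present) is treated as
#'   positive.
#' @param lambda L2 penalty on standardized coefficients.
#' @return AUC in [0, 1].
#' @export
loocv_auc <- function(features, labels, lambda = RIDGE_LAMBDA) {
  features <- as.matrix(features)
  pos <- as_positive(labels)
  n <- nrow(features)
  stopifnot(length(pos) == n)
  if (sum(pos) < 3 || sum(!pos) < 3)
    stop("at least 3 samples per class are required")
  y <- as.numeric(pos)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- features[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    beta <- fit_ridge_logistic(Xs, y[-i], lambda = lambda)
    xi <- (features[i, ] - mu) / sdv
    probs[i] <- stats::plogis(beta[1] + sum(beta[-1] * xi))
  }
  auc_from_scores(probs, pos)
}

combo_key <- function(ids) paste(sort(ids), collapse = "+")

rank_combos <- function(keys, aucs) {
  # descending AUC, ties resolved lexicographically on the sorted-id key
  ord <- order(-aucs, keys)
  data.frame(rank = seq_along(ord), combo = keys[ord], auc = aucs[ord],
             stringsAsFactors = FALSE)
}

combo_report <- function(ranked, k, n_evaluated, top_f, top_n = 30) {
  topf <- utils::head(ranked, top_f)
  freq <- sort(table(unlist(strsplit(topf$combo, "+", fixed = TRUE))),
               decreasing = TRUE)
  topn <- utils::head(ranked, top_n)
  prot <- strsplit(topn$combo, "+", fixed = TRUE)
  best_rank <- tapply(rep(topn$rank, lengths(prot)), unlist(prot), min)
  top30 <- data.frame(protein_id = names(best_rank),
                      best_rank = as.integer(best_rank),
                      stringsAsFactors = FALSE)
  top30 <- top30[order(top30$best_rank, top30$protein_id), ]
  rownames(top30) <- NULL
  out <- list(ranked = ranked, k = k, n_evaluated = n_evaluated,
              top_f = top_f, frequency = freq, top30 = top30)
  class(out) <- "ptx_search_report"
  out
}

#' @export
print.ptx_search_report <- function(x, ...) {
  cat(sprintf("<ptx_search_report> k=%d, %d evaluations", x$k, x$n_evaluated))
  if (!is.null(x$ranked) && nrow(x$ranked))
    cat(sprintf(", best AUC %.3f (%s)", x$ranked$auc[1], x$ranked$combo[1]))
  cat("\n")
  invisible(x)
}

#' Exhaustive search over all k-protein combinations
#'
#' Evaluates every k-subset of the pool exactly once (choose(|pool|, k)
#' evaluations) by LOOCV AUC, ranks them with a deterministic
#' lexicographic tie-break, and tabulates protein frequencies over the top
#' `top_f` combinations.
#'
#' @param pool character vector of candidate protein ids.
#' @param k subset size.
#' @param data numeric matrix, samples in rows, proteins in columns
#'   (superset of `pool`); ignored when `count_only = TRUE`.
#' @param labels two-class labels aligned with rows of `data`.
#' @param top_f number of top combinations used for frequency counting.
#' @param count_only if `TRUE`, only the evaluation count is computed
#'   (no model fitting); used to verify combinatorial scale.
#' @return a `ptx_search_report` with elements `ranked`, `n_evaluated`,
#'   `frequency`, `top30`.
#' @export
exhaustive_search <- function(pool, k = 4, data = NULL, labels = NULL,
                              top_f = 100, count_only = FALSE) {
  pool <- as.character(pool)
  if (length(pool) < k) stop("pool smaller than k")
  n_eval <- choose(length(pool), k)
  if (count_only) {
    out <- list(ranked = NULL, k = k, n_evaluated = n_eval, top_f = top_f,
                frequency = NULL, top30 = NULL)
    class(out) <- "ptx_search_report"
    return(out)
  }
  combos <- utils::combn(sort(pool), k, simplify = FALSE)
  keys <- vapply(combos, combo_key, character(1))
  aucs <- vapply(combos, function(ids) {
    loocv_auc(data[, ids, drop = FALSE], labels)
  }, numeric(1))
  combo_report(rank_combos(keys, aucs), k, length(combos), top_f)
}

#' Random probing of k-protein combinations
#'
#' Draws `n_draws` k-subsets uniformly at random (without replacement
#' within a draw; duplicate draws across iterations are allowed and
#' deduplicated in the report) and scores each distinct subset by LOOCV
#' AUC. Deterministic under `seed`.
#'
#' @inheritParams exhaustive_search
#' @param n_draws number of random draws.
#' @param seed RNG seed.
#' @return a `ptx_search_report`; `n_evaluated` is the number of draws,
#'   the ranking covers the distinct subsets drawn.
#' @export
random_probe <- function(pool, k = 5, n_draws = 500000, data = NULL,
                         labels = NULL, seed = 1L, top_f = 100) {
  pool <- as.character(pool)
  if (length(pool) < k) stop("pool smaller than k")
  keys <- with_seed(seed, {
    vapply(seq_len(n_draws),
           function(i) combo_key(sample(pool, k)), character(1))
  })
  uniq <- sort(unique(keys))
  aucs <- vapply(strsplit(uniq, "+", fixed = TRUE), function(ids) {
    loocv_auc(data[, ids, drop = FALSE], labels)
  }, numeric(1))
  combo_report(rank_combos(uniq, aucs), k, n_draws, top_f)
}

#' Forward stepwise signature construction
#'
#' Starts from a seed protein (the one with the highest single-protein
#' LOOCV AUC, or a caller-supplied id such as the most robust marker) and
#' greedily adds the protein that maximally increases the LOOCV AUC,
#' stopping when no addition improves the AUC by more than `epsilon` or
#' when `max_k` proteins are reached.
#'
#' @inheritParams exhaustive_search
#' @param start `"highest_auc"` or a protein id in `pool`.
#' @param epsilon minimum AUC improvement to accept an addition.
#' @param max_k maximum signature size.
#' @return a `ptx_signature_model`: `proteins`, `coefficients` (ridge fit
#'   on the full standardized data, intercept first), `loocv_auc`, `k`,
#'   and the addition `trace`.
#' @export
stepwise_signature <- function(pool, data, labels, start = "highest_auc",
                               epsilon = 0.005, max_k = 6) {
  pool <- as.character(pool)
  if (length(pool) == 0) stop("pool must be non-empty")
  single <- vapply(pool, function(p) {
    loocv_auc(data[, p, drop = FALSE], labels)
  }, numeric(1))
  if (identical(start, "highest_auc")) {
    start_protein <- pool[order(-single, pool)][1]
  } else {
    if (!start %in% pool) stop("start protein not in pool: ", start)
    start_protein <- start
  }
  current <- start_protein
  current_auc <- single[[start_protein]]
  trace <- data.frame(step = 1L, added = start_protein, auc = current_auc,
                      stringsAsFactors = FALSE)
  while (length(current) < max_k) {
    remaining <- setdiff(pool, current)
    if (length(remaining) == 0) break
    cand_auc <- vapply(remaining, function(p) {
      loocv_auc(data[, c(current, p), drop = FALSE], labels)
    }, numeric(1))
    best <- remaining[order(-cand_auc, remaining)][1]
    if (cand_auc[[best]] - current_auc <= epsilon) break
    current <- c(current, best)
    current_auc <- cand_auc[[best]]
    trace <- rbind(trace, data.frame(step = length(current), added = best,
                                     auc = current_auc,
                                     stringsAsFactors = FALSE))
  }
  X <- data[, current, drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  beta <- fit_ridge_logistic(Xs, as.numeric(as_positive(labels)))
  out <- list(proteins = current,
              coefficients = stats::setNames(beta, c("(Intercept)", current)),
              center = mu, scale = sdv,
              loocv_auc = current_auc, k = length(current), trace = trace,
              start = start_protein)
  class(out) <- "ptx_signature_model"
  out
}

#' @export
print.ptx_signature_model <- function(x, ...) {
  cat(sprintf("<ptx_signature_model> %d proteins (%s), LOOCV AUC %.3f\n",
              x$k, paste(x$proteins, collapse = ", "), x$loocv_auc))
  invisible(x)
}

#' Assemble a full signature report for scoring
#'
#' Bundles the exhaustive 4-protein report, the random 5-protein report,
#' and the stepwise signatures into the structure consumed by
#' [signature_score()].
#'
#' @param report4,report5 `ptx_search_report` objects for k = 4 and k = 5
#'   (either may be `NULL`).
#' @param stepwise list of `ptx_signature_model` objects.
#' @return a `ptx_signature_report`.
#' @export
signature_report <- function(report4 = NULL, report5 = NULL,
                             stepwise = list()) {
  out <- list(top30 = list(`4` = if (!is.null(report4)) report4$top30,
                           `5` = if (!is.null(report5)) report5$top30),
              stepwise = stepwise)
  class(out) <- "ptx_signature_report"
  out
}
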