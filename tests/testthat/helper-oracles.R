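# Independent oracles and shared fixtures. Every oracle here re-derives
# the quantity it checks by a different route than the implementation
# (grid search, exact enumeration, hand product-limit arithmetic,
# optim-based penalized likelihood).

# small, fast synthetic configuration for module-level tests
tiny_config <- function(...) {
  default_config(n_proteins = 150, n_samples_discovery = 30,
                 n_samples_validation_act = 16, n_samples_validation_ut = 8,
                 n_planted_de = 20, ...)
}

# ---- beta-binomial grid-search likelihood oracle -------------------------

oracle_bb_loglik <- function(y, n, pi, phi) {
  ab <- 1 / phi - 1
  a <- pi * ab
  b <- (1 - pi) * ab
  sum(lbeta(y + a, n - y + b) - lbeta(a, b))
}

# maximize over a dense grid of (pi_a, pi_b, phi); returns the LRT
# statistic computed purely by enumeration
oracle_bb_lrt <- function(ya, na, yb, nb, n_pi = 120, n_phi = 60) {
  p_all <- (sum(ya) + sum(yb)) / (sum(na) + sum(nb))
  pis <- exp(seq(log(p_all / 30), log(min(p_all * 30, 0.5)),
                 length.out = n_pi))
  phis <- exp(seq(log(1e-6), log(0.9), length.out = n_phi))
  best_null <- -Inf
  best_alt <- -Inf
  for (phi in phis) {
    lla <- vapply(pis, function(p) oracle_bb_loglik(ya, na, p, phi),
                  numeric(1))
    llb <- vapply(pis, function(p) oracle_bb_loglik(yb, nb, p, phi),
                  numeric(1))
    best_null <- max(best_null, max(lla + llb))  # same pi index for both
    best_alt <- max(best_alt, max(lla) + max(llb))
  }
  2 * (best_alt - best_null)
}

# ---- exact hypergeometric tail by enumeration ----------------------------

oracle_hyper_tail <- function(n_disc, n_val, n_overlap, universe) {
  ks <- n_overlap:min(n_disc, n_val)
  sum(choose(n_disc, ks) * choose(universe - n_disc, n_val - ks)) /
    choose(universe, n_val)
}

# ---- hand product-limit estimator ----------------------------------------

oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# ---- independent LOOCV ridge-logistic scorer -----------------------------

# fits the penalized logistic likelihood with optim (BFGS on the analytic
# objective), standardizing inside each training fold, and pools held-out
# probabilities into a rank AUC; shares no code with the package path
oracle_loocv_auc <- function(X, labels, lambda = 1e-3) {
  pos <- labels == "PRG"
  y <- as.numeric(pos)
  n <- nrow(X)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    obj <- function(b) {
      eta <- b[1] + drop(Xs %*% b[-1])
      -sum(y[-i] * eta - log1p(exp(eta))) + lambda / 2 * sum(b[-1]^2)
    }
    fit <- optim(rep(0, ncol(X) + 1), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    xi <- (X[i, ] - mu) / sdv
    probs[i] <- plogis(fit$par[1] + sum(fit$par[-1] * xi))
  }
  r <- rank(probs)
  n1 <- sum(pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
}

# toy two-class feature matrix with a controllable number of informative
# proteins
make_toy_features <- function(n_per_class = 10, n_proteins = 8,
                              n_informative = 2, shift = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_proteins), n, n_proteins,
              dimnames = list(NULL, sprintf("P%02d", seq_len(n_proteins))))
  labels <- rep(c("PRG", "GRG"), each = n_per_class)
  if (n_informative > 0)
    X[labels == "PRG", seq_len(n_informative)] <-
      X[labels == "PRG", seq_len(n_informative)] + shift
  list(X = X, labels = labels)
}

# small DE-result table builder for cross-cohort tests
make_de_table <- function(protein_id, direction, p_value, tier,
                          comparison = "panNSCLC", cohort = "discovery") {
  data.frame(protein_id = protein_id, comparison = comparison,
             cohort = cohort, p_value = p_value,
             fold_change = 2, direction = direction,
             presence_up = 0.8, mean_up = 20, tier = tier,
             stringsAsFactors = FALSE)
}
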