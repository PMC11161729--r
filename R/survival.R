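# Response-group assignment from recurrence-free survival, Kaplan-Meier
# estimation, log-rank comparison, and abundance-quantile splits.
# Estimation itself is delegated to the survival package (survfit /
# survdiff); the functions here define the study-specific contracts.

#' Assign response groups from recurrence-free survival
#'
#' Poor response/survival group (PRG): RFS of at most 16 months; good
#' response/survival group (GRG): RFS beyond 24 months; everything in
#' between is `"intermediate"` (excluded from differential comparisons but
#' retained elsewhere).
#'
#' @param annotation sample annotation data.frame with `rfs_months`.
#' @return `annotation` with a `response_group` column.
#' @export
assign_response_groups <- function(annotation) {
  rfs <- annotation$rfs_months
  if (any(is.na(rfs))) stop("missing RFS values")
  if (any(rfs < 0)) stop("negative RFS values")
  annotation$response_group <- ifelse(rfs <= 16, "PRG",
                                      ifelse(rfs > 24, "GRG", "intermediate"))
  annotation
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times event/censoring times (months), non-negative.
#' @param events event indicators (1 = recurrence or death observed,
#'   0 = censored).
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `survival` (non-increasing, starting below 1 only after the first
#'   event).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom and a two-sided
#' p-value. If no events are observed in either group the comparison is
#' degenerate and p = 1 is returned with a message.
#'
#' @param times_a,events_a times and event indicators for group A.
#' @param times_b,events_b times and event indicators for group B.
#' @return list with `chisq`, `p_value`, and per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) {
    message("no events in either group; degenerate log-rank p = 1")
    return(list(chisq = 0, p_value = 1,
                observed = c(0, 0), expected = c(NA_real_, NA_real_)))
  }
  grp <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))))
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Split samples on a protein's abundance quantile
#'
#' Samples with normalized abundance strictly above the `q`-th sample
#' quantile (linear-interpolation definition) form the high group; ties at
#' the quantile fall to the low group. With q = 0.75 this reproduces a
#' top-quartile vs lower-three-quartiles split.
#'
#' @param norm normalized-count `ptx_matrix`.
#' @param protein protein id (must be a row of `norm`).
#' @param quantile quantile in [0, 1); default 0.75.
#' @return list with character vectors `high` and `low` of sample ids, and
#'   the `cutoff` used.
#' @export
abundance_split <- function(norm, protein, quantile = 0.75) {
  if (!protein %in% rownames(norm)) stop("protein not present: ", protein)
  v <- norm[protein, ]
  if (stats::sd(v) == 0) stop("constant abundance; no split possible")
  cut <- stats::quantile(v, quantile, names = FALSE)
  list(high = colnames(norm)[v > cut],
       low = colnames(norm)[v <= cut],
       cutoff = cut)
}
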