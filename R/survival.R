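# Kaplan-Meier estimation, k-group log-rank testing and per-gene Cox hazard
# ratios, as thin validated wrappers over the survival package (survfit,
# survdiff, coxph with Efron ties).

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times (years).
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return List: `curve` (data frame: time, n_risk, n_event, surv — one row
#'   per distinct observed time) and `median` (smallest time with
#'   `S(t) <= 0.5`; `NA` when never reached).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv),
       median = if (is.na(med)) NA_real_ else med)
}

#' Multi-group log-rank test
#'
#' Standard k-group log-rank: observed versus expected events per group
#' summed over distinct event times, chi-square with k - 1 degrees of
#' freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group label per observation (>= 2 distinct groups and at
#'   least one event overall).
#' @return List: chi2, df, p.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("log-rank needs >= 2 groups")
  if (sum(events) < 1) stop("log-rank needs >= 1 observed event")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  list(chi2 = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model for one gene
#'
#' Expression is standardized to unit variance before fitting, so the hazard
#' ratio is per SD of expression; HR > 1 means high expression associates
#' with earlier death. Ties are handled by the Efron approximation.
#'
#' @param expr Numeric expression vector (one value per sample).
#' @param times,events As in [km_estimate()]; requires >= 10 samples and
#'   >= 3 events.
#' @return List: hr, beta, se, wald_p, n, n_events.
#' @export
cox_hr <- function(expr, times, events) {
  if (length(expr) != length(times)) stop("expression/survival length mismatch")
  if (length(expr) < 10) stop("Cox fit needs >= 10 samples")
  if (sum(events) < 3) stop("Cox fit needs >= 3 events")
  s <- stats::sd(expr)
  if (s == 0) stop("zero-variance expression vector")
  z <- (expr - mean(expr)) / s
  fit <- survival::coxph(survival::Surv(times, events) ~ z,
                         ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox fit did not converge in 50 iterations")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  list(hr = exp(beta), beta = beta, se = se,
       wald_p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
       n = fit$n, n_events = fit$nevent)
}

#' Per-gene Cox hazard ratios over an expression matrix
#'
#' @param m An `ExpressionMatrix`.
#' @param clinical A `ClinicalTable` covering the matrix samples.
#' @param genes_use Genes to fit (default all non-constant genes).
#' @return Data frame: gene, hr, beta, se, wald_p.
#' @export
cox_hr_table <- function(m, clinical, genes_use = NULL) {
  idx <- match(samples(m), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table is missing matrix samples")
  if (is.null(genes_use))
    genes_use <- genes(m)[apply(m$values, 1, stats::sd) > 0]
  rows <- lapply(genes_use, function(g) {
    fit <- cox_hr(m$values[g, ], clinical$survival_time[idx],
                  clinical$event[idx])
    data.frame(gene = g, hr = fit$hr, beta = fit$beta, se = fit$se,
               wald_p = fit$wald_p)
  })
  do.call(rbind, rows)
}
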