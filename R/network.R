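# Subtype-specific TF->target regulatory networks: for each target, its
# library regulators enter a bidirectional AIC stepwise linear regression on
# standardized expression within the subtype's samples; the fitted
# standardized coefficients are the regulation efficacies (sign = activation
# vs repression, magnitude = strength).

#' Stepwise regression of one target on its candidate TFs
#'
#' Variables are standardized, selection starts from the empty model and
#' adds/drops terms by an information criterion (`stats::step`) until no
#' move improves. The default criterion is BIC (`penalty = log(n)`): it is
#' threshold-free and deterministic like AIC, but conservative enough that
#' spurious regulators are rarely retained under the null, keeping edge
#' precision high; set `penalty = 2` for classic AIC. Candidates are
#' processed in lexicographic order, which makes ties deterministic.
#'
#' @param target Target gene id.
#' @param candidates Character vector of candidate regulator ids (the
#'   library regulators of the target; the target itself is excluded).
#' @param m `ExpressionMatrix` restricted to one subtype's samples (>= 10).
#' @param penalty Per-parameter information-criterion penalty passed to
#'   `stats::step`'s `k`; default `log(n)` (BIC).
#' @return List: target, edges (data frame regulator/efficacy for retained
#'   TFs; zero rows when the empty model wins), r2, aic, aic_null, n.
#' @export
stepwise_regress <- function(target, candidates, m, penalty = NULL) {
  if (ncol(m$values) < 10) stop("need >= 10 samples to fit")
  candidates <- sort(setdiff(unique(candidates), target))
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  y <- zscore(m$values[target, ])
  n <- length(y)
  if (is.null(penalty)) penalty <- log(n)
  if (length(candidates) == 0) {
    null_fit <- stats::lm(y ~ 1)
    return(list(target = target,
                edges = data.frame(regulator = character(0),
                                   efficacy = numeric(0)),
                r2 = 0, aic = stats::AIC(null_fit),
                aic_null = stats::AIC(null_fit), n = n))
  }
  # safe internal names; mapped back on output
  vn <- sprintf("X%03d", seq_along(candidates))
  df <- as.data.frame(lapply(candidates, function(g) zscore(m$values[g, ])))
  colnames(df) <- vn
  df$y <- y
  null_fit <- stats::lm(y ~ 1, data = df)
  scope <- stats::reformulate(vn)
  sel <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                     direction = "both", trace = 0, k = penalty)
  co <- stats::coef(sel)
  co <- co[setdiff(names(co), "(Intercept)")]
  edges <- data.frame(
    regulator = candidates[match(names(co), vn)],
    efficacy = unname(co))
  edges <- edges[order(edges$regulator), , drop = FALSE]
  rownames(edges) <- NULL
  list(target = target, edges = edges,
       r2 = summary(sel)$r.squared, aic = stats::AIC(sel),
       aic_null = stats::AIC(null_fit), n = n)
}

#' Fit a subtype-specific regulatory network
#'
#' Runs [stepwise_regress()] for every library target present in the matrix,
#' within one group's samples. Groups with fewer than `min_samples` samples
#' are refused.
#'
#' @param m `ExpressionMatrix` restricted to the group's samples.
#' @param library A `RegulatoryLibrary`.
#' @param label Group label stored on the network (e.g. subtype id or
#'   `"normal"`).
#' @param targets_use Optional subset of targets to model (default: all
#'   library targets in `m`).
#' @param min_samples Minimum samples to fit (default 10).
#' @param penalty Passed to [stepwise_regress()].
#' @return List of class `RegulatoryNetwork`: label, edges (data frame:
#'   regulator, target, efficacy, present — one row per library edge with
#'   both endpoints in `m`; absent edges carry efficacy 0), fits (per-target
#'   r2/aic/n), library_key (edge keys, for compatibility checks).
#' @export
fit_network <- function(m, library, label, targets_use = NULL,
                        min_samples = 10, penalty = NULL) {
  if (ncol(m$values) < min_samples)
    stop(sprintf("group '%s' has %d samples, below the minimum of %d",
                 label, ncol(m$values), min_samples))
  ed <- library$edges
  ed <- ed[ed$regulator %in% genes(m) & ed$target %in% genes(m), , drop = FALSE]
  if (is.null(targets_use)) targets_use <- unique(ed$target)
  targets_use <- intersect(targets_use, unique(ed$target))
  eff <- stats::setNames(rep(0, nrow(ed)),
                         paste(ed$regulator, ed$target, sep = "->"))
  present <- stats::setNames(rep(FALSE, nrow(ed)), names(eff))
  fits <- list()
  for (tg in sort(targets_use)) {
    cand <- ed$regulator[ed$target == tg]
    fit <- stepwise_regress(tg, cand, m, penalty = penalty)
    fits[[tg]] <- data.frame(target = tg, r2 = fit$r2, aic = fit$aic,
                             aic_null = fit$aic_null, n = fit$n)
    if (nrow(fit$edges) > 0) {
      keys <- paste(fit$edges$regulator, tg, sep = "->")
      eff[keys] <- fit$edges$efficacy
      present[keys] <- TRUE
    }
  }
  structure(list(label = label,
                 edges = data.frame(regulator = ed$regulator,
                                    target = ed$target,
                                    efficacy = unname(eff),
                                    present = unname(present),
                                    row.names = NULL),
                 fits = if (length(fits) > 0)
                   do.call(rbind, c(unname(fits),
                                    list(make.row.names = FALSE)))
                 else NULL,
                 library_key = sort(names(eff))),
            class = "RegulatoryNetwork")
}

#' Compare two regulatory networks edge by edge
#'
#' For every library edge, reports both efficacies and a status:
#' `absent-both`, `gained` (absent in `net_a`, present in `net_b`), `lost`
#' (the reverse), `sign-flipped` (present in both with opposite signs) or
#' `stable` (present in both, signs agree).
#'
#' @param net_a,net_b `RegulatoryNetwork`s fitted on the same library.
#' @return Data frame: regulator, target, efficacy_a, efficacy_b, status.
#' @export
differential_network <- function(net_a, net_b) {
  if (!identical(net_a$library_key, net_b$library_key))
    stop("networks were fitted on different libraries")
  ea <- net_a$edges
  eb <- net_b$edges[match(paste(ea$regulator, ea$target),
                          paste(net_b$edges$regulator, net_b$edges$target)), ]
  status <- ifelse(!ea$present & !eb$present, "absent-both",
            ifelse(!ea$present & eb$present, "gained",
            ifelse(ea$present & !eb$present, "lost",
            ifelse(sign(ea$efficacy) != sign(eb$efficacy),
                   "sign-flipped", "stable"))))
  data.frame(regulator = ea$regulator, target = ea$target,
             efficacy_a = ea$efficacy, efficacy_b = eb$efficacy,
             status = status, row.names = NULL)
}
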