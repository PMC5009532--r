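# Per-gene two-condition differential expression: Welch two-sample t-test on
# log-scale values with Benjamini-Hochberg correction. The downstream
# pipeline consumes only the DEG flag.

#' Per-gene differential expression between two conditions
#'
#' Welch (unequal-variance) t-test per gene; effect is
#' `mean(second condition) - mean(first condition)` (tumor minus normal under
#' the default label ordering). Genes with zero variance in both groups
#' cannot carry evidence of change and get `p = 1` by convention.
#'
#' @param m Two-condition `ExpressionMatrix` (each condition >= 2 samples).
#' @param conditions Length-2 character vector `c(reference, test)`; default
#'   sorted unique labels, so `c("normal", "tumor")` gives tumor - normal
#'   effects.
#' @param alpha BH q-value cutoff for the DEG flag (default 0.05).
#' @return Data frame: gene, effect, t, df, p, q, is_deg.
#' @export
differential_expression <- function(m, conditions = NULL, alpha = 0.05) {
  if (is.null(conditions)) conditions <- sort(unique(m$condition))
  if (length(conditions) != 2) stop("exactly two conditions required")
  a <- m$condition == conditions[1]
  b <- m$condition == conditions[2]
  n1 <- sum(a); n2 <- sum(b)
  if (n1 < 2 || n2 < 2) stop("each condition needs >= 2 samples")
  x1 <- m$values[, a, drop = FALSE]
  x2 <- m$values[, b, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- v1 == 0 & v2 == 0
  tt[degenerate] <- 0
  df[degenerate] <- NA_real_
  p[degenerate] <- 1
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes(m), effect = m2 - m1, t = tt, df = df,
             p = p, q = q, is_deg = q < alpha, row.names = NULL)
}
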