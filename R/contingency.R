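#' Build a validated contingency table
#'
#' Constructs an R x C table of non-negative integer counts with outcome
#' groups in rows and exposure levels in columns, as used for the
#' genetic-model and methylation-category cross-tabulations.
#'
#' @param counts Numeric matrix of non-negative counts, at least 2 x 2.
#' @param row_labels,col_labels Optional character labels; default to the
#'   dimnames of `counts`.
#' @return An object of class `contingency_table`: the integer count matrix
#'   with labels attached.
#' @examples
#' contingency_table(rbind(responder = c(50, 97), non_responder = c(20, 73)))
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("a contingency table needs at least 2 rows and 2 columns")
  counts <- round(counts)
  if (sum(counts) == 0) stop("grand total is zero")
  if (is.null(row_labels)) row_labels <- paste0("row", seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- paste0("col", seq_len(ncol(counts)))
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", "matrix"))
}

#' Pearson chi-squared test on a contingency table
#'
#' Classical Pearson chi-squared test of independence with *no* continuity
#' correction, so that 2 x 2 genetic-model tables reproduce the uncorrected
#' statistics used throughout the association analysis.
#'
#' @param table A `contingency_table` or a plain count matrix.
#' @return A list of class `chi2_result` with elements `statistic`, `df`,
#'   `p`, and the matrix of `expected` counts.
#' @details The statistic is \eqn{\sum (O - E)^2 / E} with
#'   \eqn{E = (\mathrm{row\ total} \times \mathrm{col\ total}) / N} and
#'   \eqn{df = (R-1)(C-1)}. A zero row or column margin makes the expected
#'   counts degenerate and is an error naming the margin.
#' @examples
#' pearson_chi2(rbind(c(50, 63, 34), c(20, 49, 24)))
#' @export
pearson_chi2 <- function(table) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0))
    stop("degenerate margin: row(s) ", paste(rownames(table)[rs == 0], collapse = ", "),
         " have zero total")
  if (any(cs == 0))
    stop("degenerate margin: column(s) ", paste(colnames(table)[cs == 0], collapse = ", "),
         " have zero total")
  n <- sum(table)
  expected <- outer(rs, cs) / n
  statistic <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(
    list(statistic = statistic, df = df,
         p = stats::pchisq(statistic, df, lower.tail = FALSE),
         expected = expected),
    class = "chi2_result"
  )
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Odds ratio with Woolf (log-method) confidence interval
#'
#' @param a,b,c,d Cell counts of a 2 x 2 table laid out so that the odds
#'   ratio of interest is `(a*d)/(b*c)`; the caller documents which margin
#'   is exposure and which is outcome.
#' @param alpha Two-sided type-I error for the confidence interval.
#' @param haldane If `TRUE`, add 0.5 to every cell when any cell is zero
#'   (Haldane-Anscombe correction). With the default `FALSE`, a zero cell
#'   is an error.
#' @return A list of class `odds_ratio_result` with `or`, `ci_low`,
#'   `ci_high`, `log_or`, `se_log_or`, `p` (Wald), and `alpha`.
#' @details The confidence interval is
#'   \eqn{\exp(\log \mathrm{OR} \mp z_{1-\alpha/2} \sqrt{1/a + 1/b + 1/c + 1/d})}.
#' @examples
#' # allele-model odds ratio, T vs C, response as outcome
#' odds_ratio_woolf(131, 163, 97, 89)
#' @export
odds_ratio_woolf <- function(a, b, c, d, alpha = 0.05, haldane = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) stop("cells must be non-negative numbers")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(cells == 0)) {
    if (!haldane)
      stop("zero cell in 2x2 table; use haldane = TRUE for the 0.5 correction")
    cells <- cells + 0.5
  }
  log_or <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(or = unname(exp(log_or)),
         ci_low = unname(exp(log_or - z * se)),
         ci_high = unname(exp(log_or + z * se)),
         log_or = unname(log_or), se_log_or = unname(se),
         p = unname(2 * stats::pnorm(-abs(log_or / se))),
         alpha = alpha),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (%d%% CI %.3f, %.3f)\n",
              x$or, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Pearson goodness-of-fit test of observed genotype counts against the
#' Hardy-Weinberg expectations \eqn{N(\hat p^2, 2\hat p\hat q, \hat q^2)}
#' at the allele frequency estimated from the counts, on 1 degree of
#' freedom.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return A `chi2_result` with an extra element `allele_freq` (the
#'   estimated frequency of the A allele).
#' @examples
#' hwe_test(70, 112, 58)  # in equilibrium, p > 0.05
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) stop("monomorphic sample: allele frequency is 0 or 1")
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  statistic <- sum((counts - expected)^2 / expected)
  structure(
    list(statistic = statistic, df = 1L,
         p = stats::pchisq(statistic, 1L, lower.tail = FALSE),
         expected = expected, allele_freq = p),
    class = "chi2_result"
  )
}
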