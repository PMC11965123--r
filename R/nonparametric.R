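#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation using mid-ranks for ties, with the two-sided p-value
#' from the t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on
#' \eqn{n - 2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A list with `rho`, `p`, and `n`.
#' @examples
#' spearman_corr(c(1, 2, 2, 4), c(7, 5, 6, 1))
#' @export
spearman_corr <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H across two or more groups, with the
#' p-value from the chi-squared approximation on k - 1 degrees of freedom.
#' Thin wrapper over [stats::kruskal.test()] adding the degenerate-input
#' contracts used by the pipeline.
#'
#' @param groups A list of non-empty numeric vectors (k >= 2).
#' @return A list with `H`, `df`, `p`, and per-group sizes `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(pooled))) stop("values must be finite")
  if (length(unique(pooled)) == 1L)
    stop("all pooled values identical: tie-corrected H is undefined")
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = as.integer(sizes))
}

#' Mann-Whitney U test (normal approximation)
#'
#' U statistic for x-over-y wins (ties counted half) with the tie-corrected
#' normal approximation and no continuity correction, via
#' [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric vectors.
#' @return A list with `U`, `p`, and sizes `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero-variance case: U at its null mean
  list(U = unname(wt$statistic), p = p,
       n_x = length(x), n_y = length(y))
}
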