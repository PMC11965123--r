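#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Newton-Raphson / IRLS maximum likelihood for a logistic model, with the
#' Wald standard errors taken from the inverse observed information. This
#' is the workhorse behind all adjusted odds ratios (genetic models,
#' per-CpG associations, composite-score models).
#'
#' @param design Numeric design matrix including the intercept column.
#'   Column names label the coefficients; an unnamed first column is
#'   labelled `(Intercept)`.
#' @param outcome Binary 0/1 vector (non-responder = 0 by convention).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change.
#' @return An object of class `logistic_fit`: a list with `coefficients`,
#'   `se`, `wald_z`, `p_values`, `odds_ratios`, `or_ci_low`, `or_ci_high`
#'   (95% Wald), `converged`, `n_obs`, `iterations`, `loglik` and `vcov`.
#' @details Divergence of any coefficient beyond 15 in absolute value
#'   during iteration is treated as (quasi-)complete separation and raised
#'   as an error; non-convergence within `max_iter` returns a fit flagged
#'   `converged = FALSE`, which downstream reporting refuses to use.
#' @examples
#' x <- cbind(1, c(0, 0, 1, 1, 0, 1, 1, 0))
#' y <- c(0, 1, 1, 1, 0, 0, 1, 0)
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(design, outcome, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(design)
  y <- as.numeric(outcome)
  if (length(y) != nrow(x)) stop("outcome length must match design rows")
  if (any(!y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (any(!is.finite(x))) stop("design matrix must be finite")
  if (nrow(x) <= ncol(x)) stop("need more observations than predictors")
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)",
                     if (ncol(x) > 1L) paste0("x", seq_len(ncol(x) - 1L)))
  } else if (colnames(x)[1] == "") {
    colnames(x)[1] <- "(Intercept)"
  }

  beta <- numeric(ncol(x))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(x, x * w)
    score <- crossprod(x, y - mu)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("singular information matrix: collinear or degenerate predictors"))
    beta_new <- beta + drop(step)
    if (any(abs(beta_new) > 15))
      stop("perfect separation detected: coefficients diverging")
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  vcov <- solve(crossprod(x, x * w))
  se <- sqrt(diag(vcov))
  wald_z <- beta / se
  zc <- stats::qnorm(0.975)
  names(beta) <- names(se) <- names(wald_z) <- colnames(x)

  structure(
    list(coefficients = beta, se = se, wald_z = wald_z,
         p_values = 2 * stats::pnorm(-abs(wald_z)),
         odds_ratios = exp(beta),
         or_ci_low = exp(beta - zc * se),
         or_ci_high = exp(beta + zc * se),
         converged = converged, n_obs = nrow(x), iterations = iter,
         loglik = sum(y * log(pmax(mu, 1e-300)) +
                        (1 - y) * log(pmax(1 - mu, 1e-300))),
         vcov = vcov),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fit (n = %d, %s in %d iterations)\n", x$n_obs,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  tab <- data.frame(
    beta = round(x$coefficients, digits), se = round(x$se, digits),
    wald = round(x$wald_z^2, digits), or = round(x$odds_ratios, digits),
    ci_low = round(x$or_ci_low, digits), ci_high = round(x$or_ci_high, digits),
    p = signif(x$p_values, digits)
  )
  print(tab)
  invisible(x)
}

#' Tidy a logistic fit into a Table-2-shaped data frame
#'
#' @param fit A `logistic_fit`.
#' @param terms Optional subset of coefficient names to keep.
#' @return A data frame with columns `term`, `beta`, `se`, `wald`, `df`,
#'   `or`, `or_ci_low`, `or_ci_high`, `p` (Wald chi-squared on 1 df).
#' @export
logistic_report <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge; results suppressed")
  nm <- names(fit$coefficients)
  if (!is.null(terms)) nm <- intersect(nm, terms)
  data.frame(
    term = nm,
    beta = unname(fit$coefficients[nm]),
    se = unname(fit$se[nm]),
    wald = unname(fit$wald_z[nm]^2),
    df = 1L,
    or = unname(fit$odds_ratios[nm]),
    or_ci_low = unname(fit$or_ci_low[nm]),
    or_ci_high = unname(fit$or_ci_high[nm]),
    p = unname(fit$p_values[nm]),
    stringsAsFactors = FALSE
  )
}
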