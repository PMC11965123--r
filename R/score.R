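#' Ordinal protective coding of a methylation category
#'
#' Hypermethylation scores 0, intermediate 1, hypomethylation 2 -- low
#' methylation is the putatively protective state.
#'
#' @param category Factor/character vector over low/medium/high.
#' @return Integer vector in {0, 1, 2}.
#' @export
methylation_code <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), c("low", "medium", "high"))
  if (length(bad)) stop("unknown methylation category: ", paste(bad, collapse = ", "))
  unname(c(high = 0L, medium = 1L, low = 2L)[category])
}

#' Ordinal protective coding of the rs705379 genotype
#'
#' TT scores 0, CT 1, CC 2 -- the C allele is the putatively protective
#' allele.
#'
#' @param genotype CC/CT/TT vector.
#' @return Integer vector in {0, 1, 2}.
#' @export
genotype_code <- function(genotype) {
  genotype <- as.character(genotype)
  bad <- setdiff(unique(genotype), c("CC", "CT", "TT"))
  if (length(bad)) stop("unknown genotype: ", paste(bad, collapse = ", "))
  unname(c(TT = 0L, CT = 1L, CC = 2L)[genotype])
}

#' The nine CpG sites entering the composite score by default
#' @return Character vector of CpG ids.
#' @export
default_scored_cpgs <- function() {
  paste0("cg17330251_", c(2, 3, 4, 6, 7, 8, 9, 10, 12))
}

#' Composite genetic protective score
#'
#' Sums the ordinal methylation codes over the scored CpG sites plus the
#' genotype code, giving an integer in \[0, 2k + 2\] (k scored sites;
#' 0-20 with the default nine). The score is then categorised into
#' cohort quartiles Q1-Q4 at its 25th/50th/75th percentiles (linear
#' interpolation; values at a cutoff fall into the lower quartile).
#'
#' @param categories Data frame or matrix of low/medium/high categories,
#'   columns named by CpG id (as from [categorize_cpg()] applied
#'   per column).
#' @param genotype Aligned CC/CT/TT vector.
#' @param scored_cpgs CpG ids to score; all must be present in
#'   `categories`.
#' @return A list of class `composite_score` with `score` (integer
#'   vector), `quartile` (factor Q1-Q4), `quartile_code` (1-4),
#'   `cutoffs`, `genotype_code` and the per-site `methylation_codes`
#'   matrix.
#' @export
composite_score <- function(categories, genotype,
                            scored_cpgs = default_scored_cpgs()) {
  categories <- as.data.frame(categories)
  missing <- setdiff(scored_cpgs, names(categories))
  if (length(missing))
    stop("missing scored CpG site(s): ", paste(missing, collapse = ", "))
  n <- nrow(categories)
  if (length(genotype) != n) stop("genotype must align with categories")
  mc <- sapply(scored_cpgs, function(s) methylation_code(categories[[s]]))
  mc <- matrix(mc, nrow = n, dimnames = list(NULL, scored_cpgs))
  gc <- genotype_code(genotype)
  score <- as.integer(rowSums(mc) + gc)
  q <- stats::quantile(score, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  code <- findInterval(score, q, left.open = TRUE) + 1L
  quartile <- factor(paste0("Q", code), levels = paste0("Q", 1:4))
  structure(
    list(score = score, quartile = quartile, quartile_code = code,
         cutoffs = c(q25 = q[1], q50 = q[2], q75 = q[3]),
         genotype_code = gc, methylation_codes = mc,
         scored_cpgs = scored_cpgs),
    class = "composite_score"
  )
}

#' Univariate covariate screening at a liberal threshold
#'
#' Fits one unadjusted logistic model per candidate covariate and keeps
#' those with a Wald p-value below the threshold (default 0.2), the
#' entry rule used to select traditional prognostic covariates.
#'
#' @param candidates Named data frame of numeric candidate covariates.
#' @param responder 0/1 outcome vector.
#' @param threshold Retention threshold on the Wald p-value.
#' @return A data frame with `name`, `or`, `ci_low`, `ci_high`, `p`,
#'   `retained`; candidates that are constant or whose fit fails are
#'   excluded with a warning (`retained = NA`).
#' @export
screen_covariates <- function(candidates, responder, threshold = 0.2) {
  candidates <- as.data.frame(candidates)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  rows <- lapply(names(candidates), function(nm) {
    x <- as.numeric(candidates[[nm]])
    if (length(unique(x[is.finite(x)])) <= 1L) {
      warning("candidate ", nm, " is constant; excluded from screening")
      return(data.frame(name = nm, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, retained = NA,
                        stringsAsFactors = FALSE))
    }
    fit <- tryCatch(
      fit_logistic(cbind(`(Intercept)` = 1, x = x), responder),
      error = function(e) e
    )
    if (inherits(fit, "error") || !fit$converged) {
      warning("candidate ", nm, " excluded: ",
              if (inherits(fit, "error")) conditionMessage(fit) else "no convergence")
      return(data.frame(name = nm, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, retained = NA,
                        stringsAsFactors = FALSE))
    }
    data.frame(name = nm, or = fit$odds_ratios[["x"]],
               ci_low = fit$or_ci_low[["x"]], ci_high = fit$or_ci_high[["x"]],
               p = fit$p_values[["x"]],
               retained = fit$p_values[["x"]] < threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# variance inflation factors from a predictor matrix (no intercept column)
vif_from_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(stats::setNames(rep(1, ncol(x)), colnames(x)))
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' Multifactor models for the composite protective score
#'
#' Model 1 regresses response on the score term alone; Model 2 adds the
#' screened covariates. Variance inflation factors are computed for
#' Model 2's predictors and flagged above 5.
#'
#' @param score_term Numeric score predictor (quartile code 1-4 by
#'   default usage, or the raw 0-20 sum).
#' @param screened Named data frame of covariates entering Model 2 (may
#'   have zero columns).
#' @param responder 0/1 outcome vector.
#' @return A list of class `multifactor_models` with `model1`, `model2`
#'   (both `logistic_fit`), `vif` (named vector for Model 2 predictors)
#'   and `collinearity_flag`.
#' @export
fit_multifactor <- function(score_term, screened, responder) {
  score_term <- as.numeric(score_term)
  screened <- as.data.frame(screened)
  n <- length(score_term)
  stopifnot(length(responder) == n,
            nrow(screened) == n || ncol(screened) == 0)

  m1 <- tryCatch(
    fit_logistic(cbind(`(Intercept)` = 1, score = score_term), responder),
    error = function(e) stop("model1 failed: ", conditionMessage(e)))

  x2 <- cbind(score = score_term,
              if (ncol(screened)) sapply(screened, as.numeric))
  colnames(x2) <- c("score", names(screened))
  vif <- vif_from_matrix(x2)
  if (any(!is.finite(vif))) {
    warning("model2 predictors are perfectly collinear (unbounded VIF: ",
            paste(names(vif)[!is.finite(vif)], collapse = ", "),
            "); model2 not fitted")
    m2 <- NULL
  } else {
    m2 <- tryCatch(
      fit_logistic(cbind(`(Intercept)` = 1, x2), responder),
      error = function(e) stop("model2 failed: ", conditionMessage(e)))
  }
  structure(
    list(model1 = m1, model2 = m2, vif = vif,
         collinearity_flag = any(!is.finite(vif) | vif > 5)),
    class = "multifactor_models"
  )
}

#' Table-2-shaped report for the multifactor models
#'
#' @param models Result of [fit_multifactor()].
#' @return A data frame with columns model, term, beta, se, wald, df,
#'   or, or_ci_low, or_ci_high, p.
#' @export
multifactor_report <- function(models) {
  stopifnot(inherits(models, "multifactor_models"))
  r1 <- cbind(model = "model1", logistic_report(models$model1),
              stringsAsFactors = FALSE)
  if (is.null(models$model2)) return(r1)
  rbind(r1, cbind(model = "model2", logistic_report(models$model2),
                  stringsAsFactors = FALSE))
}
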