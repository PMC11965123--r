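#' Quartile-based categorisation of one CpG site
#'
#' Splits methylation values into low / medium / high at the cohort's
#' 25th and 75th percentiles (linear interpolation between order
#' statistics). Values strictly below the 25th percentile are low,
#' strictly above the 75th are high; values exactly at a cutoff are
#' medium, which keeps the low and high groups at no more than a quarter
#' each under heavy ties.
#'
#' @param values Numeric vector, length at least 4.
#' @return A factor with levels low/medium/high and attribute `cutoffs`
#'   (named q25, q75). A constant vector yields all-medium with a
#'   warning.
#' @examples
#' categorize_cpg(c(0.1, 0.2, 0.3, 0.4))
#' @export
categorize_cpg <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("need at least 4 values to form quartiles")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L) {
    warning("constant values: all observations categorised as medium")
    out <- factor(rep("medium", length(values)),
                  levels = c("low", "medium", "high"))
    attr(out, "cutoffs") <- c(q25 = values[1], q75 = values[1])
    return(out)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  cat <- ifelse(values < q[1], "low", ifelse(values > q[2], "high", "medium"))
  out <- factor(cat, levels = c("low", "medium", "high"))
  attr(out, "cutoffs") <- c(q25 = q[1], q75 = q[2])
  out
}

#' Per-CpG association between methylation category and response
#'
#' For each CpG column: (i) the ordinal protective coding
#' (high = 0, medium = 1, low = 2) entered in an age/sex-adjusted
#' logistic fit; (ii) adjusted pairwise contrasts medium-vs-low and
#' high-vs-low on the corresponding subsets; (iii) the uncorrected
#' chi-squared test on the 2 x 3 outcome-by-category table.
#'
#' @param methylation n x k matrix of methylation fractions (columns are
#'   CpG sites).
#' @param responder 0/1 outcome vector.
#' @param age,sex Adjustment covariates; sex is coded female = 1.
#' @param on_error `"stop"` (default) propagates a failed ordinal fit
#'   (e.g. separation) as an error naming the CpG; `"warn"` records an
#'   all-NA row with a warning so an orchestrated run can continue.
#' @return A list of class `cpg_assoc` with a summary data frame
#'   (`$summary`: cpg, ordinal OR and CI and p, contrast ORs, chi2, p)
#'   and per-CpG details (`$details`: categories, tables, fits).
#' @export
per_cpg_association <- function(methylation, responder, age, sex,
                                on_error = c("stop", "warn")) {
  on_error <- match.arg(on_error)
  methylation <- as.matrix(methylation)
  n <- nrow(methylation)
  stopifnot(length(responder) == n, length(age) == n, length(sex) == n)
  sexf <- if (is.numeric(sex)) as.numeric(sex)
          else as.numeric(as.character(sex) == "female")
  details <- list()
  rows <- list()
  for (j in seq_len(ncol(methylation))) {
    cpg <- colnames(methylation)[j]
    if (is.null(cpg)) cpg <- paste0("cpg_", j)
    cats <- categorize_cpg(methylation[, j])
    # a category with no members is merged into medium so the ordinal
    # coding and the table stay estimable
    tabc <- table(cats)
    empty <- names(tabc)[tabc == 0]
    if (length(empty) && any(c("low", "high") %in% empty))
      warning(cpg, ": empty category ", paste(empty, collapse = ", "),
              " collapsed into medium")
    code <- methylation_code(cats)

    design <- cbind(`(Intercept)` = 1, code = code, age = age, sex = sexf)
    ord_fit <- tryCatch(fit_logistic(design, responder), error = function(e) {
      msg <- paste0(cpg, ": ", conditionMessage(e))
      if (on_error == "stop") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      NULL
    })

    contrast_fit <- function(keep_level) {
      idx <- cats %in% c("low", keep_level)
      if (length(unique(cats[idx])) < 2 || length(unique(responder[idx])) < 2)
        return(NULL)
      d <- cbind(`(Intercept)` = 1,
                 level = as.numeric(cats[idx] == keep_level),
                 age = age[idx], sex = sexf[idx])
      tryCatch(fit_logistic(d, responder[idx]), error = function(e) e)
    }
    med_vs_low <- contrast_fit("medium")
    high_vs_low <- contrast_fit("high")

    xt <- table(factor(responder, levels = c(1, 0)), cats)
    keep <- colSums(xt) > 0
    chi2 <- if (sum(keep) >= 2)
      pearson_chi2(contingency_table(xt[, keep, drop = FALSE],
                                     row_labels = c("responder", "non_responder"),
                                     col_labels = colnames(xt)[keep]))
    else NULL

    or_of <- function(f, term) {
      if (is.null(f) || inherits(f, "error")) rep(NA_real_, 4)
      else c(f$odds_ratios[[term]], f$or_ci_low[[term]],
             f$or_ci_high[[term]], f$p_values[[term]])
    }
    mv <- or_of(med_vs_low, "level"); hv <- or_of(high_vs_low, "level")
    ord <- or_of(ord_fit, "code")
    rows[[j]] <- data.frame(
      cpg = cpg,
      ordinal_or = ord[1],
      ordinal_ci_low = ord[2],
      ordinal_ci_high = ord[3],
      ordinal_p = ord[4],
      med_vs_low_or = mv[1], med_vs_low_ci_low = mv[2],
      med_vs_low_ci_high = mv[3], med_vs_low_p = mv[4],
      high_vs_low_or = hv[1], high_vs_low_ci_low = hv[2],
      high_vs_low_ci_high = hv[3], high_vs_low_p = hv[4],
      chi2 = if (is.null(chi2)) NA_real_ else chi2$statistic,
      chi2_p = if (is.null(chi2)) NA_real_ else chi2$p,
      stringsAsFactors = FALSE
    )
    details[[cpg]] <- list(categories = cats, ordinal_fit = ord_fit,
                           med_vs_low = med_vs_low, high_vs_low = high_vs_low,
                           table = xt, chi2 = chi2)
  }
  structure(list(summary = do.call(rbind, rows), details = details),
            class = "cpg_assoc")
}

#' Per-patient average methylation across the 12 CpG sites
#'
#' @param methylation n x 12 matrix of methylation fractions in \[0, 1\].
#' @return Numeric vector of row means; missing entries are averaged over
#'   the observed sites, with the per-row missing count attached as
#'   attribute `n_missing`.
#' @export
average_methylation <- function(methylation) {
  methylation <- as.matrix(methylation)
  if (ncol(methylation) != 12) stop("expected 12 CpG columns")
  rng <- range(methylation, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("methylation values must be in [0, 1]")
  out <- rowMeans(methylation, na.rm = TRUE)
  attr(out, "n_missing") <- rowSums(is.na(methylation))
  out
}

#' Average methylation by rs705379 genotype
#'
#' Per-genotype median and interquartile range of average methylation,
#' with the Kruskal-Wallis test across genotype groups.
#'
#' @param avg Per-patient average methylation ([average_methylation()]).
#' @param genotypes Aligned CC/CT/TT vector.
#' @return A list with `summary` (data frame: genotype, n, median, q25,
#'   q75) and `kruskal` (list H, df, p).
#' @export
methylation_by_genotype <- function(avg, genotypes) {
  genotypes <- as.character(genotypes)
  stopifnot(length(avg) == length(genotypes))
  groups <- split(as.numeric(avg), factor(genotypes, levels = c("CC", "CT", "TT")))
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty)) {
    warning("empty genotype group(s) omitted: ", paste(empty, collapse = ", "))
    groups <- groups[lengths(groups) > 0]
  }
  if (length(groups) < 2) stop("need at least 2 genotype groups")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    q <- stats::quantile(groups[[g]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(genotype = g, n = length(groups[[g]]),
               median = q[2], q25 = q[1], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, kruskal = kruskal_wallis(groups))
}

#' Correlation between average methylation and DAS28 improvement
#'
#' @param avg Per-patient average methylation.
#' @param delta_das28 Aligned DAS28 improvement (baseline minus month 6).
#' @return Spearman correlation result from [spearman_corr()].
#' @export
correlate_with_ddas28 <- function(avg, delta_das28) {
  spearman_corr(avg, delta_das28)
}
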