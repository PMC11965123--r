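#' Cross-tabulate rs705379 genotypes against response under a genetic model
#'
#' @param genotypes CC/CT/TT vector.
#' @param responder 0/1 vector aligned with `genotypes`.
#' @param model One of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"allele"`.
#' @return A [contingency_table()] with outcome groups in rows
#'   (responder, non_responder) and exposure levels in columns. The
#'   codominant model is 2 x 3 (CC, CT, TT); dominant collapses CT+TT;
#'   recessive collapses CC+CT; the allele model counts two alleles per
#'   subject (columns C, T).
#' @examples
#' g <- rep(c("CC", "CT", "TT"), c(70, 112, 58))
#' r <- rep(c(1, 0), length.out = 240)
#' build_model_table(g, r, "dominant")
#' @export
build_model_table <- function(genotypes, responder,
                              model = c("codominant", "dominant",
                                        "recessive", "allele")) {
  model <- match.arg(model)
  genotypes <- as.character(genotypes)
  if (length(genotypes) == 0) stop("empty cohort")
  if (length(genotypes) != length(responder))
    stop("genotypes and responder must be aligned")
  if (any(!genotypes %in% c("CC", "CT", "TT"))) stop("invalid genotype value")
  if (any(!responder %in% c(0, 1))) stop("responder must be 0/1")

  counts_for <- function(resp) {
    g <- genotypes[responder == resp]
    c(CC = sum(g == "CC"), CT = sum(g == "CT"), TT = sum(g == "TT"))
  }
  r1 <- counts_for(1); r0 <- counts_for(0)
  cells <- switch(model,
    codominant = rbind(r1, r0),
    dominant = rbind(c(r1["CC"], sum(r1[c("CT", "TT")])),
                     c(r0["CC"], sum(r0[c("CT", "TT")]))),
    recessive = rbind(c(sum(r1[c("CC", "CT")]), r1["TT"]),
                      c(sum(r0[c("CC", "CT")]), r0["TT"])),
    allele = rbind(c(2 * r1["CC"] + r1["CT"], 2 * r1["TT"] + r1["CT"]),
                   c(2 * r0["CC"] + r0["CT"], 2 * r0["TT"] + r0["CT"]))
  )
  cols <- switch(model,
    codominant = c("CC", "CT", "TT"),
    dominant = c("CC", "CT+TT"),
    recessive = c("CC+CT", "TT"),
    allele = c("C", "T")
  )
  contingency_table(cells, row_labels = c("responder", "non_responder"),
                    col_labels = cols)
}

#' Genetic-model association analysis at rs705379
#'
#' For each genetic model, builds the outcome-by-genotype table and
#' reports the uncorrected Pearson chi-squared test, crude Woolf odds
#' ratios per non-reference level (reference CC, or C for the allele
#' model), and -- for the genotype models -- odds ratios from a logistic
#' fit adjusted for the given covariates. The allele model reports the
#' crude odds ratio only: its rows are alleles, not independent subjects,
#' so covariate adjustment on doubled records is not performed.
#'
#' @param cohort Data frame with columns `genotype`, `responder`, and the
#'   covariate columns (default `age` and numeric-codable `sex`).
#' @param covariates Character vector of adjustment covariate names; sex
#'   is coded female = 1, male = 0.
#' @param models Genetic models to run.
#' @param on_error `"stop"` (default) propagates any model failure --
#'   degenerate margins, separation, non-convergence -- as an error named
#'   after the model; `"warn"` downgrades it to a warning and records the
#'   message in that model's `error` field, so an orchestrated run over a
#'   sparse cohort can continue.
#' @return A list of class `genetic_assoc` keyed by model, each element
#'   holding `table`, `chi2`, `crude_or` (list per non-reference level)
#'   and `adjusted` (a `logistic_fit`, or NULL for the allele model).
#' @export
associate_all_models <- function(cohort, covariates = c("age", "sex"),
                                 models = c("codominant", "dominant",
                                            "recessive", "allele"),
                                 on_error = c("stop", "warn")) {
  on_error <- match.arg(on_error)
  stopifnot(all(c("genotype", "responder") %in% names(cohort)))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))

  covmat <- NULL
  if (length(covariates)) {
    covmat <- sapply(covariates, function(v) {
      x <- cohort[[v]]
      if (v == "sex" || is.factor(x) || is.character(x))
        as.numeric(as.character(x) == "female")
      else as.numeric(x)
    })
    covmat <- matrix(covmat, nrow = nrow(cohort),
                     dimnames = list(NULL, covariates))
  }

  g <- as.character(cohort$genotype)
  y <- cohort$responder
  res <- list()
  for (model in models) {
    tab <- build_model_table(g, y, model)
    one <- tryCatch(
      analyse_one_model(model, tab, g, y, covmat),
      error = function(e) {
        msg <- paste0(model, " model: ", conditionMessage(e))
        if (on_error == "stop") stop(msg, call. = FALSE)
        warning(msg, call. = FALSE)
        list(model = model, table = tab, chi2 = NULL, crude_or = NULL,
             adjusted = NULL, error = msg)
      })
    res[[model]] <- one
  }
  structure(res, class = "genetic_assoc")
}

analyse_one_model <- function(model, tab, g, y, covmat) {
  chi2 <- pearson_chi2(tab)
  # crude OR per non-reference column: odds of response for that level
  # versus the reference (first) column
  crude <- list()
  for (j in 2:ncol(tab)) {
    crude[[colnames(tab)[j]]] <- odds_ratio_woolf(
      a = tab[1, j], b = tab[1, 1], c = tab[2, j], d = tab[2, 1],
      haldane = any(tab[, c(1, j)] == 0)
    )
  }
  adjusted <- NULL
  if (model != "allele") {
    ind <- switch(model,
      codominant = cbind(CT = as.numeric(g == "CT"),
                         TT = as.numeric(g == "TT")),
      dominant = cbind(`CT+TT` = as.numeric(g != "CC")),
      recessive = cbind(TT = as.numeric(g == "TT"))
    )
    design <- cbind(`(Intercept)` = 1, ind, covmat)
    adjusted <- fit_logistic(design, y)
  }
  list(model = model, table = tab, chi2 = chi2, crude_or = crude,
       adjusted = adjusted, error = NULL)
}

#' Flatten a genetic association analysis into a Table-1-shaped data frame
#'
#' @param assoc Result of [associate_all_models()].
#' @return A data frame with one row per genotype level per model:
#'   counts and percentages by outcome group, the model chi-squared and
#'   its p, crude OR (95% CI), and the age/sex-adjusted OR where defined.
#' @export
genetic_report <- function(assoc) {
  stopifnot(inherits(assoc, "genetic_assoc"))
  rows <- list()
  for (m in names(assoc)) {
    a <- assoc[[m]]
    if (!is.null(a$error)) next
    tab <- a$table
    pr <- prop.table(unclass(tab), margin = 1) * 100
    for (j in seq_len(ncol(tab))) {
      lev <- colnames(tab)[j]
      crude <- if (j == 1) NULL else a$crude_or[[lev]]
      adj_or <- adj_lo <- adj_hi <- adj_p <- NA_real_
      if (j > 1 && !is.null(a$adjusted)) {
        nm <- lev
        if (nm %in% names(a$adjusted$coefficients)) {
          adj_or <- a$adjusted$odds_ratios[[nm]]
          adj_lo <- a$adjusted$or_ci_low[[nm]]
          adj_hi <- a$adjusted$or_ci_high[[nm]]
          adj_p <- a$adjusted$p_values[[nm]]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, level = lev,
        responders_n = tab[1, j], responders_pct = pr[1, j],
        non_responders_n = tab[2, j], non_responders_pct = pr[2, j],
        chi2 = if (j == 1) a$chi2$statistic else NA_real_,
        chi2_p = if (j == 1) a$chi2$p else NA_real_,
        crude_or = if (j == 1) NA_real_ else crude$or,
        crude_ci_low = if (j == 1) NA_real_ else crude$ci_low,
        crude_ci_high = if (j == 1) NA_real_ else crude$ci_high,
        adj_or = adj_or, adj_ci_low = adj_lo, adj_ci_high = adj_hi,
        adj_p = adj_p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
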