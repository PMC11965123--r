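#' Clinical scoring stage: DAS28, response category, inflammation indices
#'
#' Computes baseline and month-6 DAS28 (raw visit components win over any
#' precomputed columns; discrepancies above 0.01 are counted and
#' reported), the EULAR response category and responder flag, and the
#' NLR/PLR/SII/SIRI indices.
#'
#' @param cohort A cohort data frame ([read_cohort()] /
#'   [generate_cohort()]).
#' @return The cohort with columns `das28_baseline`, `das28_month6`,
#'   `delta_das28`, `category`, `responder`, `nlr`, `plr`, `sii`, `siri`
#'   added; attribute `das28_mismatch` counts precomputed scores
#'   differing from the recomputed ones by more than 0.01.
#' @export
score_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  schema <- cohort_schema()
  have_visit <- all(schema$visit %in% names(cohort))
  mismatch <- 0L
  if (have_visit) {
    d0 <- das28(cohort$tjc28_baseline, cohort$sjc28_baseline,
                cohort$esr_baseline, cohort$vas_baseline)
    d6 <- das28(cohort$tjc28_month6, cohort$sjc28_month6,
                cohort$esr_month6, cohort$vas_month6)
    for (col in c("das28_baseline", "das28_month6")) {
      if (col %in% names(cohort)) {
        pre <- cohort[[col]]
        rec <- if (col == "das28_baseline") d0 else d6
        mismatch <- mismatch + sum(!is.na(pre) & abs(pre - rec) > 0.01)
      }
    }
    cohort$das28_baseline <- d0
    cohort$das28_month6 <- d6
  } else if (!all(schema$das28 %in% names(cohort))) {
    stop("cohort has neither visit components nor precomputed DAS28")
  }
  resp <- classify_response(cohort$das28_baseline, cohort$das28_month6)
  cohort$delta_das28 <- resp$delta_das28
  cohort$category <- resp$category
  cohort$responder <- resp$responder
  idx <- inflammation_indices(cohort$neut, cohort$lymph, cohort$mono, cohort$plt)
  cohort <- cbind(cohort, idx)
  attr(cohort, "das28_mismatch") <- mismatch
  class(cohort) <- c("lef_cohort", "data.frame")
  cohort
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order: clinical scoring, univariate covariate screening,
#' HWE and genetic-model association, per-CpG methylation
#' categorisation/association, average-methylation analyses (genotype
#' comparison and correlation with the DAS28 improvement), the composite
#' protective score, and the two multifactor models. Optionally writes
#' every report table as CSV.
#'
#' @param cohort A cohort data frame, or NULL to simulate one from
#'   `config`.
#' @param config A [cohort_config()] used when `cohort` is NULL.
#' @param scored_cpgs CpG ids entering the composite score.
#' @param score_coding `"quartile"` (score enters the models as its
#'   quartile code 1-4) or `"raw"` (the 0-20 sum).
#' @param screen_threshold Univariate retention threshold for Model 2
#'   covariates.
#' @param candidates Names of candidate covariate columns for screening.
#' @param out_dir Optional directory for CSV reports.
#' @param na_action `"complete_case"` (drop incomplete rows per analysis,
#'   logged) or `"impute_median"` (single median/mode fill before
#'   analysis).
#' @return A list of class `lef_run` with every stage result and a
#'   `report` summary (row counts, warnings, files written).
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         scored_cpgs = default_scored_cpgs(),
                         score_coding = c("quartile", "raw"),
                         screen_threshold = 0.2,
                         candidates = c("pct", "mono", "plt", "siri"),
                         out_dir = NULL,
                         na_action = c("complete_case", "impute_median")) {
  score_coding <- match.arg(score_coding)
  na_action <- match.arg(na_action)
  simulated <- is.null(cohort)
  if (simulated) cohort <- generate_cohort(config)
  cohort <- as.data.frame(cohort)
  n_in <- nrow(cohort)
  if (n_in == 0) stop("empty cohort")

  meth_cols <- cohort_schema()$methylation
  n_incomplete <- sum(!stats::complete.cases(
    cohort[, intersect(names(cohort), c("age", "sex", "genotype", meth_cols))]))
  if (na_action == "impute_median" && n_incomplete > 0) {
    for (col in names(cohort)) {
      v <- cohort[[col]]
      if (anyNA(v)) {
        if (is.numeric(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
        else {
          tb <- table(v)
          v[is.na(v)] <- names(tb)[which.max(tb)]
        }
        cohort[[col]] <- v
      }
    }
  } else if (n_incomplete > 0) {
    keep <- stats::complete.cases(cohort)
    cohort <- cohort[keep, , drop = FALSE]
  }

  scored <- score_cohort(cohort)
  if (nrow(scored) < 30)
    warning("small cohort (n = ", nrow(scored),
            "): model-based results are unstable")

  # univariate screening of traditional prognostic covariates
  cand <- scored[, intersect(candidates, names(scored)), drop = FALSE]
  screening <- screen_covariates(cand, scored$responder,
                                 threshold = screen_threshold)

  # genetic association: HWE then the four model tables
  gcounts <- table(factor(scored$genotype, levels = c("CC", "CT", "TT")))
  hwe <- hwe_test(gcounts[["CC"]], gcounts[["CT"]], gcounts[["TT"]])
  genetic <- associate_all_models(scored, on_error = "warn")

  # methylation: per-CpG categories and associations
  meth <- as.matrix(scored[, meth_cols])
  cpg <- per_cpg_association(meth, scored$responder, scored$age, scored$sex,
                             on_error = "warn")

  avg <- average_methylation(meth)
  by_geno <- methylation_by_genotype(avg, scored$genotype)
  corr <- correlate_with_ddas28(avg, scored$delta_das28)

  # composite protective score and the two multifactor models
  cats <- as.data.frame(lapply(as.data.frame(meth), categorize_cpg))
  names(cats) <- meth_cols
  score <- composite_score(cats, scored$genotype, scored_cpgs = scored_cpgs)
  score_term <- if (score_coding == "quartile") score$quartile_code else score$score
  retained <- screening$name[!is.na(screening$retained) & screening$retained]
  models <- fit_multifactor(score_term,
                            scored[, retained, drop = FALSE],
                            scored$responder)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      files <<- c(files, p)
    }
    if (simulated) {
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      files <- c(files, file.path(out_dir, "cohort.csv"))
    }
    emit(data.frame(category = names(table(scored$category)),
                    n = as.integer(table(scored$category))),
         "response_categories.csv")
    emit(screening, "covariate_screening.csv")
    emit(genetic_report(genetic), "genetic_association.csv")
    emit(cpg$summary, "per_cpg_association.csv")
    emit(by_geno$summary, "methylation_by_genotype.csv")
    emit(multifactor_report(models), "multifactor_models.csv")
  }

  report <- list(
    n_input = n_in, n_analyzed = nrow(scored),
    n_incomplete = n_incomplete, na_action = na_action,
    das28_mismatch = attr(scored, "das28_mismatch"),
    responders = sum(scored$responder),
    files = files
  )
  structure(
    list(cohort = scored, screening = screening, hwe = hwe,
         genetic = genetic, cpg = cpg,
         methylation_by_genotype = by_geno, correlation = corr,
         score = score, models = models, report = report),
    class = "lef_run"
  )
}

#' Reconstruct a cohort matching the published genotype-by-response counts
#'
#' Builds a deterministic 240-patient cohort whose genotype-by-outcome
#' cross-tabulation equals the published association table exactly
#' (responders 50 CC / 63 CT / 34 TT; non-responders 20 / 49 / 24), with
#' neutral placeholder values for methylation, covariates and blood
#' counts. Used to verify the genetic-model statistics against their
#' printed values.
#'
#' @return A data frame of class `lef_cohort` with `responder` and
#'   DAS28 columns consistent with the response split.
#' @export
reconstruct_published_cohort <- function() {
  counts <- list(
    responder = c(CC = 50, CT = 63, TT = 34),
    non_responder = c(CC = 20, CT = 49, TT = 24)
  )
  genotype <- c(rep(names(counts$responder), counts$responder),
                rep(names(counts$non_responder), counts$non_responder))
  responder <- rep(c(1L, 0L), c(sum(counts$responder), sum(counts$non_responder)))
  n <- length(genotype)
  # responders: good response (5.6 -> 3.0); non-responders: delta 0.2
  das0 <- rep(5.6, n)
  das6 <- ifelse(responder == 1, 3.0, 5.4)
  meth <- matrix(0.5, nrow = n, ncol = 12,
                 dimnames = list(NULL, paste0("cg17330251_", 1:12)))
  cohort <- cbind(
    data.frame(
      id = sprintf("T%04d", seq_len(n)),
      age = 40 + (seq_len(n) %% 31),          # deterministic spread 40-70
      sex = factor(ifelse(seq_len(n) %% 5 == 0, "male", "female"),
                   levels = c("female", "male")),
      genotype = factor(genotype, levels = c("CC", "CT", "TT"))
    ),
    as.data.frame(meth),
    data.frame(
      das28_baseline = das0, das28_month6 = das6,
      delta_das28 = das0 - das6, responder = responder,
      neut = 4, lymph = 2, mono = 0.5, plt = 250, pct = 0.22
    )
  )
  class(cohort) <- c("lef_cohort", "data.frame")
  cohort
}
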