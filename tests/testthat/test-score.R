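test_that("ordinal codings follow the protective convention", {
  expect_identical(methylation_code(c("high", "medium", "low")), c(0L, 1L, 2L))
  expect_identical(genotype_code(c("TT", "CT", "CC")), c(0L, 1L, 2L))
  expect_error(methylation_code("middling"), "unknown")
  expect_error(genotype_code("GG"), "unknown")
})

test_that("composite_score attains its bounds and sums the codes", {
  cpgs <- default_scored_cpgs()
  expect_length(cpgs, 9)

  all_low <- as.data.frame(matrix("low", 4, 9, dimnames = list(NULL, cpgs)))
  all_high <- as.data.frame(matrix("high", 4, 9, dimnames = list(NULL, cpgs)))
  expect_equal(composite_score(all_low, rep("CC", 4))$score, rep(20L, 4))
  expect_equal(composite_score(all_high, rep("TT", 4))$score, rep(0L, 4))

  # 3 low + 4 medium + 2 high with CT: 3*2 + 4*1 + 2*0 + 1 = 11
  one <- as.data.frame(as.list(stats::setNames(
    c(rep("low", 3), rep("medium", 4), rep("high", 2)), cpgs)))
  mixed <- rbind(one, one, one, one)
  expect_equal(composite_score(mixed, rep("CT", 4))$score, rep(11L, 4))

  expect_error(composite_score(all_low[, -1], rep("CC", 4)),
               "cg17330251_2")
})

test_that("every single-step recoding moves the score by exactly one", {
  cpgs <- default_scored_cpgs()
  set.seed(61)
  cats <- as.data.frame(matrix(
    sample(c("low", "medium", "high"), 4 * 9, replace = TRUE),
    4, 9, dimnames = list(NULL, cpgs)), stringsAsFactors = FALSE)
  g <- c("TT", "CT", "CC", "CT")
  base <- composite_score(cats, g)$score

  step_up <- c(high = "medium", medium = "low")
  for (j in seq_along(cpgs)) {
    cur <- cats[[j]][1]
    if (cur == "low") next
    cats2 <- cats
    cats2[[j]][1] <- step_up[[cur]]
    expect_equal(composite_score(cats2, g)$score[1], base[1] + 1L)
  }
  gstep <- c(TT = "CT", CT = "CC")
  for (i in 1:4) {
    if (g[i] == "CC") next
    g2 <- g; g2[i] <- gstep[[g[i]]]
    expect_equal(composite_score(cats, g2)$score[i], base[i] + 1L)
  }

  # with methylation fixed, CC - TT is exactly 2 for every patient
  expect_equal(composite_score(cats, rep("CC", 4))$score -
                 composite_score(cats, rep("TT", 4))$score,
               rep(2L, 4))
})

test_that("score quartile categories respect the cutoffs", {
  cpgs <- default_scored_cpgs()
  set.seed(62)
  n <- 200
  cats <- as.data.frame(matrix(
    sample(c("low", "medium", "high"), n * 9, replace = TRUE),
    n, 9, dimnames = list(NULL, cpgs)), stringsAsFactors = FALSE)
  g <- sample(c("CC", "CT", "TT"), n, replace = TRUE)
  cs <- composite_score(cats, g)
  expect_true(all(cs$score >= 0 & cs$score <= 20))
  expect_true(all(cs$quartile_code %in% 1:4))
  expect_true(all(cs$score[cs$quartile_code == 1] <= cs$cutoffs["q25"]))
  expect_true(all(cs$score[cs$quartile_code == 4] > cs$cutoffs["q75"]))
})

test_that("screen_covariates applies the liberal univariate threshold", {
  set.seed(63)
  n <- 2000
  strong <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 1.2 * strong))
  noise <- rnorm(n)
  expect_warning(
    res <- screen_covariates(
      data.frame(strong = strong, noise = noise, flat = rep(1, n)), y),
    "constant")
  expect_true(res$retained[res$name == "strong"])
  expect_true(is.na(res$retained[res$name == "flat"]))
  expect_lt(res$p[res$name == "strong"], 1e-6)

  expect_error(screen_covariates(data.frame(x = strong), y, threshold = 1.5),
               "threshold")
})

test_that("an unrelated candidate is retained at roughly the threshold rate", {
  set.seed(64)
  kept <- vapply(1:300, function(i) {
    x <- rnorm(400)
    y <- rbinom(400, 1, 0.6)
    screen_covariates(data.frame(x = x), y)$retained
  }, logical(1))
  expect_gt(mean(kept), 0.13)
  expect_lt(mean(kept), 0.28)
})

test_that("fit_multifactor builds both models and flags collinearity", {
  sc <- small_scored_cohort(n = 240, seed = 65)
  cats <- as.data.frame(lapply(sc[, meth_cols], categorize_cpg))
  names(cats) <- meth_cols
  cs <- composite_score(cats, sc$genotype)
  mm <- fit_multifactor(cs$quartile_code,
                        data.frame(siri = sc$siri, mono = sc$mono),
                        sc$responder)
  expect_true(mm$model1$converged && mm$model2$converged)
  expect_named(mm$vif, c("score", "siri", "mono"))
  rep2 <- multifactor_report(mm)
  expect_setequal(unique(rep2$model), c("model1", "model2"))
  expect_true(all(rep2$or_ci_low <= rep2$or & rep2$or <= rep2$or_ci_high))

  # duplicated predictor: unbounded VIF flagged, model2 withheld
  dup <- data.frame(siri = sc$siri, siri2 = sc$siri)
  expect_warning(mm_dup <- fit_multifactor(cs$quartile_code, dup, sc$responder),
                 "collinear")
  expect_true(mm_dup$collinearity_flag)
  expect_true(any(!is.finite(mm_dup$vif)))
  expect_null(mm_dup$model2)
})

test_that("score direction matches the protective construction in most cohorts", {
  hits <- vapply(1:200, function(s) {
    sc <- score_cohort(generate_cohort(cohort_config(n = 240, seed = 900 + s)))
    cats <- as.data.frame(lapply(sc[, meth_cols], categorize_cpg))
    names(cats) <- meth_cols
    cs <- composite_score(cats, sc$genotype)
    f <- fit_logistic(cbind(1, score = cs$quartile_code), sc$responder)
    unname(f$odds_ratios["score"]) > 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
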