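test_that("categorize_cpg splits at interpolated quartile cutoffs", {
  cats <- categorize_cpg(1:100)
  cut <- attr(cats, "cutoffs")
  expect_equal(unname(cut), c(25.75, 75.25))
  # order-statistics oracle: values strictly below/above the cutoffs
  expect_equal(as.integer(table(cats)), c(25, 50, 25))

  cats <- categorize_cpg(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(attr(cats, "cutoffs")), c(0.175, 0.325))
  expect_equal(as.character(cats), c("low", "medium", "medium", "high"))

  expect_warning(cats <- categorize_cpg(rep(0.4, 4)), "constant")
  expect_true(all(cats == "medium"))
  expect_error(categorize_cpg(1:3), "at least 4")
})

test_that("categorisation is equivariant under strictly monotone transforms", {
  set.seed(51)
  x <- rbeta(200, 2, 5)
  base <- as.character(categorize_cpg(x))
  expect_identical(as.character(categorize_cpg(qlogis(x))), base)
  expect_identical(as.character(categorize_cpg(x^3)), base)
})

test_that("low/high groups stay within a quarter plus ties at the cutoff", {
  set.seed(52)
  for (i in 1:10) {
    x <- sample(round(runif(80), 2), 80, replace = TRUE)  # heavy ties
    cats <- categorize_cpg(x)
    cut <- attr(cats, "cutoffs")
    n <- length(x)
    expect_lte(abs(sum(cats == "low") - 0.25 * n), sum(x == cut["q25"]) + 1)
    expect_lte(abs(sum(cats == "high") - 0.25 * n), sum(x == cut["q75"]) + 1)
    expect_lte(sum(cats == "low"), ceiling(0.25 * n))
    expect_lte(sum(cats == "high"), ceiling(0.25 * n))
  }
})

test_that("per_cpg_association estimates a null ordinal OR near 1", {
  set.seed(53)
  n <- 1e4
  m <- matrix(rbeta(n, 4, 6), ncol = 1, dimnames = list(NULL, "cg17330251_1"))
  y <- rbinom(n, 1, 0.6)
  res <- per_cpg_association(m, y, age = rnorm(n, 55, 10),
                             sex = rbinom(n, 1, 0.8))
  expect_gt(res$summary$ordinal_or, 0.9)
  expect_lt(res$summary$ordinal_or, 1.1)
  expect_false(is.na(res$summary$chi2))
})

test_that("a deterministic category-outcome link raises the separation error", {
  set.seed(54)
  m <- matrix(runif(200), ncol = 1, dimnames = list(NULL, "cg17330251_1"))
  cats <- categorize_cpg(m[, 1])
  y <- as.integer(cats == "low")
  expect_error(
    per_cpg_association(m, y, age = rnorm(200), sex = rbinom(200, 1, 0.5)),
    "separation")
})

test_that("flipping the outcome inverts the ordinal OR to its reciprocal", {
  sc <- small_scored_cohort(n = 240, seed = 55)
  m <- as.matrix(sc[, meth_cols[1:3]])
  a <- per_cpg_association(m, sc$responder, sc$age,
                           as.numeric(sc$sex == "female"))
  b <- per_cpg_association(m, 1 - sc$responder, sc$age,
                           as.numeric(sc$sex == "female"))
  expect_equal(a$summary$ordinal_or, 1 / b$summary$ordinal_or,
               tolerance = 1e-6)
})

test_that("protective methylation lowers the adjusted risk of non-response in most cohorts", {
  # direction recovery: with the default negative methylation effect,
  # hypomethylation (code 2) should predict response (OR > 1 for the
  # protective coding) in most seeds
  hits <- vapply(1:40, function(s) {
    sc <- score_cohort(generate_cohort(cohort_config(n = 240, seed = 700 + s)))
    avg <- average_methylation(as.matrix(sc[, meth_cols]))
    m <- matrix(avg, ncol = 1, dimnames = list(NULL, "avg"))
    res <- per_cpg_association(m, sc$responder, sc$age,
                               as.numeric(sc$sex == "female"))
    res$summary$ordinal_or > 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("average_methylation is the row mean with a logged missing count", {
  m <- matrix(0.5, 3, 12)
  expect_equal(unname(average_methylation(m)), rep(0.5, 3), ignore_attr = TRUE)
  m2 <- matrix(rep(c(0, 1), 18), 3, 12)
  expect_equal(as.numeric(average_methylation(m2)), rep(0.5, 3))
  set.seed(56)
  m3 <- matrix(runif(12), 1, 12)
  expect_equal(as.numeric(average_methylation(m3)), sum(m3) / 12)

  m3[1, c(2, 5)] <- NA
  avg <- average_methylation(m3)
  expect_equal(as.numeric(avg), mean(m3[1, ], na.rm = TRUE))
  expect_equal(unname(attr(avg, "n_missing")), 2)

  expect_error(average_methylation(matrix(0.5, 2, 11)), "12")
  expect_error(average_methylation(matrix(1.2, 2, 12)), "\\[0, 1\\]")
})

test_that("methylation_by_genotype summarises groups and tests across them", {
  sc <- small_scored_cohort(n = 240, seed = 57)
  avg <- average_methylation(as.matrix(sc[, meth_cols]))
  r <- methylation_by_genotype(avg, sc$genotype)
  expect_setequal(r$summary$genotype, c("CC", "CT", "TT"))
  expect_true(all(r$summary$q25 <= r$summary$median &
                    r$summary$median <= r$summary$q75))
  expect_lt(r$kruskal$p, 0.001)

  expect_error(methylation_by_genotype(avg, rep("CC", length(avg))),
               "2 genotype groups")
  expect_warning(
    methylation_by_genotype(avg[sc$genotype != "TT"],
                            as.character(sc$genotype[sc$genotype != "TT"])),
    "omitted")
})
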