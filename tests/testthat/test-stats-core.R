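test_that("pearson_chi2 matches published genotype-table statistics and the expected-count oracle", {
  # codominant genotype-by-response table
  r <- pearson_chi2(rbind(c(50, 63, 34), c(20, 49, 24)))
  expect_equal(r$statistic, 4.404246, tolerance = 1e-6)
  expect_identical(r$df, 2L)

  # proportional rows carry no association
  expect_equal(pearson_chi2(rbind(c(10, 10), c(10, 10)))$statistic, 0)

  # brute-force expected-count oracle on [[5,1],[2,8]]: margins (6,10)
  # and (7,9) over N = 16 give expected cells 2.625/3.375/4.375/5.625
  m <- rbind(c(5, 1), c(2, 8))
  exp_cells <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(unname(exp_cells[1, ]), c(2.625, 3.375))
  expect_equal(pearson_chi2(m)$statistic, sum((m - exp_cells)^2 / exp_cells))

  # independent route: chisq.test without continuity correction
  set.seed(42)
  for (i in 1:25) {
    m <- random_table(sample(2:3, 1), sample(2:4, 1))
    expect_equal(pearson_chi2(m)$statistic,
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = FALSE)$statistic)),
                 tolerance = 1e-10)
  }
})

test_that("pearson_chi2 is invariant under row and column permutation", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_table(3, 3)
    base <- pearson_chi2(m)$statistic
    expect_equal(pearson_chi2(m[sample(3), sample(3)])$statistic, base)
  }
})

test_that("pearson_chi2 rejects degenerate tables with named margins", {
  expect_error(pearson_chi2(matrix(0, 2, 2)), "grand total")
  m <- rbind(c(0, 0), c(3, 4))
  expect_error(pearson_chi2(contingency_table(m, row_labels = c("resp", "non"))),
               "resp")
  expect_error(pearson_chi2(rbind(c(0, 3), c(0, 4))), "column")
  expect_error(contingency_table(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("odds_ratio_woolf reproduces the published allele odds ratio and closed forms", {
  r <- odds_ratio_woolf(131, 163, 97, 89)
  expect_equal(r$or, 0.737, tolerance = 1e-3)
  expect_equal(r$ci_low, 0.510, tolerance = 1e-3)
  expect_equal(r$ci_high, 1.066, tolerance = 1e-3)

  expect_equal(odds_ratio_woolf(1, 1, 1, 1)$or, 1.0)

  # Haldane correction with one zero cell
  r0 <- odds_ratio_woolf(0, 5, 3, 7, haldane = TRUE)
  expect_equal(r0$or, (0.5 * 7.5) / (5.5 * 3.5))
  expect_error(odds_ratio_woolf(0, 5, 3, 7), "haldane")
})

test_that("swapping the exposure margin inverts the odds ratio exactly", {
  set.seed(3)
  for (i in 1:20) {
    cells <- stats::rpois(4, 10) + 1
    o1 <- odds_ratio_woolf(cells[1], cells[2], cells[3], cells[4])
    o2 <- odds_ratio_woolf(cells[2], cells[1], cells[4], cells[3])
    expect_equal(o1$or * o2$or, 1.0, tolerance = 1e-12)
  }
})

test_that("hwe_test is zero at exact Hardy-Weinberg proportions and matches the closed form", {
  expect_equal(hwe_test(25, 50, 25)$statistic, 0)

  # pooled genotype counts 70/112/58: allele freq 0.525
  r <- hwe_test(70, 112, 58)
  expect_equal(r$allele_freq, 0.525)
  expect_equal(r$statistic, 0.993, tolerance = 1e-3)
  expect_equal(r$p, 0.319, tolerance = 1e-3)
  expect_gt(r$p, 0.05)

  expect_lt(hwe_test(50, 0, 50)$p, 1e-10)
  expect_error(hwe_test(10, 0, 0), "monomorphic")

  # any counts sitting exactly at N*(p^2, 2pq, q^2) give statistic 0
  for (p in c(0.2, 0.5, 0.7)) {
    n <- 1000
    expect_equal(hwe_test(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)$statistic,
                 0, tolerance = 1e-10)
  }
})

test_that("fit_logistic recovers closed forms and agrees with glm", {
  # intercept-only with balanced outcome: log-odds 0
  y <- rep(c(0, 1), 20)
  f <- fit_logistic(matrix(1, 40, 1), y)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-10)

  # single binary predictor reproduces the contingency-table OR and
  # Woolf SE to at least 6 decimals
  set.seed(5)
  x <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, plogis(-0.3 + 0.8 * x))
  f <- fit_logistic(cbind(1, x = x), y)
  a <- sum(x == 1 & y == 1); b <- sum(x == 0 & y == 1)
  c_ <- sum(x == 1 & y == 0); d <- sum(x == 0 & y == 0)
  o <- odds_ratio_woolf(a, b, c_, d)
  expect_equal(unname(f$odds_ratios["x"]), o$or, tolerance = 1e-7)
  expect_equal(unname(f$se["x"]), o$se_log_or, tolerance = 1e-7)

  # independent route: glm coefficients and SEs
  set.seed(6)
  x1 <- rnorm(150); x2 <- rbinom(150, 1, 0.5)
  y <- rbinom(150, 1, plogis(0.2 + 0.5 * x1 - 0.7 * x2))
  f <- fit_logistic(cbind(1, x1 = x1, x2 = x2), y)
  g <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  # glm stops on the deviance, this IRLS on the coefficients; SEs agree
  # to the solvers' common precision
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_true(f$converged)
})

test_that("fit_logistic flags separation and degenerate designs", {
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(cbind(1, x = y), y), "separation")
  expect_error(fit_logistic(cbind(1, a = 1:20, b = 2 * (1:20)), y), "singular")
  expect_error(fit_logistic(matrix(1, 5, 1), c(0, 1, 2, 0, 1)), "0/1")
})

test_that("spearman_corr uses mid-ranks and the t approximation", {
  expect_equal(spearman_corr(1:3, c(10, 20, 30))$rho, 1.0)
  expect_equal(spearman_corr(1:3, c(3, 2, 1))$rho, -1.0)

  # mid-rank oracle on a tied vector
  x <- c(1, 2, 2, 4); y <- c(7, 5, 6, 1)
  oracle_rho <- stats::cor(rank(x), rank(y))
  r <- spearman_corr(x, y)
  expect_equal(r$rho, oracle_rho)
  tstat <- oracle_rho * sqrt((4 - 2) / (1 - oracle_rho^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tstat), 2))

  # independent route: cor.test with the asymptotic p
  set.seed(9)
  x <- rnorm(30); y <- x + rnorm(30)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  r <- spearman_corr(x, y)
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-10)

  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("kruskal_wallis matches the direct rank-sum formula and the two-group special case", {
  expect_equal(kruskal_wallis(list(1:3, 1:3, 1:3))$H, 0)

  # no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  pooled <- unlist(groups)
  rk <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(rk, idx, mean)
  N <- length(pooled)
  H_oracle <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  expect_equal(kruskal_wallis(groups)$H, H_oracle)

  # two groups: p agrees with the tie-corrected normal-approximation
  # Mann-Whitney p (z^2 is chi-squared on 1 df)
  set.seed(13)
  x <- sample(1:8, 9, replace = TRUE); y <- sample(3:10, 7, replace = TRUE)
  expect_equal(kruskal_wallis(list(x, y))$p, mann_whitney(x, y)$p,
               tolerance = 1e-10)

  expect_error(kruskal_wallis(list(rep(2, 3), rep(2, 4))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("mann_whitney counts winning pairs and handles symmetry", {
  expect_equal(mann_whitney(1:3, 4:6)$U, 0)
  expect_equal(mann_whitney(1:3, 1:3)$p, 1.0)

  # brute-force pairwise-count oracle
  set.seed(21)
  x <- sample(1:10, 5, replace = TRUE); y <- sample(1:10, 5, replace = TRUE)
  wins <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(mann_whitney(x, y)$U), wins)
})

test_that("chi-squared p-values are approximately uniform under the null", {
  # 2x2 tables from independent margins; rejection rate at 0.05 within
  # [0.03, 0.07] over 2000 replicates
  set.seed(314)
  n <- 200
  rej <- logical(2000)
  for (i in seq_len(2000)) {
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.4)
    tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
    rej[i] <- pearson_chi2(tab)$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
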