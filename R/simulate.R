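#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' @param n Number of subjects.
#' @param allele_freq_C Frequency p of the C allele; genotypes are drawn
#'   multinomially with probabilities (p^2, 2pq, q^2) for (CC, CT, TT).
#' @return A factor of length `n` with levels CC, CT, TT.
#' @export
sample_genotypes <- function(n, allele_freq_C) {
  if (allele_freq_C <= 0 || allele_freq_C >= 1)
    stop("allele_freq_C must be in (0, 1)")
  p <- allele_freq_C
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  factor(sample(c("CC", "CT", "TT"), size = n, replace = TRUE, prob = probs),
         levels = c("CC", "CT", "TT"))
}

#' Sample genotype-conditional CpG methylation
#'
#' Allele-specific methylation is modelled at the patient level: each
#' patient draws a latent methylation level from the Beta distribution
#' matching their genotype's median/IQR targets, and the 12 CpG sites
#' scatter around it on the logit scale with per-site offsets and noise
#' scaled by `site_sd * sqrt(1 - site_corr)`.
#'
#' @param genotypes Factor/character vector of CC/CT/TT genotypes.
#' @param config A [cohort_config()].
#' @return An n x 12 matrix with columns `cg17330251_1` ... `cg17330251_12`,
#'   all values strictly inside (0, 1).
#' @export
sample_methylation <- function(genotypes, config) {
  validate_cohort_config(config)
  genotypes <- as.character(genotypes)
  n <- length(genotypes)
  sites <- paste0("cg17330251_", 1:12)
  if (n == 0)
    return(matrix(numeric(0), nrow = 0, ncol = 12, dimnames = list(NULL, sites)))
  if (any(!genotypes %in% c("CC", "CT", "TT"))) stop("invalid genotype value")

  params <- lapply(c(CC = "CC", CT = "CT", TT = "TT"), function(g) {
    beta_params_from_median_iqr(config$meth_median[[g]],
                                config$meth_q25[[g]], config$meth_q75[[g]])
  })
  latent <- numeric(n)
  for (g in c("CC", "CT", "TT")) {
    idx <- which(genotypes == g)
    if (length(idx))
      latent[idx] <- stats::rbeta(length(idx), params[[g]]$alpha, params[[g]]$beta)
  }
  latent <- pmin(pmax(latent, 1e-6), 1 - 1e-6)
  z <- stats::qlogis(latent)
  noise_sd <- config$site_sd * sqrt(1 - config$site_corr)
  eps <- matrix(stats::rnorm(n * 12, sd = noise_sd), nrow = n)
  logits <- sweep(eps, 2, config$site_offsets, "+") + z
  meth <- stats::plogis(logits)
  meth <- pmin(pmax(meth, 1e-8), 1 - 1e-8)
  dimnames(meth) <- list(NULL, sites)
  meth
}

# expected average methylation under the configured genotype mixture,
# used to centre the methylation effect in the outcome model
expected_mean_methylation <- function(config) {
  p <- config$allele_freq_C
  w <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum(w * unname(config$meth_median))
}

# back-solve TJC/SJC/ESR/VAS from a target DAS28: ESR and VAS are drawn
# first, joint counts absorb the remainder, and the continuous VAS takes
# up the rounding residual so the recomputed score stays within 0.15 of
# the target except at clamped extremes
backfill_visit <- function(target) {
  n <- length(target)
  target <- pmax(target, 0)
  esr <- pmin(pmax(stats::rlnorm(n, log(28), 0.45), 1), 140)
  # keep the ESR term at no more than 60% of the target score
  cap <- 0.6 * target
  over <- 0.70 * log(esr) > cap
  esr[over] <- exp(pmax(cap[over], 0) / 0.70)
  esr <- pmin(pmax(esr, 1), 140)
  vas <- stats::runif(n, 10, 50)
  rem <- target - 0.70 * log(esr) - 0.014 * vas
  neg <- rem < 0
  vas[neg] <- pmax(0, (target[neg] - 0.70 * log(esr[neg])) / 0.014)
  vas <- pmin(vas, 100)
  rem <- pmax(target - 0.70 * log(esr) - 0.014 * vas, 0)
  tjc <- pmin(round((rem / 0.84)^2), 28)
  rem2 <- rem - 0.56 * sqrt(tjc)
  sjc <- pmin(pmax(round((pmax(rem2, 0) / 0.28)^2), 0), 28)
  rem3 <- rem2 - 0.28 * sqrt(sjc)
  vas <- pmin(pmax(vas + rem3 / 0.014, 0), 100)
  achieved <- 0.56 * sqrt(tjc) + 0.28 * sqrt(sjc) + 0.70 * log(esr) + 0.014 * vas
  list(tjc28 = as.integer(tjc), sjc28 = as.integer(sjc), esr = esr, vas = vas,
       das28 = achieved, residual = target - achieved)
}

#' Sample treatment outcomes given genotype and methylation
#'
#' The six-month DAS28 improvement is linear in centred average
#' methylation with Gaussian noise; baseline DAS28 is a truncated normal;
#' month-6 DAS28 is baseline minus improvement, floored at 0; raw
#' TJC/SJC/ESR/VAS are back-filled consistently with the DAS28 formula.
#'
#' @param genotypes Genotype vector (used only for its length; the
#'   genotype effect on outcome is mediated through methylation).
#' @param methylation n x 12 methylation matrix from
#'   [sample_methylation()].
#' @param config A [cohort_config()].
#' @return A data frame with baseline/month-6 visit components, the
#'   achieved DAS28 scores and the improvement `delta_das28`, plus an
#'   attribute `backfill_residual` with the DAS28 reconstruction
#'   residuals.
#' @export
sample_outcomes <- function(genotypes, methylation, config) {
  validate_cohort_config(config)
  n <- length(genotypes)
  if (n == 0) {
    out <- data.frame(tjc28_baseline = integer(0), sjc28_baseline = integer(0),
                      esr_baseline = numeric(0), vas_baseline = numeric(0),
                      tjc28_month6 = integer(0), sjc28_month6 = integer(0),
                      esr_month6 = numeric(0), vas_month6 = numeric(0),
                      das28_baseline = numeric(0), das28_month6 = numeric(0),
                      delta_das28 = numeric(0))
    attr(out, "backfill_residual") <- numeric(0)
    return(out)
  }
  avg <- rowMeans(methylation)
  centre <- expected_mean_methylation(config)
  delta <- config$delta_mean +
    config$meth_effect_on_delta * (avg - centre) +
    stats::rnorm(n, sd = config$delta_sd)

  rng <- config$baseline_das28_range
  plo <- stats::pnorm(rng[1], config$baseline_das28_mean, config$baseline_das28_sd)
  phi <- stats::pnorm(rng[2], config$baseline_das28_mean, config$baseline_das28_sd)
  baseline <- stats::qnorm(stats::runif(n, plo, phi),
                           config$baseline_das28_mean, config$baseline_das28_sd)
  month6 <- pmax(baseline - delta, 0)

  v0 <- backfill_visit(baseline)
  v6 <- backfill_visit(month6)
  out <- data.frame(
    tjc28_baseline = v0$tjc28, sjc28_baseline = v0$sjc28,
    esr_baseline = v0$esr, vas_baseline = v0$vas,
    tjc28_month6 = v6$tjc28, sjc28_month6 = v6$sjc28,
    esr_month6 = v6$esr, vas_month6 = v6$vas,
    das28_baseline = v0$das28, das28_month6 = v6$das28,
    delta_das28 = v0$das28 - v6$das28
  )
  attr(out, "backfill_residual") <- cbind(baseline = v0$residual,
                                          month6 = v6$residual)
  out
}

#' Generate a synthetic RA cohort
#'
#' Composes the genotype, methylation, outcome and hematology samplers
#' into a full per-patient table. All draws come from one seeded stream
#' in a fixed order (age, sex, genotype, methylation, outcomes,
#' hematology), so cohorts are bit-reproducible given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `lef_cohort`, one row per patient, with
#'   demographics, genotype, the 12 `cg17330251_*` methylation columns,
#'   baseline and month-6 visit components plus achieved DAS28, and
#'   blood counts.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 20, seed = 42))
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n
  arng <- config$age_range
  plo <- stats::pnorm(arng[1], config$age_mean, config$age_sd)
  phi <- stats::pnorm(arng[2], config$age_mean, config$age_sd)
  age <- round(stats::qnorm(stats::runif(n, plo, phi),
                            config$age_mean, config$age_sd), 1)
  sex <- factor(ifelse(stats::runif(n) < config$prop_female, "female", "male"),
                levels = c("female", "male"))
  genotype <- sample_genotypes(n, config$allele_freq_C)
  meth <- sample_methylation(genotype, config)
  outcomes <- sample_outcomes(genotype, meth, config)
  h <- config$hematology
  hem <- data.frame(
    neut = stats::rlnorm(n, h$neut[1], h$neut[2]),
    lymph = stats::rlnorm(n, h$lymph[1], h$lymph[2]),
    mono = stats::rlnorm(n, h$mono[1], h$mono[2]),
    plt = stats::rlnorm(n, h$plt[1], h$plt[2]),
    pct = stats::rlnorm(n, h$pct[1], h$pct[2])
  )
  id <- if (n > 0) sprintf("P%04d", seq_len(n)) else character(0)
  cohort <- cbind(
    data.frame(id = id, age = age, sex = sex, genotype = genotype),
    as.data.frame(meth), outcomes, hem
  )
  rownames(cohort) <- NULL
  attr(cohort, "config") <- config
  attr(cohort, "backfill_residual") <- attr(outcomes, "backfill_residual")
  class(cohort) <- c("lef_cohort", "data.frame")
  cohort
}
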