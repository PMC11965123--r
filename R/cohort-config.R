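#' Configuration for the synthetic RA cohort generator
#'
#' Bundles every generator parameter with validation. The defaults encode
#' the study conditions the analysis assumes: 240 patients, rs705379 C
#' allele frequency 0.525 (pooled genotype counts 70/112/58), per-genotype
#' average-methylation medians and IQRs of 0.229 (0.195-0.287) for CC,
#' 0.363 (0.332-0.395) for CT and 0.531 (0.496-0.557) for TT, and a
#' negative methylation effect on the six-month DAS28 improvement sized to
#' give a Spearman correlation near -0.13 at n = 240.
#'
#' @param n Cohort size.
#' @param allele_freq_C Frequency of the C allele, in (0, 1).
#' @param meth_median,meth_q25,meth_q75 Named length-3 vectors (CC, CT, TT)
#'   of the target median and quartiles of the per-patient latent
#'   methylation level, each strictly inside (0, 1) with q25 < median < q75
#'   and medians strictly increasing CC < CT < TT.
#' @param site_offsets Length-12 vector of per-CpG offsets on the logit
#'   scale; defaults are small, symmetric and sum to zero.
#' @param site_corr Within-patient correlation knob in \[0, 1\]; 1 makes
#'   all 12 sites identical up to their offsets.
#' @param site_sd Logit-scale standard deviation of independent per-site
#'   noise at `site_corr = 0`; the effective noise sd is
#'   `site_sd * sqrt(1 - site_corr)`.
#' @param meth_effect_on_delta Slope of centred average methylation in the
#'   DAS28-improvement model (negative: higher methylation, less
#'   improvement).
#' @param delta_mean Mean DAS28 improvement at the average methylation
#'   level.
#' @param delta_sd Residual sd of the improvement.
#' @param baseline_das28_mean,baseline_das28_sd,baseline_das28_range
#'   Truncated-normal parameters of baseline DAS28.
#' @param hematology Named list of `c(meanlog, sdlog)` pairs for the
#'   log-normal blood-count draws (`neut`, `lymph`, `mono`, `plt`, `pct`),
#'   counts in 10^9/L, plateletcrit in percent.
#' @param age_mean,age_sd,age_range Truncated-normal age parameters
#'   (years).
#' @param prop_female Probability a patient is female.
#' @param seed Integer seed making cohorts bit-reproducible.
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n = 50, seed = 7)
#' @export
cohort_config <- function(n = 240,
                          allele_freq_C = 0.525,
                          meth_median = c(CC = 0.229, CT = 0.363, TT = 0.531),
                          meth_q25 = c(CC = 0.195, CT = 0.332, TT = 0.496),
                          meth_q75 = c(CC = 0.287, CT = 0.395, TT = 0.557),
                          site_offsets = NULL,
                          site_corr = 0.85,
                          site_sd = 0.25,
                          meth_effect_on_delta = -1.0,
                          delta_mean = 1.3,
                          delta_sd = 1.0,
                          baseline_das28_mean = 5.1,
                          baseline_das28_sd = 1.0,
                          baseline_das28_range = c(0.5, 9.0),
                          hematology = list(
                            neut = c(meanlog = log(4.0), sdlog = 0.35),
                            lymph = c(meanlog = log(1.8), sdlog = 0.35),
                            mono = c(meanlog = log(0.45), sdlog = 0.35),
                            plt = c(meanlog = log(250), sdlog = 0.25),
                            pct = c(meanlog = log(0.22), sdlog = 0.2)
                          ),
                          age_mean = 55, age_sd = 10, age_range = c(18, 90),
                          prop_female = 0.8,
                          seed = 1L) {
  if (is.null(site_offsets)) {
    site_offsets <- seq(-0.15, 0.15, length.out = 12)
    site_offsets <- site_offsets - mean(site_offsets)
  }
  cfg <- list(
    n = n, allele_freq_C = allele_freq_C,
    meth_median = meth_median, meth_q25 = meth_q25, meth_q75 = meth_q75,
    site_offsets = site_offsets, site_corr = site_corr, site_sd = site_sd,
    meth_effect_on_delta = meth_effect_on_delta,
    delta_mean = delta_mean, delta_sd = delta_sd,
    baseline_das28_mean = baseline_das28_mean,
    baseline_das28_sd = baseline_das28_sd,
    baseline_das28_range = baseline_das28_range,
    hematology = hematology,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    prop_female = prop_female, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n), length(cfg$n) == 1, cfg$n >= 0,
            cfg$n == round(cfg$n))
  if (cfg$allele_freq_C <= 0 || cfg$allele_freq_C >= 1)
    stop("allele_freq_C must be in (0, 1)")
  gl <- c("CC", "CT", "TT")
  for (nm in c("meth_median", "meth_q25", "meth_q75")) {
    v <- cfg[[nm]]
    if (length(v) != 3) stop(nm, " must have length 3 (CC, CT, TT)")
    if (any(v <= 0) || any(v >= 1)) stop(nm, " must lie strictly in (0, 1)")
  }
  m <- unname(cfg$meth_median); lo <- unname(cfg$meth_q25); hi <- unname(cfg$meth_q75)
  if (any(!(lo < m & m < hi)))
    stop("need meth_q25 < meth_median < meth_q75 per genotype")
  # the default configuration orders medians CC < CT < TT (allele-specific
  # methylation); equal medians are allowed so null scenarios can be simulated
  if (length(cfg$site_offsets) != 12) stop("site_offsets must have length 12")
  if (cfg$site_corr < 0 || cfg$site_corr > 1) stop("site_corr must be in [0, 1]")
  if (cfg$site_sd < 0) stop("site_sd must be non-negative")
  if (cfg$delta_sd < 0) stop("delta_sd must be non-negative")
  if (cfg$baseline_das28_sd <= 0) stop("baseline_das28_sd must be positive")
  if (diff(cfg$baseline_das28_range) <= 0) stop("invalid baseline_das28_range")
  for (nm in c("neut", "lymph", "mono", "plt", "pct")) {
    h <- cfg$hematology[[nm]]
    if (is.null(h) || length(h) != 2 || h[2] < 0)
      stop("hematology$", nm, " must be c(meanlog, sdlog) with sdlog >= 0")
  }
  if (cfg$prop_female < 0 || cfg$prop_female > 1) stop("prop_female must be in [0, 1]")
  invisible(cfg)
}

# cache for beta-parameter root finds keyed by the three quantile targets
.beta_param_cache <- new.env(parent = emptyenv())

#' Beta distribution parameters matching a median and IQR
#'
#' Numerically inverts the Beta quantile function so that the 25th, 50th
#' and 75th percentiles match the given targets; used to turn the printed
#' per-genotype median/IQR summaries into sampling distributions.
#'
#' @param median,q25,q75 Target quantiles with 0 < q25 < median < q75 < 1.
#' @param tol Maximum absolute quantile error regarded as an exact match.
#' @return A list with `alpha`, `beta`, `residual` (root-mean-square
#'   quantile error) and `achieved` (the fitted quantiles). When the three
#'   targets are not exactly attainable, the least-squares compromise is
#'   returned with its residual.
#' @examples
#' beta_params_from_median_iqr(0.229, 0.195, 0.287)
#' @export
beta_params_from_median_iqr <- function(median, q25, q75, tol = 1e-4) {
  if (!(0 < q25 && q25 < median && median < q75 && q75 < 1))
    stop("need 0 < q25 < median < q75 < 1")
  key <- paste(format(c(q25, median, q75), digits = 12), collapse = "|")
  if (!is.null(.beta_param_cache[[key]])) return(.beta_param_cache[[key]])

  targets <- c(q25, median, q75)
  # moment-based start: mean ~ median, sd ~ IQR/1.349
  m <- median; v <- ((q75 - q25) / 1.349)^2
  k <- max(m * (1 - m) / v - 1, 0.5)
  obj <- function(lp) {
    q <- stats::qbeta(c(0.25, 0.5, 0.75), exp(lp[1]), exp(lp[2]))
    sum((q - targets)^2)
  }
  starts <- list(log(c(m * k, (1 - m) * k)),
                 log(c(m * k, (1 - m) * k)) + c(1, 1),
                 log(c(m * k, (1 - m) * k)) - c(1, 1),
                 c(0, 0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, obj, control = list(iter.max = 5000,
                                           abs.tol = 1e-20, rel.tol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    stop("beta parameter search failed to converge from all starts; ",
         "targets: ", paste(format(targets), collapse = ", "))
  ab <- exp(best$par)
  achieved <- stats::qbeta(c(0.25, 0.5, 0.75), ab[1], ab[2])
  res <- list(alpha = ab[1], beta = ab[2],
              residual = sqrt(mean((achieved - targets)^2)),
              achieved = achieved, exact = max(abs(achieved - targets)) < tol)
  .beta_param_cache[[key]] <- res
  res
}
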