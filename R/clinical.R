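#' Disease Activity Score over 28 joints (4-variable, ESR form)
#'
#' \deqn{DAS28 = 0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.70\ln(ESR) + 0.014\,VAS}
#'
#' @param tjc28 Tender joint count, integer 0-28.
#' @param sjc28 Swollen joint count, integer 0-28.
#' @param esr Erythrocyte sedimentation rate in mm/h, strictly positive.
#' @param vas Patient pain visual analogue scale in mm, 0-100.
#' @return Numeric DAS28 score(s); all arguments are vectorised.
#' @examples
#' das28(4, 4, 20, 50)
#' @export
das28 <- function(tjc28, sjc28, esr, vas) {
  if (any(!is.finite(tjc28)) || any(tjc28 < 0) || any(tjc28 > 28))
    stop("tjc28 must be in [0, 28]")
  if (any(!is.finite(sjc28)) || any(sjc28 < 0) || any(sjc28 > 28))
    stop("sjc28 must be in [0, 28]")
  if (any(!is.finite(esr)) || any(esr <= 0))
    stop("esr must be strictly positive (its logarithm is taken)")
  if (any(!is.finite(vas)) || any(vas < 0) || any(vas > 100))
    stop("vas must be in [0, 100] mm")
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.70 * log(esr) + 0.014 * vas
}

#' EULAR response classification after 6 months of treatment
#'
#' Classifies each patient from baseline and month-6 DAS28 into good,
#' moderate, or no response, and consolidates good + moderate into the
#' binary "responder" flag used as the analysis outcome.
#'
#' Good response requires an improvement \eqn{\Delta DAS28 > 1.2} with a
#' final score of at most 3.2. Non-response is an improvement of at most
#' 0.6, or an improvement in (0.6, 1.2] with a final score above 5.1.
#' Everything in between is a moderate response. The boundary
#' \eqn{\Delta = 0.6} is non-response regardless of the endpoint.
#'
#' @param das28_baseline,das28_month6 Numeric DAS28 scores (vectorised).
#' @return A data frame with `das28_baseline`, `das28_month6`,
#'   `delta_das28` (baseline minus month 6), `category` (factor
#'   good/moderate/none) and `responder` (integer 0/1).
#' @examples
#' classify_response(5.0, 3.0)  # good
#' classify_response(6.5, 5.4)  # delta 1.1 but endpoint > 5.1: none
#' @export
classify_response <- function(das28_baseline, das28_month6) {
  if (any(!is.finite(das28_baseline)) || any(!is.finite(das28_month6)))
    stop("DAS28 scores must be finite")
  delta <- das28_baseline - das28_month6
  final <- das28_month6
  good <- delta > 1.2 & final <= 3.2
  none <- delta <= 0.6 | (delta > 0.6 & delta <= 1.2 & final > 5.1)
  category <- ifelse(good, "good", ifelse(none, "none", "moderate"))
  category <- factor(category, levels = c("good", "moderate", "none"))
  data.frame(
    das28_baseline = das28_baseline, das28_month6 = das28_month6,
    delta_das28 = delta, category = category,
    responder = as.integer(category != "none")
  )
}

#' Blood-count inflammation indices
#'
#' Computes the four composite indices used as candidate prognostic
#' covariates: NLR = neut/lymph, PLR = plt/lymph,
#' SII = neut * plt / lymph, SIRI = neut * mono / lymph.
#'
#' @param neut,lymph,mono,plt Cell counts in 10^9/L, strictly positive
#'   (vectorised).
#' @return A data frame with columns `nlr`, `plr`, `sii`, `siri`.
#' @examples
#' inflammation_indices(4, 2, 0.5, 300)
#' @export
inflammation_indices <- function(neut, lymph, mono, plt) {
  vals <- cbind(neut, lymph, mono, plt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all blood counts must be strictly positive")
  data.frame(
    nlr = neut / lymph,
    plr = plt / lymph,
    sii = neut * plt / lymph,
    siri = neut * mono / lymph
  )
}
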