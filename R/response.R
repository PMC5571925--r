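#' PERCIST-style metabolic response classification
#'
#' Classifies the change in body-weight SUVpeak between baseline and
#' post-chemotherapy studies into the four PERCIST categories, with
#' precedence PMD > CMR > PMR > SMD:
#' * PMD (progressive metabolic disease): a new lesion, or an increase of at
#'   least 30\% and at least 0.8 SUV;
#' * CMR (complete metabolic response): post SUVpeak at or below the
#'   background reference;
#' * PMR (partial metabolic response): a decrease of at least 30\% and at
#'   least 0.8 SUV;
#' * SMD (stable metabolic disease): anything else.
#'
#' @param suvpeak_pre baseline SUVpeak, > 0 (vectorized).
#' @param suvpeak_post post-therapy SUVpeak (vectorized).
#' @param background_ref background reference SUV.
#' @param new_lesion logical; any unequivocal new lesion forces PMD.
#' @return Character vector with values in `c("PMD", "CMR", "PMR", "SMD")`.
#' @examples
#' percist_classify(5, 3, 1.5)   # 40% and 2.0 SUV decrease -> PMR
#' percist_classify(5, 1.2, 1.5) # at/below background -> CMR
#' @export
percist_classify <- function(suvpeak_pre, suvpeak_post, background_ref,
                             new_lesion = FALSE) {
  n <- max(length(suvpeak_pre), length(suvpeak_post))
  pre <- rep_len(suvpeak_pre, n)
  post <- rep_len(suvpeak_post, n)
  bg <- rep_len(background_ref, n)
  nl <- rep_len(new_lesion, n)
  if (any(pre <= 0)) stopf("baseline SUVpeak must be > 0")
  change <- post - pre
  pct <- 100 * change / pre
  out <- rep("SMD", n)
  out[pct <= -30 & change <= -0.8] <- "PMR"
  out[post <= bg] <- "CMR"
  out[nl | (pct >= 30 & change >= 0.8)] <- "PMD"
  out
}

#' Histologic response dichotomy from the Salzer-Kuntschik grade
#'
#' Grades I--III (under 10\% viable tumor cells in the resected specimen)
#' define responders; grades IV--VI define non-responders.
#'
#' @param grade integer Salzer-Kuntschik regression grade in 1..6
#'   (vectorized).
#' @return Character vector, `"responder"` or `"non_responder"`.
#' @export
histologic_responder <- function(grade) {
  grade <- as.integer(grade)
  if (any(is.na(grade)) || any(grade < 1L) || any(grade > 6L)) {
    stopf("Salzer-Kuntschik grade must be an integer in 1..6")
  }
  ifelse(grade <= 3L, "responder", "non_responder")
}
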