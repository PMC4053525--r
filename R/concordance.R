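#' Harrell's c-index for censored survival data
#'
#' The proportion of all comparable patient pairs in which predictions
#' and outcomes are concordant. A pair is comparable when the ordering of
#' the two event times is determinable under censoring: the member with
#' the shorter follow-up experienced the event (pairs whose shorter
#' follow-up is censored are incomparable; two events at the same time
#' are incomparable; equal times with exactly one event are comparable,
#' the event-bearer treated as earlier). A comparable pair is concordant
#' when the subject with the earlier event carries the higher risk score;
#' pairs tied on the score count one half. A value of 0.5 is the
#' concordance expected by chance and 1 is perfect concordance.
#'
#' The 95% confidence interval uses the large-sample normal variance of
#' the concordance proportion over pairs
#' (`c (1 - c) / n_comparable_pairs`).
#'
#' @param times Follow-up times (months).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param scores Risk scores; higher score = higher risk = predicted
#'   earlier event. The prognostic index is the natural choice.
#' @return A one-row tibble: `c`, `conf.low`, `conf.high`,
#'   `n_pairs` (comparable), `n_concordant`, `n_tied` (score ties).
#' @export
harrell_c <- function(times, events, scores) {
  n <- length(times)
  if (length(events) != n || length(scores) != n) {
    abort("times, events and scores must have equal length")
  }
  keep <- !(is.na(times) | is.na(events) | is.na(scores))
  times <- times[keep]; events <- events[keep]; scores <- scores[keep]
  if (sum(events) < 1) abort("need at least one event")
  conc <- tied <- pairs <- 0
  idx_event <- which(events == 1)
  for (i in idx_event) {
    # pairs where subject i is the determinably earlier event:
    # longer follow-up, or equal follow-up without an event
    later <- times > times[i] | (times == times[i] & events == 0)
    later[i] <- FALSE
    # avoid double counting event-event pairs (each counted once,
    # from the earlier member)
    np <- sum(later)
    if (np == 0) next
    pairs <- pairs + np
    conc <- conc + sum(scores[i] > scores[later])
    tied <- tied + sum(scores[i] == scores[later])
  }
  if (pairs == 0) abort("no comparable pairs")
  cstat <- (conc + 0.5 * tied) / pairs
  se <- sqrt(cstat * (1 - cstat) / pairs)
  tibble::tibble(
    c = cstat,
    conf.low = max(0, cstat - qnorm(0.975) * se),
    conf.high = min(1, cstat + qnorm(0.975) * se),
    n_pairs = pairs, n_concordant = conc, n_tied = tied
  )
}

#' Concordance difference between development and validation
#'
#' External validity is assessed informally from the difference in
#' c-index between the development fit and each validation cohort; a
#' difference whose magnitude is at most `tol` (0.05 by default) is read
#' as the model generalising.
#'
#' @param c_dev,c_val Results from [harrell_c()] (or any one-row data
#'   frame with a `c` column).
#' @param tol Acceptable magnitude of the difference.
#' @return A one-row tibble: `delta` (validation minus development,
#'   signed, rounded to 2 decimals), `generalises`.
#' @export
concordance_difference <- function(c_dev, c_val, tol = 0.05) {
  delta <- round(c_val$c - c_dev$c, 2)
  tibble::tibble(delta = delta, generalises = abs(delta) <= tol)
}
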