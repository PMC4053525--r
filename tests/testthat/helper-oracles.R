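# Independent oracles used across the suite. These deliberately use
# naive enumeration / textbook formulas, not the package's code paths.

# Exhaustive-pair concordance: loop over all unordered pairs, apply the
# comparability rules directly.
oracle_concordance <- function(times, events, scores) {
  n <- length(times)
  conc <- tied <- pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- times[i]; tj <- times[j]
      ei <- events[i]; ej <- events[j]
      if (ti == tj) {
        if (ei + ej != 1) next           # both events or both censored
        early <- if (ei == 1) i else j   # event-bearer treated earlier
        late <- if (ei == 1) j else i
      } else {
        early <- if (ti < tj) i else j
        late <- if (ti < tj) j else i
        if (events[early] != 1) next     # shorter follow-up censored
      }
      pairs <- pairs + 1
      if (scores[early] > scores[late]) {
        conc <- conc + 1
      } else if (scores[early] == scores[late]) {
        tied <- tied + 1
      }
    }
  }
  if (pairs == 0) return(NULL)
  list(c = (conc + 0.5 * tied) / pairs, pairs = pairs, conc = conc,
       tied = tied)
}

# Newton-Raphson solution of the untied two-group Cox partial-likelihood
# score equation, from the definition.
oracle_cox_beta <- function(times, events, x, tol = 1e-12) {
  b <- 0
  for (iter in 1:100) {
    U <- 0; I <- 0
    for (i in which(events == 1)) {
      at_risk <- times >= times[i]
      w <- exp(b * x[at_risk])
      s0 <- sum(w)
      s1 <- sum(x[at_risk] * w)
      s2 <- sum(x[at_risk]^2 * w)
      U <- U + x[i] - s1 / s0
      I <- I + s2 / s0 - (s1 / s0)^2
    }
    step <- U / I
    b <- b + step
    if (abs(step) < tol) break
  }
  b
}

# small random censored instance with ties, guaranteed to have at least
# one comparable pair
random_small_instance <- function(n_max = 8) {
  repeat {
    n <- sample(2:n_max, 1)
    times <- sample(1:5, n, replace = TRUE)
    events <- rbinom(n, 1, 0.6)
    scores <- sample(1:4, n, replace = TRUE)
    orc <- oracle_concordance(times, events, scores)
    if (!is.null(orc)) {
      return(list(times = times, events = events, scores = scores,
                  oracle = orc))
    }
  }
}

# tiny hand-checkable cohort builder
mini_cohort <- function(time, event, age = 30, study = "X", ...) {
  n <- length(time)
  extra <- list(...)
  base <- tibble::tibble(
    subject_id = sprintf("m%03d", seq_len(n)),
    study = study,
    age_at_first_seizure = rep_len(age, n),
    sex = "male",
    aetiology = "not_remote_symptomatic",
    fdr_epilepsy = "no",
    sleep_only = "no",
    eeg = "normal",
    imaging = "normal",
    treatment = "delayed",
    time = time,
    event = event
  )
  for (nm in names(extra)) base[[nm]] <- rep_len(extra[[nm]], n)
  validate_cohort(base)
}
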