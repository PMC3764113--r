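#' Synthetic cohorts with known memory structure
#'
#' Three generator families provide ground truth for every stage of the
#' pipeline without patient data. All of them draw an increment process and
#' integrate it (profile = cumulative sum), mirroring how the analysis treats
#' real data: the profile is left on its natural scale and passed through
#' [normalize_sigma()] like a recording, so rho-in-sigma semantics are
#' identical for real and synthetic series. Each subject uses a deterministic
#' substream of `seed`; identical `(parameters, seed)` reproduce the cohort
#' bit for bit.
#'
#' * `gen_random_walk()`: i.i.d. standard-normal increments -- the memoryless
#'   null, distributionally indistinguishable from its own increment shuffle.
#' * `gen_ar_increments()`: increments follow an order-`p` linear
#'   autoregression with unit-variance innovations, so exactly `p` previous
#'   increments shape the present one. A burn-in of `10 * p` steps is
#'   discarded. With `order_p = 0` this is the random walk, bit for bit.
#' * `gen_clustered_events()`: a two-regime increment process emulating the
#'   pathological signature in which a rare event tends to be followed by
#'   further similar rare events. Baseline increments are i.i.d. standard
#'   normal; each step triggers, with probability `event_rate`, an event
#'   regime lasting `event_length` steps during which the increment mean is
#'   shifted by `event_shift` (negative shift: clustered accelerating events).
#'   Retriggering during an event resets the remaining length.
#'
#' @param n series length (>= 10).
#' @param n_subjects number of subjects in the cohort.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param group group label attached to every subject (also the subject-id
#'   prefix).
#' @param order_p autoregression order (>= 0).
#' @param coefficients numeric vector of `order_p` AR coefficients; the
#'   recursion must be stationary (all characteristic roots outside the unit
#'   circle).
#' @param event_rate per-step probability of (re)triggering an event regime,
#'   in `[0, 1]`.
#' @param event_length event regime duration in steps (>= 1).
#' @param event_shift increment mean shift during events, in units of the
#'   baseline increment standard deviation (which is 1).
#' @return a list of `n_subjects` [interval_series()] objects
#'   (`modality = "synthetic"`).
#' @examples
#' cohort <- gen_random_walk(n = 100, n_subjects = 2, seed = 7)
#' identical(cohort, gen_random_walk(n = 100, n_subjects = 2, seed = 7))
#' @name synthetic_cohorts
NULL

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 10)
    stop("`n` must be a single number >= 10", call. = FALSE)
  as.integer(n)
}

make_cohort <- function(n_subjects, group, gen1) {
  lapply(seq_len(n_subjects), function(j) {
    interval_series(gen1(j),
                    subject_id = sprintf("%s_s%02d", group, j),
                    group = group, modality = "synthetic")
  })
}

#' @rdname synthetic_cohorts
#' @export
gen_random_walk <- function(n, n_subjects = 1L, seed = 1L, group = "rw") {
  n <- check_n(n)
  make_cohort(n_subjects, group, function(j) {
    cumsum(with_seed(sub_seed(seed, j), rnorm(n)))
  })
}

#' @rdname synthetic_cohorts
#' @export
gen_ar_increments <- function(order_p, coefficients, n, n_subjects = 1L,
                              seed = 1L, group = "ar") {
  n <- check_n(n)
  order_p <- as.integer(order_p)
  if (order_p < 0L) stop("`order_p` must be >= 0", call. = FALSE)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != order_p)
    stop(sprintf("`coefficients` must have length order_p = %d, got %d",
                 order_p, length(coefficients)), call. = FALSE)
  if (order_p > 0L) {
    roots <- polyroot(c(1, -coefficients))
    bad <- Mod(roots) <= 1 + 1e-10
    if (any(bad))
      stop(sprintf("non-stationary AR coefficients: characteristic root modulus %.6g <= 1",
                   min(Mod(roots)[bad])), call. = FALSE)
  }
  burn <- 10L * order_p
  make_cohort(n_subjects, group, function(j) {
    e <- with_seed(sub_seed(seed, j), rnorm(n + burn))
    incr <- if (order_p == 0L) e
            else as.numeric(stats::filter(e, coefficients, method = "recursive"))
    cumsum(incr[(burn + 1L):(burn + n)])
  })
}

#' @rdname synthetic_cohorts
#' @export
gen_clustered_events <- function(event_rate, event_length, event_shift, n,
                                 n_subjects = 1L, seed = 1L, group = "ce") {
  n <- check_n(n)
  if (!is.numeric(event_rate) || event_rate < 0 || event_rate > 1)
    stop("`event_rate` must be a probability in [0, 1]", call. = FALSE)
  event_length <- as.integer(event_length)
  if (is.na(event_length) || event_length < 1L)
    stop("`event_length` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(event_shift) || length(event_shift) != 1L ||
      !is.finite(event_shift))
    stop("`event_shift` must be a single finite number", call. = FALSE)
  make_cohort(n_subjects, group, function(j) {
    draws <- with_seed(sub_seed(seed, j),
                       list(base = rnorm(n), u = runif(n)))
    trig <- draws$u < event_rate
    ev <- logical(n)
    rem <- 0L
    for (t in seq_len(n)) {
      if (trig[t]) rem <- event_length
      if (rem > 0L) {
        ev[t] <- TRUE
        rem <- rem - 1L
      }
    }
    cumsum(draws$base + event_shift * ev)
  })
}
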