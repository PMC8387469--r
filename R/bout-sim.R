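#' Parameters for the bouted lever-press generator
#'
#' Describes a press stream with the bimodal inter-response-interval (IRI)
#' structure characteristic of operant responding: clusters ("bouts") of
#' presses separated by short within-bout gaps, interleaved with isolated
#' ("solitary") presses.  Bout onsets and solitary presses arise from
#' independent homogeneous Poisson processes; within-bout IRIs are drawn from
#' an exponential truncated to `(0, gap_threshold)` so that every within-bout
#' gap is below the partition threshold.  Between-event spacing (bout to bout,
#' bout to solitary, solitary to solitary) is enforced to be at least
#' `4 * gap_threshold`, which makes the generated labels the unique
#' gap-threshold partition of the stream and lets recovery tests demand exact
#' equality rather than statistical agreement.
#'
#' @param bout_rate bouts per minute (Poisson rate of bout onsets).
#' @param presses_per_bout_mean mean presses per bout; must be >= 2 since a
#'   bout is by definition a run of at least two presses.  Sizes are drawn as
#'   `2 + rpois(presses_per_bout_mean - 2)`.
#' @param within_bout_iri_mean scale (seconds) of the exponential from which
#'   within-bout IRIs are drawn before truncation at `gap_threshold`; must be
#'   positive and less than `gap_threshold`.
#' @param solitary_rate solitary presses per minute.
#' @param duration session length in seconds.
#' @param gap_threshold the bout-partition gap threshold the stream is built
#'   around (seconds, default 5).
#' @param seed optional integer seed.
#' @return an object of class `bout_process_params`.
#' @seealso [simulate_bout_process()], [partition_bouts()]
#' @export
bout_process_params <- function(bout_rate, presses_per_bout_mean = 4,
                                within_bout_iri_mean = 1, solitary_rate = 0,
                                duration = 3600, gap_threshold = 5,
                                seed = NULL) {
  stop_if_not_scalar_pos(bout_rate, "bout_rate", allow_zero = TRUE)
  stop_if_not_scalar_pos(solitary_rate, "solitary_rate", allow_zero = TRUE)
  stop_if_not_scalar_pos(within_bout_iri_mean, "within_bout_iri_mean")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(gap_threshold, "gap_threshold")
  if (presses_per_bout_mean < 2)
    stop("`presses_per_bout_mean` must be >= 2 (a bout has at least two presses)",
         call. = FALSE)
  if (within_bout_iri_mean >= gap_threshold)
    stop("`within_bout_iri_mean` must be below `gap_threshold`; otherwise the ",
         "ground-truth bout labels would not be the gap-threshold partition",
         call. = FALSE)
  structure(list(bout_rate = bout_rate,
                 presses_per_bout_mean = presses_per_bout_mean,
                 within_bout_iri_mean = within_bout_iri_mean,
                 solitary_rate = solitary_rate,
                 duration = duration,
                 gap_threshold = gap_threshold,
                 seed = seed),
            class = "bout_process_params")
}

# Truncated exponential on (0, upper) with pre-truncation scale `mean`.
rtexp <- function(n, mean, upper) {
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-upper / mean)))
}

#' Simulate a bouted press stream with ground-truth labels
#'
#' Draws bout onsets from a Poisson process, fills each bout with presses
#' whose gaps are below the bout threshold, and adds solitary presses from an
#' independent Poisson process.  Bouts that would overlap a previous bout
#' (closer than `4 * gap_threshold`) or run past the session end are dropped;
#' solitary presses landing within `4 * gap_threshold` of any accepted press
#' are rejected.  The result is a stream whose unique gap-threshold partition
#' equals the returned labels.
#'
#' @param params a [bout_process_params()] object.
#' @return a list with elements `times` (sorted press times, seconds),
#'   `labels` (integer per press: bout index, or 0 for solitary), `bouts`
#'   (list of per-bout press-time vectors), `solitary` (vector of solitary
#'   press times), and `params`.
#' @export
simulate_bout_process <- function(params) {
  stopifnot(inherits(params, "bout_process_params"))
  with_seed(params$seed, {
    thr <- params$gap_threshold
    guard <- 4 * thr
    dur <- params$duration

    bouts <- list()
    if (params$bout_rate > 0) {
      n_cand <- stats::rpois(1L, params$bout_rate / 60 * dur)
      onsets <- sort(stats::runif(n_cand, 0, dur))
      last_end <- -Inf
      for (on in onsets) {
        if (on < last_end + guard) next
        size <- 2L + stats::rpois(1L, params$presses_per_bout_mean - 2)
        gaps <- rtexp(size - 1L, params$within_bout_iri_mean, thr)
        press <- on + c(0, cumsum(gaps))
        if (press[length(press)] > dur) next
        bouts[[length(bouts) + 1L]] <- press
        last_end <- press[length(press)]
      }
    }

    solitary <- numeric(0)
    if (params$solitary_rate > 0) {
      n_cand <- stats::rpois(1L, params$solitary_rate / 60 * dur)
      cand <- sort(stats::runif(n_cand, 0, dur))
      anchors <- unlist(bouts, use.names = FALSE)
      for (s in cand) {
        if (length(anchors) && min(abs(anchors - s)) < guard) next
        if (length(solitary) && min(abs(solitary - s)) < guard) next
        solitary <- c(solitary, s)
      }
    }

    times <- c(unlist(bouts, use.names = FALSE), solitary)
    labels <- c(rep.int(seq_along(bouts), vapply(bouts, length, 1L)),
                rep.int(0L, length(solitary)))
    ord <- order(times)
    times <- times[ord]
    labels <- labels[ord]
    # relabel bouts in temporal order of first press
    if (length(bouts)) {
      first <- vapply(bouts, function(b) b[1L], 1)
      rk <- rank(first)
      labels[labels > 0L] <- rk[labels[labels > 0L]]
      bouts <- bouts[order(first)]
    }
    list(times = times, labels = as.integer(labels), bouts = bouts,
         solitary = sort(solitary), params = params)
  })
}
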