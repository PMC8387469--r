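#' Configuration of the response-bout analysis
#'
#' Operant lever pressing is partitioned into "bouts" — runs of presses whose
#' successive inter-response intervals (IRIs) are all below a gap threshold —
#' and "solitary" presses (runs of length one).  The 5-s threshold follows
#' from the observation that the conditional probability of a further press is
#' maximal in the first 5-s epoch after a press (see
#' [epoch_response_probabilities()]).
#'
#' @param epoch_width width of the IRI epochs, seconds (default 5).
#' @param gap_threshold gap at or above which a run is split, seconds
#'   (default 5).  Presses strictly less than `gap_threshold` apart share a
#'   run; a gap exactly equal to the threshold splits.
#' @param min_bout_size minimum run length to count as a bout (default 2).
#' @return an object of class `bout_config`.
#' @export
bout_config <- function(epoch_width = 5, gap_threshold = 5, min_bout_size = 2) {
  stop_if_not_scalar_pos(epoch_width, "epoch_width")
  stop_if_not_scalar_pos(gap_threshold, "gap_threshold")
  if (min_bout_size < 2 || min_bout_size != round(min_bout_size))
    stop("`min_bout_size` must be a whole number >= 2", call. = FALSE)
  structure(list(epoch_width = epoch_width, gap_threshold = gap_threshold,
                 min_bout_size = as.integer(min_bout_size)),
            class = "bout_config")
}

#' Inter-response intervals
#'
#' @param times press timestamps, sorted ascending (seconds).
#' @return numeric vector of the n-1 successive differences; empty for n <= 1.
#' @export
inter_response_intervals <- function(times) {
  if (!is.numeric(times)) stop("`times` must be numeric", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted ascending", call. = FALSE)
  if (length(times) <= 1L) return(numeric(0))
  diff(times)
}

#' Per-epoch response probabilities (discrete IRI hazard)
#'
#' For epoch k (half-open interval `[k*w, (k+1)*w)`, `w = epoch_width`), the
#' probability that the next press falls in that epoch given that it has not
#' yet occurred:
#' \deqn{P_k = |\{IRI \in [kw, (k+1)w)\}| / |\{IRI \ge kw\}|}
#' i.e. presses occurring within epoch k after the preceding press, divided by
#' all intervals of at least `k*w` seconds.  This is the discrete hazard of
#' the IRI distribution; for memoryless (exponential) IRIs it is flat across
#' epochs at `1 - exp(-lambda*w)`.  Epochs are reported up to the one
#' containing the largest IRI (the last epoch's probability is therefore
#' always 1).
#'
#' @param iris non-empty numeric vector of IRIs (seconds, >= 0).
#' @param cfg a [bout_config()].
#' @return numeric vector of per-epoch probabilities, named by epoch interval.
#' @export
epoch_response_probabilities <- function(iris, cfg = bout_config()) {
  stopifnot(inherits(cfg, "bout_config"))
  if (length(iris) == 0L) stop("no intervals: need at least two presses", call. = FALSE)
  if (any(iris < 0)) stop("IRIs must be non-negative", call. = FALSE)
  w <- cfg$epoch_width
  kmax <- floor(max(iris) / w)
  p <- vapply(0:kmax, function(k) {
    at_risk <- sum(iris >= k * w)
    sum(iris >= k * w & iris < (k + 1) * w) / at_risk
  }, 1)
  names(p) <- sprintf("[%g,%g)", (0:kmax) * w, (1:(kmax + 1)) * w)
  p
}

#' Partition a press stream into bouts and solitary presses
#'
#' Splits the sorted press sequence at every gap greater than or equal to
#' `gap_threshold`; runs of at least `min_bout_size` presses are bouts, runs
#' of one press are solitary.  Deterministic.
#'
#' @param times press timestamps, sorted ascending (seconds).
#' @param cfg a [bout_config()].
#' @return an object of class `bout_partition`: list with `bouts` (list of
#'   press-time vectors) and `solitary` (vector of press times).
#' @export
partition_bouts <- function(times, cfg = bout_config()) {
  stopifnot(inherits(cfg, "bout_config"))
  if (!is.numeric(times)) stop("`times` must be numeric", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted ascending", call. = FALSE)
  if (length(times) == 0L)
    return(structure(list(bouts = list(), solitary = numeric(0)),
                     class = "bout_partition"))
  run_id <- cumsum(c(1, as.integer(diff(times) >= cfg$gap_threshold)))
  runs <- split(times, run_id)
  sizes <- lengths(runs)
  structure(list(bouts = unname(runs[sizes >= cfg$min_bout_size]),
                 solitary = unname(unlist(runs[sizes < cfg$min_bout_size],
                                          use.names = FALSE)) %||% numeric(0)),
            class = "bout_partition")
}

#' @export
print.bout_partition <- function(x, ...) {
  cat(sprintf("<bout_partition> %d bouts (%d presses), %d solitary\n",
              length(x$bouts), sum(lengths(x$bouts)), length(x$solitary)))
  invisible(x)
}

#' Per-session bout microstructure summary
#'
#' Computes the microstructure metrics carried by the bout analysis: bout
#' frequency (number of bouts), bout density (mean presses per bout; `NA`
#' when there are no bouts — explicitly undefined, not zero), number of
#' solitary presses, total presses, magazine-entry count, and the per-epoch
#' response probabilities of the full press sequence.
#'
#' @param partition a [partition_bouts()] result.
#' @param magazine_times magazine-entry timestamps (seconds), may be empty.
#' @param cfg a [bout_config()].
#' @param density one of `"mean"` (default; mean presses per bout) or
#'   `"median"`.
#' @return an object of class `bout_summary`: list with fields `n_presses`,
#'   `bout_frequency`, `bout_density`, `n_solitary`, `n_magazine`,
#'   `epoch_probabilities`.
#' @export
bout_summary <- function(partition, magazine_times = numeric(0),
                         cfg = bout_config(), density = c("mean", "median")) {
  stopifnot(inherits(partition, "bout_partition"))
  density <- match.arg(density)
  sizes <- lengths(partition$bouts)
  n_bout_presses <- sum(sizes)
  n_solitary <- length(partition$solitary)
  all_times <- sort(c(unlist(partition$bouts, use.names = FALSE),
                      partition$solitary))
  iris <- inter_response_intervals(all_times)
  eps <- if (length(iris)) epoch_response_probabilities(iris, cfg) else numeric(0)
  structure(list(
    n_presses = n_bout_presses + n_solitary,
    bout_frequency = length(sizes),
    bout_density = if (length(sizes) == 0L) NA_real_
                   else if (density == "mean") mean(sizes) else stats::median(sizes),
    n_solitary = n_solitary,
    n_magazine = length(magazine_times),
    epoch_probabilities = eps
  ), class = "bout_summary")
}

#' @export
print.bout_summary <- function(x, ...) {
  cat(sprintf(paste0("<bout_summary> presses=%d bouts=%d density=%s ",
                     "solitary=%d magazine=%d\n"),
              x$n_presses, x$bout_frequency,
              if (is.na(x$bout_density)) "undefined" else
                formatC(x$bout_density, digits = 3, format = "fg"),
              x$n_solitary, x$n_magazine))
  invisible(x)
}

#' Summarize one session's event stream
#'
#' Convenience wrapper: partitions the stream's presses and summarizes them
#' together with its magazine entries.
#'
#' @param stream an `event_stream` from [simulate_operant_session()] or
#'   [read_event_log()].
#' @param cfg a [bout_config()].
#' @inheritParams bout_summary
#' @return a `bout_summary`.
#' @export
summarize_session <- function(stream, cfg = bout_config(),
                              density = c("mean", "median")) {
  bout_summary(partition_bouts(press_times(stream), cfg),
               magazine_times(stream), cfg, density = density)
}

#' Correlate bout metrics with magazine entries across animals
#'
#' Pearson correlation (with two-sided p-value) of bout frequency, bout
#' density and solitary-press count against magazine-entry count across
#' animals.  A metric with zero variance in either member of the pair yields
#' an undefined correlation, reported as `NA` with an explanatory flag.
#'
#' @param summaries list of [bout_summary()] objects, one per animal (>= 3).
#' @return data.frame with columns `metric`, `r`, `p`, `n`, `defined`.
#' @export
correlate_bout_magazine <- function(summaries) {
  if (length(summaries) < 3L) stop("need summaries from at least 3 animals", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, TRUE, "bout_summary")))
  mag <- vapply(summaries, `[[`, 1, "n_magazine")
  metrics <- list(bout_frequency = vapply(summaries, `[[`, 1, "bout_frequency"),
                  bout_density = vapply(summaries, `[[`, 1, "bout_density"),
                  n_solitary = vapply(summaries, `[[`, 1, "n_solitary"))
  rows <- lapply(names(metrics), function(m) {
    x <- metrics[[m]]
    ok <- stats::complete.cases(x, mag)
    x <- x[ok]; y <- mag[ok]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.frame(metric = m, r = NA_real_, p = NA_real_, n = length(x),
                 defined = FALSE)
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), defined = TRUE)
    }
  })
  do.call(rbind, rows)
}
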