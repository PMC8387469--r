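#' Parameters for synthetic fluorescence traces
#'
#' Describes per-ROI miniscope traces: a constant baseline, additive white
#' Gaussian noise, and calcium transients planted at Poisson-distributed
#' times.  Each transient follows a difference-of-exponentials kernel
#' `exp(-t/decay_tau) - exp(-t/rise_tau)` normalized to unit peak, scaled so
#' its peak equals `transient_amplitude * noise_sd` raw fluorescence units
#' (i.e. amplitude is expressed in multiples of the noise SD, the scale the
#' event-detection threshold works on).
#'
#' The number of planted events per ROI is drawn Poisson with mean
#' `event_rate * duration / 60`, then event times are placed by sequential
#' inhibition with a minimum gap of `min_event_gap` seconds.  Without a
#' minimum gap, two transients closer than any detector's peak-separation
#' window are indistinguishable from one, and "recovery of the planted rate"
#' would be ill-defined; the gap plays the same role as the spacing guard in
#' [bout_process_params()].
#'
#' @param sampling_rate frames per second (default 15).
#' @param duration recording length, seconds (default 900, i.e. 15 min).
#' @param event_rate planted transients per minute per ROI.
#' @param transient_amplitude transient peak in multiples of `noise_sd`.
#' @param rise_tau,decay_tau kernel time constants, seconds
#'   (`decay_tau > rise_tau > 0`).
#' @param baseline_level baseline fluorescence (arbitrary units, > 0).
#' @param noise_sd white-noise SD, same units (>= 0).
#' @param n_rois number of independent ROIs.
#' @param min_event_gap minimum spacing between planted events, seconds.
#' @param seed optional integer seed.
#' @return an object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(sampling_rate = 15, duration = 900,
                               event_rate = 4, transient_amplitude = 5,
                               rise_tau = 0.2, decay_tau = 1.0,
                               baseline_level = 100, noise_sd = 5,
                               n_rois = 1, min_event_gap = 2, seed = NULL) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(event_rate, "event_rate", allow_zero = TRUE)
  stop_if_not_scalar_pos(transient_amplitude, "transient_amplitude", allow_zero = TRUE)
  stop_if_not_scalar_pos(rise_tau, "rise_tau")
  stop_if_not_scalar_pos(baseline_level, "baseline_level")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  stop_if_not_scalar_pos(min_event_gap, "min_event_gap", allow_zero = TRUE)
  if (decay_tau <= rise_tau)
    stop("`decay_tau` must exceed `rise_tau`", call. = FALSE)
  if (n_rois < 1 || n_rois != round(n_rois))
    stop("`n_rois` must be a whole number >= 1", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 event_rate = event_rate,
                 transient_amplitude = transient_amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 n_rois = as.integer(n_rois), min_event_gap = min_event_gap,
                 seed = seed),
            class = "calcium_sim_params")
}

#' Difference-of-exponentials calcium kernel, unit peak
#'
#' `k(t) = (exp(-t/decay) - exp(-t/rise)) / k_max` for `t >= 0`, 0 before.
#'
#' @param t times (seconds).
#' @param rise_tau,decay_tau time constants (seconds).
#' @return kernel values.
#' @export
calcium_kernel <- function(t, rise_tau = 0.2, decay_tau = 1.0) {
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  peak <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  ifelse(t < 0, 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak)
}

# Place n points in [0, duration] with pairwise gaps >= min_gap by sequential
# inhibition; returns as many as could be placed (up to n).
place_inhibited <- function(n, duration, min_gap, max_tries = 200L) {
  pts <- numeric(0)
  for (i in seq_len(n)) {
    for (tr in seq_len(max_tries)) {
      cand <- stats::runif(1L, 0, duration)
      if (!length(pts) || min(abs(pts - cand)) >= min_gap) {
        pts <- c(pts, cand)
        break
      }
    }
  }
  sort(pts)
}

#' Simulate fluorescence traces with planted calcium transients
#'
#' @param params a [calcium_sim_params()] object.
#' @return list with `traces` (frames x ROIs matrix of raw fluorescence),
#'   `time` (frame times, seconds, starting at 0), `event_times` (list per
#'   ROI of planted transient onset times), `sampling_rate`, `params`.
#' @export
simulate_calcium_traces <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  with_seed(params$seed, {
    n <- floor(params$duration * params$sampling_rate)
    tt <- (seq_len(n) - 1) / params$sampling_rate
    amp <- params$transient_amplitude * params$noise_sd
    traces <- matrix(0, n, params$n_rois)
    ev <- vector("list", params$n_rois)
    for (r in seq_len(params$n_rois)) {
      n_ev <- stats::rpois(1L, params$event_rate * params$duration / 60)
      times <- place_inhibited(n_ev, params$duration, params$min_event_gap)
      sig <- rep(params$baseline_level, n)
      for (t0 in times)
        sig <- sig + amp * calcium_kernel(tt - t0, params$rise_tau, params$decay_tau)
      if (params$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, params$noise_sd)
      traces[, r] <- sig
      ev[[r]] <- times
    }
    colnames(traces) <- sprintf("roi%d", seq_len(params$n_rois))
    list(traces = traces, time = tt, event_times = ev,
         sampling_rate = params$sampling_rate, params = params)
  })
}

#' Parameters for a synthetic miniscope movie
#'
#' Frames contain disk-shaped sources whose brightness follows per-source
#' traces, globally translated by per-frame integer drift, multiplied by a
#' smooth illumination gain field, plus white noise on a constant baseline.
#'
#' @param frame_shape integer c(rows, cols).
#' @param n_frames number of frames.
#' @param roi_centers matrix with one row per source: (row, col) pixel
#'   coordinates in the unshifted frame.
#' @param roi_radius source disk radius, pixels (default 6, matching the
#'   analysis ROI radius).
#' @param drift_shifts `n_frames x 2` integer matrix of (row, col) shifts
#'   applied to each frame (default all zero).
#' @param illumination_field multiplicative gain map (matrix of
#'   `frame_shape`), or NULL for flat illumination.
#' @param baseline_level background intensity.
#' @param source_traces `n_frames x n_sources` matrix of source brightness
#'   added inside each disk, or NULL to use constant `source_amplitude`.
#' @param source_amplitude constant source brightness when `source_traces`
#'   is NULL.
#' @param noise_sd white-noise SD (default 0).
#' @param seed optional integer seed.
#' @return an object of class `movie_sim_params`.
#' @export
movie_sim_params <- function(frame_shape = c(64, 64), n_frames = 30,
                             roi_centers = matrix(c(32, 32), 1),
                             roi_radius = 6, drift_shifts = NULL,
                             illumination_field = NULL, baseline_level = 20,
                             source_traces = NULL, source_amplitude = 50,
                             noise_sd = 0, seed = NULL) {
  frame_shape <- as.integer(frame_shape)
  stopifnot(length(frame_shape) == 2L, all(frame_shape > 0))
  roi_centers <- matrix(roi_centers, ncol = 2)
  if (is.null(drift_shifts)) drift_shifts <- matrix(0L, n_frames, 2)
  drift_shifts <- matrix(as.numeric(drift_shifts), ncol = 2)
  if (nrow(drift_shifts) != n_frames)
    stop("`drift_shifts` must have one row per frame", call. = FALSE)
  if (any(drift_shifts != round(drift_shifts)))
    stop("drift shifts must be integers", call. = FALSE)
  max_abs <- apply(abs(drift_shifts), 2, max)
  lo <- apply(roi_centers, 2, min) - roi_radius - max_abs
  hi <- apply(roi_centers, 2, max) + roi_radius + max_abs
  if (any(lo < 1) || any(hi > frame_shape))
    stop("an ROI disk leaves the frame under the maximal drift shift", call. = FALSE)
  if (!is.null(illumination_field) &&
      !identical(dim(illumination_field), frame_shape))
    stop("`illumination_field` must match `frame_shape`", call. = FALSE)
  if (!is.null(source_traces)) {
    source_traces <- as.matrix(source_traces)
    stopifnot(nrow(source_traces) == n_frames,
              ncol(source_traces) == nrow(roi_centers))
  }
  structure(list(frame_shape = frame_shape, n_frames = as.integer(n_frames),
                 roi_centers = roi_centers, roi_radius = roi_radius,
                 drift_shifts = drift_shifts,
                 illumination_field = illumination_field,
                 baseline_level = baseline_level,
                 source_traces = source_traces,
                 source_amplitude = source_amplitude,
                 noise_sd = noise_sd, seed = seed),
            class = "movie_sim_params")
}

# Integer-translate a matrix by (dr, dc), filling vacated pixels.
shift_frame <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

#' Simulate a miniscope movie with known ground truth
#'
#' @param params a [movie_sim_params()] object.
#' @return list with `movie` (rows x cols x frames array), `shifts` (the
#'   planted per-frame shifts), `roi_masks` (list of logical matrices in the
#'   unshifted frame), `source_traces` (the planted brightness), `params`.
#' @export
simulate_movie <- function(params) {
  stopifnot(inherits(params, "movie_sim_params"))
  with_seed(params$seed, {
    fs <- params$frame_shape
    nf <- params$n_frames
    ns <- nrow(params$roi_centers)
    traces <- params$source_traces %||%
      matrix(params$source_amplitude, nf, ns)
    rows <- matrix(seq_len(fs[1]), fs[1], fs[2])
    cols <- matrix(seq_len(fs[2]), fs[1], fs[2], byrow = TRUE)
    masks <- lapply(seq_len(ns), function(i) {
      (rows - params$roi_centers[i, 1])^2 +
        (cols - params$roi_centers[i, 2])^2 <= params$roi_radius^2
    })
    movie <- array(0, c(fs, nf))
    for (t in seq_len(nf)) {
      fr <- matrix(params$baseline_level, fs[1], fs[2])
      for (i in seq_len(ns)) fr[masks[[i]]] <- fr[masks[[i]]] + traces[t, i]
      fr <- shift_frame(fr, params$drift_shifts[t, 1], params$drift_shifts[t, 2],
                        fill = params$baseline_level)
      if (!is.null(params$illumination_field)) fr <- fr * params$illumination_field
      if (params$noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(prod(fs), 0, params$noise_sd), fs[1], fs[2])
      movie[, , t] <- fr
    }
    list(movie = movie, shifts = params$drift_shifts, roi_masks = masks,
         source_traces = traces, params = params)
  })
}
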