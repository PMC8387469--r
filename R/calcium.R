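# Miniscope processing chain: illumination correction, rigid motion
# correction, background subtraction, ROI traces, dF/F, event detection.

# 2-D Gaussian blur (separable), edge-renormalized.
gaussian_blur_2d <- function(m, sigma) {
  conv_axis <- function(m, along_rows) {
    half <- max(1L, ceiling(3 * sigma))
    x <- (-half):half
    k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- matrix(0, nrow(m), ncol(m))
    wt <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(x)) {
      s <- x[j]
      idx_dst <- max(1, 1 + s):min(n, n + s)
      idx_src <- idx_dst - s
      if (along_rows) {
        acc[idx_dst, ] <- acc[idx_dst, ] + k[j] * m[idx_src, ]
        wt[idx_dst, ] <- wt[idx_dst, ] + k[j]
      } else {
        acc[, idx_dst] <- acc[, idx_dst] + k[j] * m[, idx_src]
        wt[, idx_dst] <- wt[, idx_dst] + k[j]
      }
    }
    acc / wt
  }
  conv_axis(conv_axis(m, TRUE), FALSE)
}

#' Homomorphic illumination correction of one frame
#'
#' Multiplicative illumination becomes additive in log space: the frame is
#' log-transformed, a Gaussian low-pass estimate of the illumination is
#' subtracted, the removed mean level is restored, and the result is
#' exponentiated.  On a flat-illumination frame the transform is a
#' near-identity (up to attenuation of structure wider than the cutoff).
#'
#' @param frame numeric matrix with positive values.
#' @param sigma low-pass Gaussian SD in pixels; structure much wider than
#'   this is treated as illumination.
#' @return corrected matrix.
#' @export
homomorphic_filter <- function(frame, sigma) {
  if (any(frame <= 0)) frame <- pmax(frame, 1e-6)
  l <- log(frame)
  low <- gaussian_blur_2d(l, sigma)
  exp(l - low + mean(low))
}

# Best integer shift of `frame` against `template` by exhaustive search over
# [-max_shift, max_shift]^2, maximizing Pearson correlation on the overlap.
estimate_shift <- function(frame, template, max_shift = 5) {
  best <- c(0L, 0L); best_r <- -Inf
  nr <- nrow(frame); nc <- ncol(frame)
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      fr_r <- max(1, 1 + dr):min(nr, nr + dr)
      fr_c <- max(1, 1 + dc):min(nc, nc + dc)
      a <- frame[fr_r - dr, fr_c - dc]
      b <- template[fr_r, fr_c]
      sa <- stats::sd(a); sb <- stats::sd(b)
      r <- if (sa == 0 || sb == 0) 0 else stats::cor(as.vector(a), as.vector(b))
      if (r > best_r + 1e-12) { best_r <- r; best <- c(dr, dc) }
    }
  }
  list(shift = best, r = best_r)
}

#' Preprocess a miniscope movie
#'
#' Applies, in order: (1) homomorphic filtering of each frame to remove
#' smooth multiplicative illumination; (2) rigid motion correction — each
#' frame's integer translation against the mean-projection template is
#' estimated by exhaustive cross-correlation search within
#' `[-max_shift, max_shift]^2` and undone; (3) background subtraction of a
#' per-pixel temporal low percentile.  Steps can be toggled.
#'
#' @param movie rows x cols x frames numeric array (>= 2 frames).
#' @param homomorphic apply illumination correction (default TRUE).
#' @param lowpass_sigma Gaussian SD of the illumination low-pass, pixels
#'   (default a quarter of the smaller frame dimension).
#' @param motion apply motion correction (default TRUE).
#' @param max_shift search half-window for shifts, pixels (default 5).  A
#'   shift estimated at the window edge triggers a warning.
#' @param background subtract the per-pixel temporal percentile
#'   (default TRUE).
#' @param background_percentile percentile in \[0, 1\] (default 0.1).
#' @return list with `movie` (corrected array), `shifts` (frames x 2 matrix
#'   of estimated (row, col) shifts), and `template`.
#' @export
preprocess_movie <- function(movie, homomorphic = TRUE, lowpass_sigma = NULL,
                             motion = TRUE, max_shift = 5,
                             background = TRUE, background_percentile = 0.1) {
  d <- dim(movie)
  if (length(d) != 3L) stop("`movie` must be a rows x cols x frames array", call. = FALSE)
  if (d[3] < 2L) stop("need at least 2 frames", call. = FALSE)
  nf <- d[3]
  lowpass_sigma <- lowpass_sigma %||% (min(d[1:2]) / 4)

  if (homomorphic) {
    for (t in seq_len(nf))
      movie[, , t] <- homomorphic_filter(movie[, , t], lowpass_sigma)
  }

  shifts <- matrix(0, nf, 2)
  template <- apply(movie, c(1, 2), mean)
  if (motion) {
    # Iterate template refinement: estimate against the mean projection,
    # realign, recompute the template, until the estimates stabilize.  The
    # mean template of an unregistered movie is smeared, so a single pass can
    # be off by a pixel; iterating sharpens the template and converges.  The
    # global anchor is fixed by the convention that the per-axis median shift
    # is zero (drift is corrected relative to the movie's dominant pose).
    raw <- movie
    at_edge <- FALSE
    for (pass in 1:6) {
      template <- apply(movie, c(1, 2), mean)
      changed <- FALSE
      for (t in seq_len(nf)) {
        est <- estimate_shift(movie[, , t], template, max_shift)
        a <- est$shift
        if (any(a != 0)) {
          changed <- TRUE
          shifts[t, ] <- shifts[t, ] - a
        }
      }
      med <- apply(shifts, 2, stats::median)
      shifts <- sweep(shifts, 2, round(med))
      if (any(abs(shifts) >= max_shift)) at_edge <- TRUE
      for (t in seq_len(nf)) {
        s <- shifts[t, ]
        fill <- stats::median(raw[, , t])
        movie[, , t] <- if (any(s != 0))
          shift_frame(raw[, , t], -s[1], -s[2], fill = fill) else raw[, , t]
      }
      if (!changed) break
    }
    template <- apply(movie, c(1, 2), mean)
    if (at_edge)
      warning("estimated shift at search-window edge; consider a larger `max_shift`")
  }

  if (background) {
    bg <- apply(movie, c(1, 2), stats::quantile,
                probs = background_percentile, names = FALSE)
    movie <- sweep(movie, c(1, 2), bg, `-`)
  }

  list(movie = movie, shifts = shifts,
       template = if (motion) template else apply(movie, c(1, 2), mean))
}

#' Circular ROI specification
#'
#' @param center c(row, col) pixel coordinates.
#' @param radius pixels (default 6).
#' @param id optional label.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(center, radius = 6, id = NULL) {
  stopifnot(is.numeric(center), length(center) == 2L)
  stop_if_not_scalar_pos(radius, "radius")
  structure(list(center = as.numeric(center), radius = radius,
                 id = id %||% sprintf("roi_%g_%g", center[1], center[2])),
            class = "roi_spec")
}

#' Extract mean-intensity traces from circular ROIs
#'
#' Trace value for each frame is the mean pixel intensity inside the disk
#' `(r - r0)^2 + (c - c0)^2 <= radius^2`.
#'
#' @param movie rows x cols x frames array.
#' @param rois list of [roi_spec()] objects.
#' @return frames x ROIs matrix, columns named by ROI id.
#' @export
extract_roi_traces <- function(movie, rois) {
  d <- dim(movie)
  if (length(d) != 3L) stop("`movie` must be a rows x cols x frames array", call. = FALSE)
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  flat <- matrix(movie, d[1] * d[2], d[3])
  out <- sapply(rois, function(roi) {
    ctr <- roi$center
    if (ctr[1] - roi$radius < 1 || ctr[1] + roi$radius > d[1] ||
        ctr[2] - roi$radius < 1 || ctr[2] + roi$radius > d[2])
      stop(sprintf("ROI '%s' disk leaves the frame", roi$id), call. = FALSE)
    mask <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= roi$radius^2
    colMeans(flat[as.vector(mask), , drop = FALSE])
  })
  out <- matrix(out, ncol = length(rois))
  colnames(out) <- vapply(rois, `[[`, "", "id")
  out
}

#' Whole-recording-mean dF/F normalization
#'
#' `(F_t - mean(F)) / mean(F)` per trace; the normalized trace has mean zero
#' and is invariant to positive rescaling of F.
#'
#' @param x numeric vector or frames x ROIs matrix of raw fluorescence.
#' @return object of the same shape, normalized.
#' @export
delta_f_over_f <- function(x) {
  norm1 <- function(v) {
    m <- mean(v)
    if (!is.finite(m) || m <= 0)
      stop("trace mean must be positive for dF/F (nonphysical fluorescence)",
           call. = FALSE)
    (v - m) / m
  }
  if (is.matrix(x)) apply(x, 2, norm1) else norm1(x)
}

#' Event-detection configuration
#'
#' Calcium events are local maxima of the (Gaussian-smoothed) dF/F trace
#' whose amplitude is at least `k_sigma` standard deviations above baseline
#' (the trace mean, zero after dF/F).  The noise SD is estimated robustly by
#' default from the median absolute deviation of the trace's first
#' differences (`mad(diff(x))/sqrt(2)`), the standard trick in calcium
#' imaging: transients are slow relative to the frame interval, so
#' differencing removes them and the estimate stays calibrated even when
#' transients occupy a large fraction of the recording — where the plain SD,
#' and at high event rates even the direct MAD, are inflated and would bias
#' the threshold upward.  Peaks closer than `min_separation` are merged
#' keeping the larger.
#'
#' @param k_sigma threshold multiple of the SD estimate (default 3).
#' @param min_separation minimum peak separation, seconds (default 1).
#' @param sd_estimator `"mad_diff"` (robust, default), `"mad"` (direct MAD of
#'   the trace) or `"sd"` (full-trace SD).
#' @param smoothing_sigma Gaussian smoothing SD in frames (default 2; 0
#'   disables smoothing).
#' @return an object of class `event_detect_config`.
#' @export
event_detect_config <- function(k_sigma = 3, min_separation = 1,
                                sd_estimator = c("mad_diff", "mad", "sd"),
                                smoothing_sigma = 2) {
  stop_if_not_scalar_pos(k_sigma, "k_sigma")
  stop_if_not_scalar_pos(min_separation, "min_separation", allow_zero = TRUE)
  stop_if_not_scalar_pos(smoothing_sigma, "smoothing_sigma", allow_zero = TRUE)
  structure(list(k_sigma = k_sigma, min_separation = min_separation,
                 sd_estimator = match.arg(sd_estimator),
                 smoothing_sigma = smoothing_sigma),
            class = "event_detect_config")
}

gaussian_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  if (length(x) < 2L * half + 1L)
    stop("trace shorter than the smoothing support", call. = FALSE)
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # reflect-pad so the edges keep local mean level
  xp <- c(rev(x[2:(half + 1)]), x, rev(x[(length(x) - half):(length(x) - 1)]))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Detect calcium events on a normalized trace
#'
#' @param trace dF/F-normalized numeric vector (mean approximately 0).
#' @param sampling_rate frames per second.
#' @param cfg an [event_detect_config()].
#' @return numeric vector of event times (seconds; frame i maps to
#'   `(i-1)/sampling_rate`), with attribute `"threshold"` (the amplitude
#'   cutoff used).
#' @export
detect_events <- function(trace, sampling_rate, cfg = event_detect_config()) {
  stopifnot(inherits(cfg, "event_detect_config"))
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (!is.numeric(trace) || length(trace) < 3L)
    stop("`trace` must be a numeric vector with at least 3 samples", call. = FALSE)
  sdest <- switch(cfg$sd_estimator,
                  mad_diff = stats::mad(diff(trace)) / sqrt(2),
                  mad = stats::mad(trace),
                  sd = stats::sd(trace))
  baseline <- mean(trace)
  thr <- baseline + cfg$k_sigma * sdest
  sm <- gaussian_smooth_1d(trace, cfg$smoothing_sigma)
  n <- length(sm)
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                      sm[2:(n - 1)] >= sm[3:n], FALSE)
  idx <- which(is_peak & sm >= thr)
  if (length(idx) > 1L && cfg$min_separation > 0) {
    min_frames <- cfg$min_separation * sampling_rate
    keep <- logical(length(idx))
    ord <- order(sm[idx], decreasing = TRUE)
    kept_idx <- integer(0)
    for (j in ord) {
      if (!length(kept_idx) || min(abs(kept_idx - idx[j])) >= min_frames) {
        keep[j] <- TRUE
        kept_idx <- c(kept_idx, idx[j])
      }
    }
    idx <- sort(idx[keep])
  }
  structure((idx - 1) / sampling_rate, threshold = thr)
}

#' Events per minute
#'
#' @param event_times numeric vector of event times (seconds).
#' @param duration recording duration, seconds (> 0).
#' @param roi_id,condition_label optional metadata carried on the result.
#' @return an object of class `event_rate`: list with `roi_id`,
#'   `event_times`, `events_per_minute`, `recording_duration`,
#'   `condition_label`.
#' @export
events_per_minute <- function(event_times, duration, roi_id = NULL,
                              condition_label = NULL) {
  stop_if_not_scalar_pos(duration, "duration")
  structure(list(roi_id = roi_id, event_times = as.numeric(event_times),
                 events_per_minute = 60 * length(event_times) / duration,
                 recording_duration = duration,
                 condition_label = condition_label),
            class = "event_rate")
}

#' Compare ROI-level event rates between two conditions
#'
#' Unpaired two-tailed t test between the per-ROI events-per-minute values of
#' two condition labels (e.g. post-magazine-training vs post-acquisition
#' recordings).
#'
#' @param rates_a,rates_b numeric vectors of per-ROI rates, or lists of
#'   `event_rate` objects.
#' @param var_equal assume equal variances (default FALSE, Welch).
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_event_rates <- function(rates_a, rates_b, var_equal = FALSE) {
  pull <- function(x) {
    if (is.list(x)) vapply(x, function(r) r$events_per_minute, 1) else as.numeric(x)
  }
  stats::t.test(pull(rates_a), pull(rates_b), var.equal = var_equal)
}
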