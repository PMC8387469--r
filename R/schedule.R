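#' Reinforcement-schedule configuration
#'
#' Describes the contingency of one operant session.  Supported kinds:
#' \describe{
#'   \item{FR1}{fixed ratio 1 — every press outside the post-reward timeout
#'     is rewarded.}
#'   \item{FR2}{fixed ratio 2 — every second eligible press is rewarded.}
#'   \item{RI60}{random interval — the lever starts inactive and each whole
#'     second becomes active with probability `ri_activation_prob` (default
#'     1/60); the next press on an active lever is rewarded and the lever
#'     returns to inactive.  With a continuously pressing subject this yields
#'     geometric inter-reward intervals with mean `1/ri_activation_prob`
#'     seconds.}
#'   \item{VT}{variable time — rewards are delivered noncontingently at
#'     exponential intervals with mean `vt_mean_interval` seconds, regardless
#'     of pressing (used for magazine training).}
#' }
#' The session ends at the `criterion_rewards`-th reward or at `session_cap`
#' seconds, whichever comes first.
#'
#' @param schedule_kind one of `"FR1"`, `"FR2"`, `"RI60"`, `"VT"`.
#' @param criterion_rewards session ends after this many rewards (>= 1).
#' @param session_cap maximum session duration, seconds.
#' @param timeout post-reward lockout in seconds during which presses are not
#'   counted toward the ratio requirement (default 1, as in FR1 training).
#' @param ri_activation_prob per-second lever-activation probability for RI
#'   schedules, in (0, 1] (default 1/60).
#' @param vt_mean_interval mean inter-delivery interval for VT schedules,
#'   seconds (default 60).
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(schedule_kind = c("FR1", "FR2", "RI60", "VT"),
                            criterion_rewards = 30, session_cap = 7200,
                            timeout = 1, ri_activation_prob = 1 / 60,
                            vt_mean_interval = 60) {
  schedule_kind <- match.arg(schedule_kind)
  if (criterion_rewards < 1 || criterion_rewards != round(criterion_rewards))
    stop("`criterion_rewards` must be a whole number >= 1", call. = FALSE)
  stop_if_not_scalar_pos(session_cap, "session_cap")
  stop_if_not_scalar_pos(timeout, "timeout", allow_zero = TRUE)
  if (ri_activation_prob <= 0 || ri_activation_prob > 1)
    stop("`ri_activation_prob` must be in (0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(vt_mean_interval, "vt_mean_interval")
  structure(list(schedule_kind = schedule_kind,
                 criterion_rewards = as.integer(criterion_rewards),
                 session_cap = session_cap, timeout = timeout,
                 ri_activation_prob = ri_activation_prob,
                 vt_mean_interval = vt_mean_interval),
            class = "schedule_config")
}

#' Press stream at a constant rate
#'
#' Convenience press source: one press every `interval` seconds for
#' `duration` seconds, starting at `interval`.  Useful for probing schedule
#' behaviour with a "continuously pressing" subject.
#'
#' @param duration seconds.
#' @param interval seconds between presses (default 1).
#' @return numeric vector of press times.
#' @export
regular_press_times <- function(duration, interval = 1) {
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(interval, "interval")
  seq(interval, duration, by = interval)
}

#' Simulate one operant session under a reinforcement schedule
#'
#' Takes a press source (either a [bout_process_params()] object, simulated
#' internally, or a numeric vector of press times) and applies the schedule
#' contingency to produce the session's full event log: presses, rewards,
#' magazine entries and — for RI schedules — lever activations.  Rewards obey
#' the schedule exactly; the session ends at the criterion-th reward or at the
#' session cap, whichever comes first, and all events after session end are
#' dropped.  Ground-truth bout labels (when the press source is a bout
#' process) are carried on the surviving presses.
#'
#' Magazine entries are modelled as one entry a uniform `(0,
#' magazine_latency)` delay after each reward, plus a low spontaneous Poisson
#' rate; this reproduces the coupling between reward collection and magazine
#' entries without modelling feeding.
#'
#' @param schedule a [schedule_config()] object.
#' @param press a [bout_process_params()] object or a sorted numeric vector of
#'   candidate press times (seconds).  May be empty/zero-rate: a ratio
#'   schedule then simply earns no rewards and runs to the cap.
#' @param magazine_latency maximum reward-to-magazine-entry latency, seconds.
#' @param spontaneous_magazine_rate spontaneous magazine entries per minute.
#' @param subject_id,session_id,group identifiers stamped on the event log.
#' @param seed optional integer seed (governs the schedule's own randomness
#'   and magazine entries; a `bout_process_params` press source uses its own
#'   seed field).
#' @return an object of class `event_stream`: a list with `events` (a
#'   data.frame with columns subject_id, session_id, group, event_type,
#'   time_s), `press_labels` (ground-truth bout labels or NA), `n_rewards`,
#'   `session_end`, and `schedule`.
#' @export
simulate_operant_session <- function(schedule, press,
                                     magazine_latency = 2,
                                     spontaneous_magazine_rate = 0.5,
                                     subject_id = "s1", session_id = "sess1",
                                     group = "none", seed = NULL) {
  stopifnot(inherits(schedule, "schedule_config"))
  stop_if_not_scalar_pos(magazine_latency, "magazine_latency")
  stop_if_not_scalar_pos(spontaneous_magazine_rate, "spontaneous_magazine_rate",
                         allow_zero = TRUE)

  if (inherits(press, "bout_process_params")) {
    bp <- press
    if (bp$duration < schedule$session_cap)
      bp$duration <- schedule$session_cap
    stream <- simulate_bout_process(bp)
    press_times <- stream$times
    press_labels <- stream$labels
  } else if (is.numeric(press)) {
    if (is.unsorted(press)) stop("press times must be sorted ascending", call. = FALSE)
    if (any(press < 0)) stop("press times must be non-negative", call. = FALSE)
    press_times <- as.numeric(press)
    press_labels <- rep(NA_integer_, length(press_times))
  } else {
    stop("`press` must be a bout_process_params object or numeric press times",
         call. = FALSE)
  }
  keep <- press_times <= schedule$session_cap
  press_times <- press_times[keep]
  press_labels <- press_labels[keep]

  with_seed(seed, {
    kind <- schedule$schedule_kind
    cap <- schedule$session_cap
    crit <- schedule$criterion_rewards
    reward_times <- numeric(0)
    activation_times <- numeric(0)

    if (kind %in% c("FR1", "FR2")) {
      ratio <- if (kind == "FR1") 1L else 2L
      eligible <- 0L
      last_reward <- -Inf
      for (tp in press_times) {
        if (tp - last_reward < schedule$timeout) next
        eligible <- eligible + 1L
        if (eligible %% ratio == 0L) {
          reward_times <- c(reward_times, tp)
          last_reward <- tp
          if (length(reward_times) >= crit) break
        }
      }
    } else if (kind == "RI60") {
      p <- schedule$ri_activation_prob
      # lever starts inactive; activation checks at whole seconds 1, 2, ...
      # geometric waits let us skip silent seconds without a per-second loop
      next_check <- 1
      i <- 1L
      n_press <- length(press_times)
      while (next_check <= cap && length(reward_times) < crit) {
        act <- next_check + stats::rgeom(1L, p)
        if (act > cap) break
        activation_times <- c(activation_times, act)
        while (i <= n_press && press_times[i] < act) i <- i + 1L
        if (i > n_press) break
        rt <- press_times[i]
        reward_times <- c(reward_times, rt)
        i <- i + 1L
        next_check <- floor(rt) + 1
      }
    } else { # VT: noncontingent deliveries, presses irrelevant
      t <- 0
      while (length(reward_times) < crit) {
        t <- t + stats::rexp(1L, 1 / schedule$vt_mean_interval)
        if (t > cap) break
        reward_times <- c(reward_times, t)
      }
    }

    session_end <- if (length(reward_times) >= crit)
      reward_times[crit] else cap
    reward_times <- reward_times[reward_times <= session_end]

    keep <- press_times <= session_end
    press_times <- press_times[keep]
    press_labels <- press_labels[keep]
    activation_times <- activation_times[activation_times <= session_end]

    mag <- reward_times + stats::runif(length(reward_times), 0, magazine_latency)
    if (spontaneous_magazine_rate > 0) {
      n_sp <- stats::rpois(1L, spontaneous_magazine_rate / 60 * session_end)
      mag <- c(mag, stats::runif(n_sp, 0, session_end))
    }
    mag <- dedup_times(mag[mag <= session_end])

    ev_df <- function(type, t)
      data.frame(event_type = rep(type, length(t)), time_s = t)
    ev <- rbind(ev_df("press", press_times),
                ev_df("reward", reward_times),
                ev_df("magazine", mag),
                ev_df("lever_active", activation_times))
    ev <- ev[order(ev$time_s, ev$event_type), , drop = FALSE]
    n_ev <- nrow(ev)
    events <- data.frame(subject_id = rep(subject_id, n_ev),
                         session_id = rep(session_id, n_ev),
                         group = rep(group, n_ev),
                         event_type = ev$event_type,
                         time_s = ev$time_s, row.names = NULL)
    structure(list(events = events, press_labels = press_labels,
                   n_rewards = length(reward_times),
                   session_end = session_end, schedule = schedule),
              class = "event_stream")
  })
}

#' @export
print.event_stream <- function(x, ...) {
  tab <- table(x$events$event_type)
  cat(sprintf("<event_stream> %s session, %.1f s, %d rewards\n",
              x$schedule$schedule_kind, x$session_end, x$n_rewards))
  cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Press times of an event stream
#' @param stream an `event_stream`.
#' @return sorted numeric vector of press times.
#' @export
press_times <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  stream$events$time_s[stream$events$event_type == "press"]
}

#' Magazine-entry times of an event stream
#' @param stream an `event_stream`.
#' @return sorted numeric vector of magazine-entry times.
#' @export
magazine_times <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  stream$events$time_s[stream$events$event_type == "magazine"]
}
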