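#' Build a behavior log from an event table
#'
#' @param events data.frame with columns `t` (s), `kind` (one of
#'   `approach_no_retrieve`, `drop`, `retrieve`, `rear`, `sniff`) and
#'   optional `pup_id`.
#' @param n_pups number of pups placed in the cage.
#' @param test_duration test window (s); the retrieval cutoff, default 300
#'   (5 min).
#' @return `behavior_log` object.
#' @export
behavior_log <- function(events, n_pups, test_duration = 300) {
  if (is.null(events$pup_id))
    events$pup_id <- rep(NA_integer_, nrow(events))
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL
  log <- structure(list(events = events, n_pups = as.integer(n_pups),
                        test_duration = test_duration, truth = NULL),
                   class = "behavior_log")
  validate_behavior_log(log)
  log
}

#' Cumulative retrieval curve
#'
#' Right-continuous step function giving the percent of pups retrieved by
#' time `t`.
#'
#' @param log `behavior_log`.
#' @return list with `times` (retrieve event times), `percent` (percent
#'   retrieved after each event) and `percent_at(t)`, a vectorized
#'   evaluator.
#' @examples
#' log <- behavior_log(data.frame(t = c(10, 30, 50, 200),
#'                                kind = "retrieve"), n_pups = 4)
#' cumulative_retrieval(log)$percent_at(40)  # 50
#' @export
cumulative_retrieval <- function(log) {
  validate_behavior_log(log)
  rt <- sort(log$events$t[log$events$kind == "retrieve"])
  pct <- if (length(rt)) 100 * seq_along(rt) / log$n_pups else numeric(0)
  percent_at <- function(t) {
    vapply(t, function(tt) {
      if (!length(rt)) return(0)
      k <- sum(rt <= tt)
      100 * k / log$n_pups
    }, numeric(1))
  }
  list(times = rt, percent = pct, percent_at = percent_at)
}

#' Latency to retrieve all pups
#'
#' Time of the `n_pups`-th retrieve event; censored at `test_duration`
#' when fewer pups were retrieved.
#'
#' @param log `behavior_log`.
#' @return list with `latency` (s) and `censored` flag.
#' @export
latency_all_pups <- function(log) {
  validate_behavior_log(log)
  if (log$n_pups == 0L)
    return(list(latency = 0, censored = TRUE))
  rt <- sort(log$events$t[log$events$kind == "retrieve"])
  if (length(rt) >= log$n_pups) {
    list(latency = rt[log$n_pups], censored = FALSE)
  } else {
    list(latency = log$test_duration, censored = TRUE)
  }
}

#' Relative failure index
#'
#' Proportion of pup-directed approach outcomes that ended in failure:
#' `(approaches without retrieval + drops) / (failures + retrievals)`.
#' Bounded in `[0, 1]`; more failed approaches give a higher index.  With
#' `normalize = FALSE` the raw failure count is returned instead.
#'
#' @param log `behavior_log`.
#' @param normalize divide by total pup-directed outcomes (default).
#' @return list with `index` and `no_events` flag (TRUE when no
#'   pup-directed event occurred; index then 0).
#' @export
relative_failure_index <- function(log, normalize = TRUE) {
  validate_behavior_log(log)
  kinds <- log$events$kind
  fails <- sum(kinds %in% c("approach_no_retrieve", "drop"))
  succ <- sum(kinds == "retrieve")
  if (!normalize)
    return(list(index = fails, no_events = (fails + succ) == 0L))
  if (fails + succ == 0L)
    return(list(index = 0, no_events = TRUE))
  list(index = fails / (fails + succ), no_events = FALSE)
}

#' Count events of a kind in an initial time window
#'
#' Counts events with `t` in the half-open window `[0, window)`; an event
#' exactly at `window` is excluded.  Used for rearings in the first minute
#' and sniffs in the first 30 s after the dam is introduced.
#'
#' @param log `behavior_log`.
#' @param kind event kind to count.
#' @param window window length (s), at most `test_duration`.
#' @return integer count.
#' @export
windowed_count <- function(log, kind, window) {
  validate_behavior_log(log)
  stopifnot(window <= log$test_duration)
  sum(log$events$kind == kind & log$events$t < window &
        log$events$t >= 0)
}

#' Spearman correlation between two per-animal metrics
#'
#' Thin wrapper over [spearman_cor()] for cross-metric correlations such as
#' retrieval time versus relative failure index.
#'
#' @param x,y paired per-animal values, `n >= 4`.
#' @return `test_result` from [spearman_cor()].
#' @export
metric_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  spearman_cor(x, y)
}

#' Score one behavior log to a one-row metrics table
#'
#' @param log `behavior_log`.
#' @param rear_window,sniff_window windows (s) for rearing and sniff counts.
#' @return one-row data.frame: `latency`, `censored`, `pct_retrieved`,
#'   `failure_index`, `rearing_first_min`, `sniffs_first_30s`.
#' @export
retrieval_metrics <- function(log, rear_window = 60, sniff_window = 30) {
  lat <- latency_all_pups(log)
  cum <- cumulative_retrieval(log)
  rfi <- relative_failure_index(log)
  data.frame(
    latency = lat$latency,
    censored = lat$censored,
    pct_retrieved = cum$percent_at(log$test_duration),
    failure_index = rfi$index,
    rearing_first_min = windowed_count(log, "rear", rear_window),
    sniffs_first_30s = windowed_count(log, "sniff", sniff_window)
  )
}
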