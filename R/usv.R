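#' Ultrasonic vocalization call object
#'
#' @param contour data.frame with columns `t` (s, increasing), `freq_hz`
#'   (> 0) and `amp` (linear amplitude).
#' @param call_id,litter_id,pup_id labels.
#' @return `usv_call`.
#' @export
usv_call <- function(contour, call_id = NA, litter_id = NA, pup_id = NA) {
  stopifnot(is.data.frame(contour),
            all(c("t", "freq_hz", "amp") %in% names(contour)),
            nrow(contour) >= 2L)
  if (is.unsorted(contour$t, strictly = TRUE))
    stop("contour times must be strictly increasing")
  if (any(contour$freq_hz <= 0)) stop("frequencies must be positive")
  structure(list(contour = contour, call_id = call_id,
                 litter_id = litter_id, pup_id = pup_id,
                 category_true = NA_character_),
            class = "usv_call")
}

#' Per-call acoustic metrics
#'
#' Duration (last minus first contour time), mean linear amplitude, and the
#' frequency at the maximum amplitude peak; amplitude ties resolve to the
#' earliest time.
#'
#' @param call `usv_call`.
#' @return list `duration` (s), `mean_linear_amplitude`,
#'   `freq_at_max_peak` (Hz).
#' @export
call_metrics <- function(call) {
  stopifnot(inherits(call, "usv_call"))
  ct <- call$contour
  imax <- which.max(ct$amp)          # which.max takes the earliest tie
  list(duration = ct$t[nrow(ct)] - ct$t[1],
       mean_linear_amplitude = mean(ct$amp),
       freq_at_max_peak = ct$freq_hz[imax])
}

# 3-point moving median, endpoints untouched
moving_median3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  for (i in 2:(n - 1L))
    out[i] <- stats::median(x[(i - 1L):(i + 1L)])
  out
}

# direction reversals of a contour with a hysteresis band: a reversal is
# counted when the contour retreats from its running extreme by more than
# `hyst`
count_reversals <- function(f, hyst) {
  state <- 0L
  rev <- 0L
  hi <- f[1]; lo <- f[1]; ext <- f[1]
  for (v in f[-1]) {
    if (state == 0L) {
      hi <- max(hi, v); lo <- min(lo, v)
      if (v > lo + hyst) { state <- 1L; ext <- v }
      else if (v < hi - hyst) { state <- -1L; ext <- v }
    } else if (state == 1L) {
      if (v > ext) ext <- v
      else if (v < ext - hyst) { rev <- rev + 1L; state <- -1L; ext <- v }
    } else {
      if (v < ext) ext <- v
      else if (v > ext + hyst) { rev <- rev + 1L; state <- 1L; ext <- v }
    }
  }
  rev
}

#' Default USV classification thresholds
#'
#' @param d_short maximal duration of a `short` call (s), default 5 ms.
#' @param m_flat maximal total frequency modulation of a `flat` call (Hz),
#'   default 3 kHz.
#' @param m_dir minimal net frequency change for `upward` / `downward`
#'   (Hz), default 6 kHz.
#' @param hysteresis reversal-counting hysteresis band (Hz), default 1 kHz.
#' @param smooth_window contour smoothing window (points), default 3.
#' @return named list of thresholds.
#' @export
usv_thresholds <- function(d_short = 0.005, m_flat = 3000, m_dir = 6000,
                           hysteresis = 1000, smooth_window = 3) {
  list(d_short = d_short, m_flat = m_flat, m_dir = m_dir,
       hysteresis = hysteresis, smooth_window = smooth_window)
}

#' Classify a call into one of six categories
#'
#' Decision tree on the smoothed frequency contour: duration below
#' `d_short` gives `short`; total modulation (max minus min frequency)
#' below `m_flat` gives `flat`; two or more direction reversals give
#' `complex`; one reversal with an interior frequency maximum gives
#' `chevron`; otherwise a net frequency change beyond `m_dir` gives
#' `upward` or `downward`; anything left falls back to `flat`.
#' Classification is invariant to uniform time shifts and amplitude
#' rescaling.
#'
#' @param call `usv_call`.
#' @param thresholds list from [usv_thresholds()].
#' @return category string.
#' @export
classify_call <- function(call, thresholds = usv_thresholds()) {
  stopifnot(inherits(call, "usv_call"))
  th <- thresholds
  ct <- call$contour
  d <- ct$t[nrow(ct)] - ct$t[1]
  if (d < th$d_short) return("short")
  f <- ct$freq_hz
  if (th$smooth_window >= 3 && length(f) >= 3) f <- moving_median3(f)
  M <- max(f) - min(f)
  if (M < th$m_flat) return("flat")
  R <- count_reversals(f, th$hysteresis)
  if (R >= 2L) return("complex")
  imax <- which.max(f)
  if (R == 1L && imax > 1L && imax < length(f)) return("chevron")
  df <- f[length(f)] - f[1]
  if (df > th$m_dir) return("upward")
  if (df < -th$m_dir) return("downward")
  "flat"
}

#' Generate synthetic USV calls from the six category archetypes
#'
#' Archetypes (frequencies in kHz, jitter SD `usv_jitter_khz`): `flat`
#' constant frequency; `upward` / `downward` monotone 15-kHz ramps;
#' `chevron` a rise-then-fall arc (interior peak); `complex` a contour with
#' two direction reversals; `short` a sub-threshold-duration flat call.
#' The true label is stored on each call.
#'
#' @param cfg [sim_config()].
#' @param n_litters litters the calls are spread over.
#' @return list of `usv_call` objects with `category_true` set.
#' @export
gen_usv_calls <- function(cfg, n_litters = 2L) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "usv"))
  cats <- c("short", "flat", "chevron", "complex", "upward", "downward")
  calls <- list()
  id <- 0L
  for (cat in cats) {
    for (k in seq_len(cfg$usv_n_per_category)) {
      id <- id + 1L
      dur <- if (cat == "short") stats::runif(1, 0.002, 0.004)
             else stats::runif(1, 0.02, 0.06)
      npts <- if (cat == "short") 8L else 24L
      tt <- seq(0, dur, length.out = npts)
      s <- seq(0, 1, length.out = npts)
      f0 <- stats::runif(1, 60, 80)
      base <- switch(cat,
        short = rep(f0, npts),
        flat = rep(f0, npts),
        upward = f0 + 15 * s,
        downward = f0 - 15 * s,
        chevron = f0 + 10 * sin(pi * s),
        complex = f0 + 8 * sin(2.5 * pi * s))
      f <- base + stats::rnorm(npts, 0, cfg$usv_jitter_khz)
      # amplitude envelope with a single interior peak
      pk <- stats::runif(1, 0.25, 0.75)
      amp <- exp(-((s - pk) / 0.35)^2) * stats::runif(1, 0.5, 2)
      call <- usv_call(
        data.frame(t = tt, freq_hz = f * 1000, amp = amp),
        call_id = sprintf("c%04d", id),
        litter_id = sprintf("L%d", 1L + (id %% n_litters)),
        pup_id = sprintf("p%d", 1L + (id %% 4L))
      )
      call$category_true <- cat
      calls[[id]] <- call
    }
  }
  calls
}

#' Per-litter, per-category call summary
#'
#' @param calls list of `usv_call`.
#' @param thresholds passed to [classify_call()].
#' @return data.frame with one row per litter x category: `n_calls`,
#'   `mean_duration`, `mean_amplitude`, `mean_freq_at_max_peak` (means `NA`
#'   for empty categories), plus per-litter totals as category `"all"`.
#' @export
litter_summary <- function(calls, thresholds = usv_thresholds()) {
  stopifnot(length(calls) > 0)
  rows <- lapply(calls, function(cl) {
    met <- call_metrics(cl)
    data.frame(litter_id = cl$litter_id,
               category = classify_call(cl, thresholds),
               duration = met$duration,
               amplitude = met$mean_linear_amplitude,
               freq = met$freq_at_max_peak,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  cats <- c("short", "flat", "chevron", "complex", "upward", "downward")
  out <- expand.grid(litter_id = unique(df$litter_id),
                     category = c(cats, "all"),
                     stringsAsFactors = FALSE)
  stat <- function(litter, cat, col) {
    sel <- df$litter_id == litter & (cat == "all" | df$category == cat)
    if (!any(sel)) return(NA_real_)
    mean(df[[col]][sel])
  }
  out$n_calls <- mapply(function(l, cat) {
    sum(df$litter_id == l & (cat == "all" | df$category == cat))
  }, out$litter_id, out$category)
  out$mean_duration <- mapply(stat, out$litter_id, out$category,
                              MoreArgs = list(col = "duration"))
  out$mean_amplitude <- mapply(stat, out$litter_id, out$category,
                               MoreArgs = list(col = "amplitude"))
  out$mean_freq_at_max_peak <- mapply(stat, out$litter_id, out$category,
                                      MoreArgs = list(col = "freq"))
  out[order(out$litter_id, out$category), , drop = FALSE]
}
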