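#' Mean firing rate over a half-open interval
#'
#' Spikes are counted on `[start, end)`: a spike exactly at `end` belongs to
#' the next interval.
#'
#' @param spike_times numeric vector of spike times (s), sorted increasing.
#' @param interval numeric length-2, `c(start, end)` in seconds, `end > start`.
#' @return firing rate in Hz.
#' @examples
#' firing_rate(seq(0, 1.8, by = 0.2), c(0, 2))  # 10 spikes / 2 s = 5 Hz
#' @export
firing_rate <- function(spike_times, interval) {
  stopifnot(length(interval) == 2L)
  len <- interval[2] - interval[1]
  if (len <= 0) stop("interval must have positive length")
  sum(spike_times >= interval[1] & spike_times < interval[2]) / len
}

#' Full action-potential width of a mean waveform
#'
#' Width of the extracellular AP complex, measured as the time between the
#' first and the last crossing of a threshold at `threshold_frac` (default
#' 10\%) of the peak absolute amplitude, with linear interpolation between
#' samples.  The measure is invariant to amplitude rescaling and spans the
#' whole complex including any after-hyperpolarization (undershoot) that
#' exceeds the threshold.
#'
#' @param waveform numeric vector of mean voltage samples (>= 8 samples).
#' @param dt_us sampling interval in microseconds per sample.
#' @param threshold_frac threshold as a fraction of peak absolute amplitude.
#' @return width in ms.
#' @examples
#' # symmetric triangular pulse with 1.0-ms base: width = 0.9 ms at 10%
#' v <- c(seq(0, 1, length.out = 21), seq(1, 0, length.out = 21)[-1])
#' spike_width(v, dt_us = 1000 / 40)
#' @export
spike_width <- function(waveform, dt_us, threshold_frac = 0.1) {
  stopifnot(length(waveform) >= 8L, dt_us > 0,
            threshold_frac > 0, threshold_frac < 1)
  a <- abs(waveform)
  peak <- max(a)
  if (peak <= 0) stop("flat waveform: spike width undefined")
  th <- threshold_frac * peak
  above <- which(a >= th)
  if (length(above) == 0L) stop("no samples above threshold")
  i1 <- above[1L]
  i2 <- above[length(above)]
  # linear interpolation onto the threshold on each flank
  t1 <- if (i1 == 1L) 0 else
    (i1 - 2) + (th - a[i1 - 1L]) / (a[i1] - a[i1 - 1L])
  t2 <- if (i2 == length(a)) i2 - 1 else
    (i2 - 1) + (a[i2] - th) / (a[i2] - a[i2 + 1L])
  (t2 - t1) * dt_us / 1000
}

#' Classify a single unit by firing rate and spike width
#'
#' Rule used for VTA single units: the firing-rate rule is applied first —
#' units with baseline FR above `fr_fast` Hz are `fast_firing`.  Slow-firing
#' units are split by full AP width: below `narrow_max` ms `narrow_spiking`
#' (putative GABAergic), above `wide_min` ms `wide_spiking` (putative
#' dopaminergic).  Units in the 1.2–1.4 ms dead zone are assigned
#' `wide_spiking` when the waveform shows a post-peak undershoot deeper than
#' `undershoot_frac` of the peak amplitude lasting at least
#' `undershoot_min_ms` (the slow-AP signature), and are otherwise
#' `ambiguous_excluded`.
#'
#' @param fr_baseline baseline firing rate (Hz).
#' @param width full AP width (ms).
#' @param waveform optional mean waveform, used only for dead-zone units.
#' @param dt_us sampling interval of `waveform` (microseconds/sample).
#' @param fr_fast fast-firing cutoff (Hz), default 10.
#' @param narrow_max,wide_min width cutoffs (ms), defaults 1.2 and 1.4.
#' @param undershoot_frac,undershoot_min_ms dead-zone undershoot criterion.
#' @return list with `label` (one of `fast_firing`, `narrow_spiking`,
#'   `wide_spiking`, `ambiguous_excluded`), `fr_baseline`, `width`.
#' @export
classify_unit <- function(fr_baseline, width, waveform = NULL, dt_us = NULL,
                          fr_fast = 10, narrow_max = 1.2, wide_min = 1.4,
                          undershoot_frac = 0.2, undershoot_min_ms = 0.3) {
  stopifnot(fr_baseline >= 0, width > 0)
  label <- if (fr_baseline > fr_fast) {
    "fast_firing"
  } else if (width < narrow_max) {
    "narrow_spiking"
  } else if (width > wide_min) {
    "wide_spiking"
  } else if (!is.null(waveform) &&
             has_undershoot(waveform, dt_us, undershoot_frac,
                            undershoot_min_ms)) {
    "wide_spiking"
  } else {
    "ambiguous_excluded"
  }
  list(label = label, fr_baseline = fr_baseline, width = width)
}

# TRUE when the waveform shows a post-peak opposite-sign deflection deeper
# than frac * peak for at least min_ms
has_undershoot <- function(waveform, dt_us, frac = 0.2, min_ms = 0.3) {
  stopifnot(!is.null(dt_us))
  a <- abs(waveform)
  ip <- which.max(a)
  if (ip >= length(waveform)) return(FALSE)
  s <- sign(waveform[ip])
  post <- waveform[(ip + 1L):length(waveform)]
  deep <- (-s * post) > frac * a[ip]
  if (!any(deep)) return(FALSE)
  runs <- rle(deep)
  max(runs$lengths[runs$values]) * dt_us / 1000 >= min_ms
}

#' Detect bursts in a spike train
#'
#' A burst is a run of two or more spikes in which every interspike interval
#' is below `isi_max` (default 80 ms) and the total span (last minus first
#' spike) does not exceed `max_span` (default 160 ms).  Detection is a
#' greedy left-to-right scan: a burst opens at the first ISI below the
#' threshold and extends while the next ISI stays below threshold and the
#' would-be span stays within the cap; the spike that would exceed the cap
#' starts a new candidate pair.  Bursts are disjoint.
#'
#' @param spike_times numeric, sorted increasing, seconds.
#' @param isi_max ISI threshold (s), default 0.080.
#' @param max_span maximum burst span (s), default 0.160.
#' @return list of bursts; each has `spike_indices` (into `spike_times`)
#'   and `duration` (ms).
#' @examples
#' detect_bursts(c(0, 0.05, 0.12, 0.5))  # one burst of spikes 1:3
#' @export
detect_bursts <- function(spike_times, isi_max = 0.080, max_span = 0.160) {
  n <- length(spike_times)
  if (n >= 2L && any(diff(spike_times) < 0))
    stop("spike_times must be sorted increasing")
  bursts <- list()
  i <- 1L
  while (i < n) {
    if (spike_times[i + 1L] - spike_times[i] < isi_max &&
        spike_times[i + 1L] - spike_times[i] <= max_span) {
      j <- i + 1L
      while (j < n &&
             spike_times[j + 1L] - spike_times[j] < isi_max &&
             spike_times[j + 1L] - spike_times[i] <= max_span) {
        j <- j + 1L
      }
      bursts[[length(bursts) + 1L]] <- list(
        spike_indices = i:j,
        duration = (spike_times[j] - spike_times[i]) * 1000
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  bursts
}

#' Per-unit burst statistics
#'
#' `bursting_percent` is the percentage of all spikes that fall inside
#' detected bursts; `mean_spikes_per_burst` averages over detected bursts.
#' Both are 0-safe: with no bursts the percent is 0 and the mean is reported
#' as 0 with `no_bursts = TRUE`.
#'
#' @param bursts list as returned by [detect_bursts()].
#' @param n_spikes_total total spikes in the train.
#' @return list with `bursting_percent`, `mean_spikes_per_burst`,
#'   `n_bursts`, `no_bursts`.
#' @export
burst_stats <- function(bursts, n_spikes_total) {
  stopifnot(n_spikes_total >= 0)
  n_bursts <- length(bursts)
  if (n_bursts == 0L) {
    return(list(bursting_percent = 0, mean_spikes_per_burst = 0,
                n_bursts = 0L, no_bursts = TRUE))
  }
  sizes <- vapply(bursts, function(b) length(b$spike_indices), integer(1))
  pct <- if (n_spikes_total > 0) 100 * sum(sizes) / n_spikes_total else 0
  list(bursting_percent = pct,
       mean_spikes_per_burst = mean(sizes),
       n_bursts = n_bursts,
       no_bursts = FALSE)
}

#' Standardized firing-rate change for a behavioral epoch
#'
#' Symmetric contrast ratio `(fr_epoch - fr_baseline) / (fr_epoch +
#' fr_baseline)`, bounded in `[-1, 1]`, zero iff the epoch rate equals
#' baseline, and antisymmetric under swapping the two rates.  Alternative
#' forms are available through `method` (`"ratio"`: `a/b`;
#' `"relative"`: `(a-b)/b`).
#'
#' @param fr_epoch,fr_baseline non-negative rates (Hz), not both zero.
#' @param method one of `"contrast"` (default), `"ratio"`, `"relative"`.
#' @return numeric; `NA` when both rates are zero (undefined, excluded).
#' @examples
#' delta_fr(6, 4)  # 0.2
#' @export
delta_fr <- function(fr_epoch, fr_baseline, method = c("contrast", "ratio",
                                                       "relative")) {
  method <- match.arg(method)
  stopifnot(fr_epoch >= 0, fr_baseline >= 0)
  if (fr_epoch == 0 && fr_baseline == 0) return(NA_real_)
  switch(method,
         contrast = (fr_epoch - fr_baseline) / (fr_epoch + fr_baseline),
         ratio    = fr_epoch / fr_baseline,
         relative = (fr_epoch - fr_baseline) / fr_baseline)
}

# validate an epoch-window list: named list of 2-column matrices of
# half-open [start, end) intervals, non-overlapping within an epoch
validate_epoch_windows <- function(windows) {
  stopifnot(is.list(windows), length(names(windows)) == length(windows))
  for (ep in names(windows)) {
    w <- windows[[ep]]
    if (is.null(dim(w))) w <- matrix(w, ncol = 2, byrow = TRUE)
    stopifnot(ncol(w) == 2L)
    if (any(w[, 2] <= w[, 1]))
      stop("epoch '", ep, "': intervals must have positive length")
    if (nrow(w) > 1L) {
      o <- order(w[, 1])
      if (any(w[o, 1][-1] < w[o, 2][-nrow(w)]))
        stop("epoch '", ep, "': overlapping intervals")
    }
    windows[[ep]] <- w
  }
  windows
}

#' Epoch-aligned firing-rate table for one unit
#'
#' Pools each epoch's intervals (total spikes over total duration) to a
#' single rate, and reports the standardized change versus the baseline
#' epoch.  Intervals are half-open `[start, end)`.
#'
#' @param spike_times numeric, sorted, seconds.
#' @param windows named list mapping epoch name to a 2-column matrix of
#'   `[start, end)` intervals (s); must contain a `baseline` entry.
#' @param method contrast method passed to [delta_fr()].
#' @return data.frame with columns `epoch`, `n_spikes`, `duration`, `fr`,
#'   `delta_fr` (NA for baseline).
#' @export
epoch_firing_table <- function(spike_times, windows, method = "contrast") {
  windows <- validate_epoch_windows(windows)
  if (!"baseline" %in% names(windows))
    stop("windows must contain a 'baseline' epoch")
  pooled <- lapply(windows, function(w) {
    counts <- vapply(seq_len(nrow(w)), function(i) {
      sum(spike_times >= w[i, 1] & spike_times < w[i, 2])
    }, numeric(1))
    dur <- sum(w[, 2] - w[, 1])
    if (dur <= 0) stop("epoch with zero total duration")
    c(n = sum(counts), dur = dur)
  })
  fr <- vapply(pooled, function(p) p[["n"]] / p[["dur"]], numeric(1))
  fr_base <- fr[["baseline"]]
  out <- data.frame(
    epoch = names(windows),
    n_spikes = vapply(pooled, `[[`, numeric(1), "n"),
    duration = vapply(pooled, `[[`, numeric(1), "dur"),
    fr = unname(fr),
    stringsAsFactors = FALSE
  )
  out$delta_fr <- ifelse(
    out$epoch == "baseline", NA_real_,
    vapply(out$fr, function(f) delta_fr(f, fr_base, method = method),
           numeric(1))
  )
  rownames(out) <- NULL
  out
}
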