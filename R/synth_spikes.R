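#' Synthetic mean spike waveform of requested full AP width
#'
#' Piecewise-linear template: a triangular main deflection, optionally
#' followed by a triangular undershoot (after-hyperpolarization), sampled at
#' `dt_us`.  The base of the main deflection is solved analytically so that
#' [spike_width()] at the 10\% threshold recovers `width_ms` up to one
#' sample interval.
#'
#' @param width_ms requested full AP width (ms).
#' @param undershoot logical; add an undershoot lobe (slow-AP signature).
#' @param undershoot_depth undershoot depth as a fraction of the main peak.
#' @param undershoot_base_ms base duration of the undershoot lobe (ms).
#' @param dt_us sampling interval (microseconds/sample).
#' @param amp peak amplitude (arbitrary units).
#' @param pad_ms flat padding on each side (ms).
#' @param threshold_frac width-measurement threshold the base is solved for.
#' @return numeric waveform vector with attribute `dt_us`.
#' @export
make_waveform <- function(width_ms, undershoot = FALSE,
                          undershoot_depth = 0.3, undershoot_base_ms = 1.2,
                          dt_us = 25, amp = 1, pad_ms = 0.5,
                          threshold_frac = 0.1) {
  th <- threshold_frac
  if (undershoot) {
    d <- undershoot_depth
    u <- undershoot_base_ms
    # width = (1 - th/2)*b + (u/2)*(2d - th)/d  (threshold crossings on the
    # rising main flank and the falling undershoot flank)
    b <- (width_ms - (u / 2) * (2 * d - th) / d) / (1 - th / 2)
    if (b <= 0)
      stop("width_ms too small for the requested undershoot lobe")
  } else {
    b <- width_ms / (1 - th)   # crossings at th*b/2 and b - th*b/2
    u <- 0
    d <- 0
  }
  total_ms <- pad_ms + b + u + pad_ms
  t <- seq(0, total_ms, by = dt_us / 1000)
  v <- numeric(length(t))
  # main triangle on [pad, pad + b]
  s <- (t - pad_ms) / (b / 2)
  v[s >= 0 & s <= 1] <- amp * s[s >= 0 & s <= 1]
  v[s > 1 & s <= 2] <- amp * (2 - s[s > 1 & s <= 2])
  if (undershoot) {
    s2 <- (t - pad_ms - b) / (u / 2)
    v[s2 > 0 & s2 <= 1] <- -amp * d * s2[s2 > 0 & s2 <= 1]
    v[s2 > 1 & s2 <= 2] <- -amp * d * (2 - s2[s2 > 1 & s2 <= 2])
  }
  attr(v, "dt_us") <- dt_us
  v
}

# homogeneous Poisson process on [t0, t1)
sim_poisson_train <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# renewal process with dead time: ISI = dead + Exp(lambda), mean rate = rate
sim_deadtime_train <- function(rate, t0, t1, dead) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  if (rate * dead >= 1)
    stop("rate too high for dead time ", dead, " s")
  lambda <- rate / (1 - rate * dead)
  # draw enough ISIs in one go, extend if the window is not yet covered
  times <- numeric(0)
  t <- t0
  repeat {
    k <- max(16L, ceiling((t1 - t) * rate * 1.5))
    isi <- dead + stats::rexp(k, lambda)
    tt <- t + cumsum(isi)
    times <- c(times, tt[tt < t1])
    t <- tt[length(tt)]
    if (t >= t1) break
  }
  times
}

#' Behavioral epoch windows for the recording session
#'
#' Baseline covers `[0, baseline_dur)`.  The retrieval session
#' (`[baseline_dur, baseline_dur + assay_dur)`) contains one
#' approach / retrieval / post-interaction cycle per pup, spaced evenly.
#'
#' @param cfg [sim_config()].
#' @return named list of 2-column `[start, end)` interval matrices with
#'   epochs `baseline`, `approach`, `retrieval`, `post_interaction`.
#' @export
make_epoch_windows <- function(cfg) {
  t0 <- cfg$baseline_dur
  cycle <- cfg$assay_dur / max(1L, cfg$n_pups)
  starts <- t0 + (seq_len(max(1L, cfg$n_pups)) - 1) * cycle
  windows <- list(
    baseline = matrix(c(0, cfg$baseline_dur), ncol = 2),
    approach = cbind(starts, starts + 10),
    retrieval = cbind(starts + 10, starts + 20),
    post_interaction = cbind(starts + 20, starts + 50)
  )
  validate_epoch_windows(windows)
}

# piecewise-constant rate profile implied by epoch windows and gains:
# data.frame(start, end, gain), covering [0, t_end)
rate_segments <- function(windows, epoch_gain, t_end) {
  brk <- c(0, t_end)
  gains <- list()
  for (ep in names(windows)) {
    if (ep == "baseline") next
    w <- windows[[ep]]
    brk <- c(brk, w[, 1], w[, 2])
    for (i in seq_len(nrow(w)))
      gains[[length(gains) + 1L]] <-
        c(start = unname(w[i, 1]), end = unname(w[i, 2]),
          gain = unname(epoch_gain[[ep]]))
  }
  brk <- sort(unique(brk))
  seg <- data.frame(start = brk[-length(brk)], end = brk[-1], gain = 1)
  for (g in gains) {
    hit <- seg$start >= g[["start"]] & seg$end <= g[["end"]]
    seg$gain[hit] <- g[["gain"]]
  }
  seg
}

#' Generate a synthetic single-unit spike dataset with ground truth
#'
#' Emulates a mixed VTA population: narrow-spiking units fire as homogeneous
#' Poisson processes; wide-spiking units fire tonic spikes with an enforced
#' dead time just above the burst ISI threshold, plus injected bursts
#' (`spikes_per_burst` spikes at `intra_burst_isi` ms spacing); fast-firing
#' units are Poisson at `fr_fast`.  Behavioral epochs rescale rates by
#' `epoch_gain`.  Injected bursts are kept clear of tonic spikes by more
#' than the ISI threshold, so under the burst-detection rule every injected
#' burst — and nothing else — is detected.
#'
#' @param cfg [sim_config()].
#' @return list with `trains` (list of `spike_train` objects: `unit_id`,
#'   `spike_times`, `waveform`, `dt_us`, `class_true`), `windows` (epoch
#'   windows), and `truth` (per-unit list: class, true width, tonic rate,
#'   injected burst spike indices, per-epoch expected rates).
#' @export
gen_spike_dataset <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "spikes"))
  windows <- make_epoch_windows(cfg)
  t_end <- cfg$baseline_dur + cfg$assay_dur
  isi_max <- 0.080
  dead <- isi_max + 0.005
  classes <- c("narrow", "wide", "fast")
  base_fr <- c(narrow = cfg$fr_narrow, wide = cfg$fr_wide,
               fast = cfg$fr_fast)
  burst_span <- (cfg$spikes_per_burst - 1) * cfg$intra_burst_isi / 1000
  if (burst_span > 0.160)
    stop("configured bursts exceed the 160-ms span cap")
  seg <- rate_segments(windows, cfg$epoch_gain, t_end)

  trains <- list()
  truth <- list()
  uid <- 0L
  for (cl in classes) {
    for (k in seq_len(cfg$n_units_per_class)) {
      uid <- uid + 1L
      width_true <- max(0.3, stats::rnorm(1, cfg$width_means[[cl]],
                                          cfg$width_sds[[cl]]))
      wf <- make_waveform(width_true, undershoot = (cl == "wide"))
      rate <- base_fr[[cl]]
      tonic <- unlist(lapply(seq_len(nrow(seg)), function(i) {
        r <- rate * seg$gain[i]
        if (cl == "wide") {
          sim_deadtime_train(r, seg$start[i], seg$end[i], dead)
        } else {
          sim_poisson_train(r, seg$start[i], seg$end[i])
        }
      }))
      burst_times <- list()
      if (cl == "wide" && cfg$burst_rate > 0) {
        starts <- sim_poisson_train(cfg$burst_rate, 0, t_end - burst_span)
        # keep bursts mutually separated beyond the ISI threshold
        keep <- rep(TRUE, length(starts))
        if (length(starts) > 1L) {
          last <- starts[1]
          for (i in seq_along(starts)[-1]) {
            if (starts[i] - last < burst_span + 2 * dead) {
              keep[i] <- FALSE
            } else last <- starts[i]
          }
        }
        starts <- starts[keep]
        # burst sizes vary between 2 and the configured maximum
        sizes <- if (cfg$spikes_per_burst > 2L) {
          sample(2:cfg$spikes_per_burst, length(starts), replace = TRUE)
        } else rep(2L, length(starts))
        burst_times <- lapply(seq_along(starts), function(i)
          starts[i] + (seq_len(sizes[i]) - 1) *
            cfg$intra_burst_isi / 1000)
        if (length(burst_times)) {
          bt <- sort(unlist(burst_times))
          # clear tonic spikes within `dead` of any burst spike (both
          # vectors sorted: check the nearest burst spike on each side)
          pos <- findInterval(tonic, bt)
          d_lo <- ifelse(pos >= 1L, tonic - bt[pmax(pos, 1L)], Inf)
          d_hi <- ifelse(pos < length(bt), bt[pmin(pos + 1L, length(bt))] -
                           tonic, Inf)
          tonic <- tonic[pmin(d_lo, d_hi) >= dead]
        }
      }
      spikes <- sort(c(tonic, unlist(burst_times)))
      burst_idx <- lapply(burst_times, function(b)
        findInterval(b, spikes))
      epoch_rates <- vapply(names(windows), function(ep) {
        g <- if (ep == "baseline") 1 else cfg$epoch_gain[[ep]]
        rate * g
      }, numeric(1))
      trains[[uid]] <- structure(list(
        unit_id = sprintf("u%03d", uid),
        spike_times = spikes,
        waveform = wf,
        dt_us = attr(wf, "dt_us"),
        class_true = cl
      ), class = "spike_train")
      truth[[uid]] <- list(
        unit_id = sprintf("u%03d", uid),
        class = cl,
        width_true = width_true,
        tonic_rate = rate,
        epoch_rates = epoch_rates,
        burst_spike_indices = burst_idx
      )
    }
  }
  list(trains = trains, windows = windows, truth = truth)
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train ", x$unit_id, ": ", length(x$spike_times), " spikes",
      if (!is.null(x$class_true)) paste0(" (true class ", x$class_true, ")"),
      "\n", sep = "")
  invisible(x)
}
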