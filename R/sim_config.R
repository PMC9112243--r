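#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators.  Defaults mirror
#' the assay conditions of the emulated experiment: a 10-min baseline
#' recording followed by a 15-min pup retrieval session with four foster
#' pups, a 5-min retrieval test window for behavioral scoring, and unit
#' populations whose spike widths form two modes at 0.9 and 1.6 ms.
#'
#' One global `seed` streams into independent per-generator substreams (see
#' [substream_seed()]), so adding calls to one generator never perturbs the
#' output of another.
#'
#' @param seed integer; fixes all generator output bit-for-bit.
#' @param n_units_per_class units simulated per class (narrow, wide, fast).
#' @param fr_narrow,fr_wide,fr_fast baseline firing rates (Hz) per class.
#' @param width_means,width_sds named numeric vectors (`narrow`, `wide`,
#'   `fast`), spike-width template means and SDs in ms.
#' @param burst_rate injected bursts per second for wide units (bursts/s).
#' @param intra_burst_isi spacing of spikes inside an injected burst (ms).
#' @param spikes_per_burst maximum spikes per injected burst (sizes vary
#'   between 2 and this maximum).
#' @param baseline_dur,assay_dur baseline and retrieval-session recording
#'   durations (s).
#' @param epoch_gain named non-negative multipliers applied to a unit's rate
#'   inside each behavioral epoch (`approach`, `retrieval`,
#'   `post_interaction`).
#' @param n_pups foster pups per retrieval test.
#' @param test_duration behavioral test window (s); retrieval latency is
#'   censored here.
#' @param p_fail probability that a pup approach ends in failure (either no
#'   retrieval or a drop).
#' @param approach_rate dam approach attempts per second.
#' @param rear_rate,sniff_rate rearing and sniffing rates (events/min).
#' @param usv_n_per_category calls generated per category.
#' @param usv_jitter_khz frequency jitter SD on call contours (kHz).
#' @param tree_depth branching depth of generated dendritic trees.
#' @param branch_len mean branch segment length (micron).
#' @param soma_radius soma radius (micron).
#' @param n_cells cells in generated marker tables.
#' @param p_gal probability a DAPI+ cell is galanin-positive.
#' @param p_cfos probability a Gal+ cell is c-Fos positive.
#' @param expr_fractions data.frame (gene, cluster, sex, fraction) giving
#'   the per-group probability that a cell expresses a gene; `NULL` uses a
#'   deterministic default panel over clusters i8/i16/i18 and both sexes.
#' @param n_cells_per_group cells per (cluster, sex) group in generated
#'   count matrices.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion (size)
#'   of nonzero expression counts.
#' @return object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_pups = 4)
#' cfg$p_fail
#' @export
sim_config <- function(seed = 1L,
                       n_units_per_class = 20L,
                       fr_narrow = 6, fr_wide = 4, fr_fast = 15,
                       width_means = c(narrow = 0.9, wide = 1.6, fast = 0.9),
                       width_sds = c(narrow = 0.05, wide = 0.05, fast = 0.05),
                       burst_rate = 0.2,
                       intra_burst_isi = 20,
                       spikes_per_burst = 3L,
                       baseline_dur = 600,
                       assay_dur = 900,
                       epoch_gain = c(approach = 1.2, retrieval = 1.5,
                                      post_interaction = 0.8),
                       n_pups = 4L,
                       test_duration = 300,
                       p_fail = 0.15,
                       approach_rate = 1 / 20,
                       rear_rate = 8,
                       sniff_rate = 12,
                       usv_n_per_category = 50L,
                       usv_jitter_khz = 0.3,
                       tree_depth = 4L,
                       branch_len = 30,
                       soma_radius = 8,
                       n_cells = 500L,
                       p_gal = 0.2,
                       p_cfos = 0.45,
                       expr_fractions = NULL,
                       n_cells_per_group = 300L,
                       nb_mean = 2,
                       nb_dispersion = 1) {
  num <- function(x) stats::setNames(as.numeric(x), names(x))
  cfg <- list(
    seed = as.integer(seed),
    n_units_per_class = as.integer(n_units_per_class),
    fr_narrow = num(fr_narrow), fr_wide = num(fr_wide),
    fr_fast = num(fr_fast),
    width_means = num(width_means), width_sds = num(width_sds),
    burst_rate = num(burst_rate), intra_burst_isi = num(intra_burst_isi),
    spikes_per_burst = as.integer(spikes_per_burst),
    baseline_dur = num(baseline_dur), assay_dur = num(assay_dur),
    epoch_gain = num(epoch_gain),
    n_pups = as.integer(n_pups), test_duration = num(test_duration),
    p_fail = num(p_fail), approach_rate = num(approach_rate),
    rear_rate = num(rear_rate), sniff_rate = num(sniff_rate),
    usv_n_per_category = as.integer(usv_n_per_category),
    usv_jitter_khz = num(usv_jitter_khz),
    tree_depth = as.integer(tree_depth), branch_len = num(branch_len),
    soma_radius = num(soma_radius),
    n_cells = as.integer(n_cells), p_gal = num(p_gal),
    p_cfos = num(p_cfos),
    expr_fractions = expr_fractions,
    n_cells_per_group = as.integer(n_cells_per_group),
    nb_mean = num(nb_mean), nb_dispersion = num(nb_dispersion)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(p_fail = cfg$p_fail, p_gal = cfg$p_gal, p_cfos = cfg$p_cfos)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  rates <- c(cfg$fr_narrow, cfg$fr_wide, cfg$fr_fast, cfg$burst_rate,
             cfg$approach_rate, cfg$rear_rate, cfg$sniff_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (any(cfg$epoch_gain < 0)) stop("epoch_gain must be non-negative")
  if (cfg$intra_burst_isi <= 0 || cfg$intra_burst_isi >= 80)
    stop("intra_burst_isi must lie in (0, 80) ms for unambiguous bursts")
  if (cfg$n_pups < 0L) stop("n_pups must be >= 0")
  if (cfg$tree_depth < 0L) stop("tree_depth must be >= 0")
  if (!is.null(cfg$expr_fractions)) {
    ef <- cfg$expr_fractions
    stopifnot(is.data.frame(ef),
              all(c("gene", "cluster", "sex", "fraction") %in% names(ef)))
    if (any(ef$fraction < 0 | ef$fraction > 1))
      stop("expr_fractions$fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed ", x$seed, ")\n", sep = "")
  cat("  ephys  : ", x$n_units_per_class, " units/class; FR narrow/wide/fast = ",
      x$fr_narrow, "/", x$fr_wide, "/", x$fr_fast, " Hz\n", sep = "")
  cat("  behavior: ", x$n_pups, " pups; p_fail = ", x$p_fail,
      "; test ", x$test_duration, " s\n", sep = "")
  cat("  usv    : ", x$usv_n_per_category, " calls/category\n", sep = "")
  cat("  tree   : depth ", x$tree_depth, ", branch ", x$branch_len,
      " um\n", sep = "")
  invisible(x)
}

#' Derive an independent substream seed
#'
#' Maps a global seed and a generator name to a reproducible 31-bit seed,
#' so each generator draws from its own stream and generators do not
#' perturb one another.
#'
#' @param seed global integer seed.
#' @param stream character name of the generator stream.
#' @return integer in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 69621) %% 2147483647)
}
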