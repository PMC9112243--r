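test_that("identical seeds give bit-identical generator output", {
  cfg <- sim_config(seed = 7, n_units_per_class = 2L,
                    usv_n_per_category = 3L, n_cells = 40L,
                    n_cells_per_group = 10L)
  for (gen in list(gen_spike_dataset, gen_behavior_log, gen_usv_calls,
                   gen_morphology, gen_cell_table)) {
    expect_identical(gen(cfg), gen(cfg))
  }
  e1 <- gen_expression(cfg); e2 <- gen_expression(cfg)
  expect_identical(SummarizedExperiment::assay(e1, "counts"),
                   SummarizedExperiment::assay(e2, "counts"))
})

test_that("generators draw from independent substreams", {
  cfg <- sim_config(seed = 7, n_units_per_class = 2L)
  log1 <- gen_behavior_log(cfg)
  invisible(gen_spike_dataset(cfg))      # interleaved call, other stream
  log2 <- gen_behavior_log(cfg)
  expect_identical(log1, log2)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(p_fail = 1.2), "probabilities")
  expect_error(sim_config(fr_wide = -1), "rates")
  expect_error(sim_config(epoch_gain = c(approach = -0.5, retrieval = 1,
                                         post_interaction = 1)),
               "epoch_gain")
})

test_that("zero burst rate injects no bursts; injected bursts are exactly
           the detector's findings", {
  cfg0 <- sim_config(seed = 3, n_units_per_class = 3L, burst_rate = 0)
  ds0 <- gen_spike_dataset(cfg0)
  wide0 <- which(vapply(ds0$truth, `[[`, character(1), "class") == "wide")
  for (i in wide0) {
    expect_length(ds0$truth[[i]]$burst_spike_indices, 0)
    expect_length(detect_bursts(ds0$trains[[i]]$spike_times), 0)
  }
  cfg <- sim_config(seed = 4, n_units_per_class = 3L, burst_rate = 0.2)
  ds <- gen_spike_dataset(cfg)
  wide <- which(vapply(ds$truth, `[[`, character(1), "class") == "wide")
  for (i in wide) {
    detected <- detect_bursts(ds$trains[[i]]$spike_times)
    det_idx <- lapply(detected, `[[`, "spike_indices")
    true_idx <- lapply(ds$truth[[i]]$burst_spike_indices, as.integer)
    expect_equal(lapply(det_idx, as.integer), true_idx)
  }
})

test_that("empirical firing rates match configured rates within 3 SE", {
  # Poisson SE per unit is sqrt(rate/T); the across-unit mean shrinks it by
  # sqrt(n). Narrow units are plain Poisson; wide units are checked with
  # bursts disabled.
  cfg <- sim_config(seed = 5, n_units_per_class = 50L, fr_wide = 5,
                    burst_rate = 0)
  ds <- gen_spike_dataset(cfg)
  cls <- vapply(ds$truth, `[[`, character(1), "class")
  iv <- c(0, cfg$baseline_dur)
  for (cl in c("narrow", "wide")) {
    target <- if (cl == "narrow") cfg$fr_narrow else cfg$fr_wide
    frs <- vapply(ds$trains[cls == cl], function(tr)
      firing_rate(tr$spike_times, iv), numeric(1))
    se <- sqrt(target / cfg$baseline_dur / length(frs))
    expect_lt(abs(mean(frs) - target), 3 * se)
  }
})

test_that("epoch gains modulate rates as configured", {
  cfg <- sim_config(seed = 6, n_units_per_class = 100L, fr_narrow = 5,
                    epoch_gain = c(approach = 2, retrieval = 2,
                                   post_interaction = 2))
  ds <- gen_spike_dataset(cfg)
  cls <- vapply(ds$truth, `[[`, character(1), "class")
  narrow <- ds$trains[cls == "narrow"]
  tabs <- lapply(narrow, function(tr)
    epoch_firing_table(tr$spike_times, ds$windows))
  fr_retr <- vapply(tabs, function(tb)
    tb$fr[tb$epoch == "retrieval"], numeric(1))
  dur <- sum(ds$windows$retrieval[, 2] - ds$windows$retrieval[, 1])
  se <- sqrt(10 / dur / length(fr_retr))
  expect_lt(abs(mean(fr_retr) - 10), 3 * se)
})

test_that("behavior generator honors failure probability extremes", {
  cfg0 <- sim_config(seed = 8, p_fail = 0)
  log0 <- gen_behavior_log(cfg0)
  expect_equal(log0$truth$n_failures, 0)
  expect_equal(relative_failure_index(log0)$index, 0)
  cfg1 <- sim_config(seed = 8, p_fail = 1)
  log1 <- gen_behavior_log(cfg1)
  expect_equal(log1$truth$n_retrieved, 0)
  lat <- latency_all_pups(log1)
  expect_true(lat$censored)
  expect_equal(lat$latency, cfg1$test_duration)
})

test_that("failure fraction concentrates at p_fail for many approaches", {
  # many pups and a certain-failure-free test window give ~binomial(n, p)
  cfg <- sim_config(seed = 9, p_fail = 0.5, n_pups = 10000L,
                    approach_rate = 1000, test_duration = 300)
  log <- gen_behavior_log(cfg)
  n_appr <- log$truth$n_failures + log$truth$n_retrieved
  phat <- log$truth$n_failures / n_appr
  se <- sqrt(0.5 * 0.5 / n_appr)
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("morphology generator ground truth matches brute-force length", {
  cfg <- sim_config(seed = 10, tree_depth = 0L)
  m0 <- gen_morphology(cfg)
  expect_equal(nrow(m0$nodes), 1)
  expect_equal(attr(m0, "truth")$total_length, 0)
  expect_equal(dendrite_metrics(m0)$cumulative_length, 0)
  for (s in 1:5) {
    m <- gen_morphology(sim_config(seed = s, tree_depth = 4L))
    expect_equal(attr(m, "truth")$total_length, tree_length_oracle(m))
    expect_equal(dendrite_metrics(m)$n_nodes,
                 attr(m, "truth")$n_branch_points)
  }
})

test_that("usv archetypes satisfy their defining geometry", {
  cfg <- sim_config(seed = 11, usv_n_per_category = 10L,
                    usv_jitter_khz = 0)
  calls <- gen_usv_calls(cfg)
  for (cl in calls) {
    f <- cl$contour$freq_hz
    if (cl$category_true == "flat")
      expect_equal(max(f) - min(f), 0)
    if (cl$category_true == "upward")
      expect_gt(f[length(f)], f[1])
    if (cl$category_true == "downward")
      expect_lt(f[length(f)], f[1])
    if (cl$category_true == "chevron") {
      imax <- which.max(f)
      expect_gt(imax, 1)
      expect_lt(imax, length(f))
    }
  }
})

test_that("cell-table marker flags respect the conditional structure", {
  cfg <- sim_config(seed = 12, p_cfos = 1, n_cells = 200L)
  tab <- gen_cell_table(cfg)
  expect_true(all(tab$dapi))
  expect_true(all(tab$cfos[tab$gal]))       # p_cfos = 1
  expect_true(all(!tab$cfos[!tab$gal]))     # cfos only scored in Gal+
})

test_that("expression generator hits configured expressing fractions", {
  ef <- expand.grid(gene = c("Tlr3", "Stat1"), cluster = "i8", sex = 0L,
                    stringsAsFactors = FALSE)
  ef$fraction <- c(0.6, 0)
  cfg <- sim_config(seed = 13, expr_fractions = ef,
                    n_cells_per_group = 2000L)
  sce <- gen_expression(cfg)
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd <- SummarizedExperiment::colData(sce)
  sel <- cd$cluster == "i8" & cd$sex == 0L
  expect_equal(sum(counts["Stat1", sel]), 0)
  phat <- mean(counts["Tlr3", sel] > 0)
  se <- sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(phat - 0.6), 3 * se)
})
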