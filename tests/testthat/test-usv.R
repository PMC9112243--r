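flat_call <- function(dur = 0.03, f = 70e3, n = 20, amp = NULL) {
  usv_call(data.frame(t = seq(0, dur, length.out = n),
                      freq_hz = rep(f, n),
                      amp = if (is.null(amp)) rep(1, n) else amp),
           call_id = "c1", litter_id = "L1")
}

test_that("call metrics report duration, amplitude and peak frequency", {
  tt <- seq(0, 0.040, length.out = 5)
  cl <- usv_call(data.frame(t = tt, freq_hz = c(60, 65, 70, 75, 80) * 1e3,
                            amp = c(0.1, 0.5, 2, 0.5, 0.1)))
  met <- call_metrics(cl)
  expect_equal(met$duration, 0.040)
  expect_equal(met$mean_linear_amplitude, mean(c(0.1, 0.5, 2, 0.5, 0.1)))
  expect_equal(met$freq_at_max_peak, 70e3)
  # amplitude ties resolve to the earliest time
  cl2 <- flat_call(amp = rep(3, 20))
  expect_equal(call_metrics(cl2)$freq_at_max_peak, 70e3)
  expect_error(usv_call(data.frame(t = 0, freq_hz = 1, amp = 1)))
})

test_that("the decision tree assigns the six categories", {
  n <- 20; tt <- seq(0, 0.03, length.out = n); s <- seq(0, 1, length.out = n)
  expect_equal(classify_call(flat_call()), "flat")
  expect_equal(classify_call(flat_call(dur = 0.003)), "short")
  up <- usv_call(data.frame(t = tt, freq_hz = (50 + 30 * s) * 1e3,
                            amp = rep(1, n)))
  expect_equal(classify_call(up), "upward")
  down <- usv_call(data.frame(t = tt, freq_hz = (80 - 30 * s) * 1e3,
                              amp = rep(1, n)))
  expect_equal(classify_call(down), "downward")
  chev <- usv_call(data.frame(t = tt,
                              freq_hz = (70 + 10 * sin(pi * s)) * 1e3,
                              amp = rep(1, n)))
  expect_equal(classify_call(chev), "chevron")
  cplx <- usv_call(data.frame(t = tt,
                              freq_hz = (70 + 8 * sin(2.5 * pi * s)) * 1e3,
                              amp = rep(1, n)))
  expect_equal(classify_call(cplx), "complex")
})

test_that("classification is invariant to time shift and amplitude scale", {
  cfg <- sim_config(seed = 14, usv_n_per_category = 5L)
  for (cl in gen_usv_calls(cfg)) {
    shifted <- cl
    shifted$contour$t <- shifted$contour$t + 1.23
    shifted$contour$amp <- shifted$contour$amp * 40
    expect_equal(classify_call(shifted), classify_call(cl))
  }
})

test_that("each call receives exactly one category", {
  cfg <- sim_config(seed = 15, usv_n_per_category = 20L)
  cats <- vapply(gen_usv_calls(cfg), classify_call, character(1))
  expect_true(all(cats %in% c("short", "flat", "chevron", "complex",
                              "upward", "downward")))
})

test_that("litter summary counts and means are conserved", {
  cfg <- sim_config(seed = 16, usv_n_per_category = 10L)
  calls <- gen_usv_calls(cfg, n_litters = 2L)
  summ <- litter_summary(calls)
  per_litter_n <- tapply(summ$n_calls[summ$category != "all"],
                         summ$litter_id[summ$category != "all"], sum)
  all_n <- summ$n_calls[summ$category == "all"]
  names(all_n) <- summ$litter_id[summ$category == "all"]
  expect_equal(as.numeric(per_litter_n[names(all_n)]),
               as.numeric(all_n))
  expect_equal(sum(all_n), length(calls))
  # pooled means equal the count-weighted per-category means
  for (lt in unique(summ$litter_id)) {
    sub <- summ[summ$litter_id == lt & summ$category != "all" &
                  summ$n_calls > 0, ]
    pooled <- summ[summ$litter_id == lt & summ$category == "all", ]
    expect_equal(sum(sub$n_calls * sub$mean_duration) / sum(sub$n_calls),
                 pooled$mean_duration)
  }
  # empty categories are flagged absent
  empties <- summ[summ$n_calls == 0, ]
  if (nrow(empties)) expect_true(all(is.na(empties$mean_duration)))
})

test_that("generated call durations equal the contour span exactly and
           contours round-trip through CSV", {
  cfg <- sim_config(seed = 17, usv_n_per_category = 4L)
  calls <- gen_usv_calls(cfg)
  for (cl in calls) {
    expect_equal(call_metrics(cl)$duration,
                 max(cl$contour$t) - min(cl$contour$t))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(calls, path)
  back <- read_contours(path)
  expect_length(back, length(calls))
  orig <- calls[[3]]
  rt <- back[[orig$call_id]]
  expect_equal(rt$contour$freq_hz, orig$contour$freq_hz)
  expect_equal(classify_call(rt), classify_call(orig))
})
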