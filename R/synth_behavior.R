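#' Generate a synthetic pup-retrieval event log with ground truth
#'
#' The dam makes approach attempts at exponential waiting times
#' (`approach_rate` attempts/s), each directed at the next unretrieved pup.
#' An attempt fails with probability `p_fail` (split evenly between
#' returning without the pup, `approach_no_retrieve`, and dropping it,
#' `drop`); otherwise the pup is retrieved.  Approaches stop once all pups
#' are retrieved or the test window ends.  Rearing and sniffing are
#' independent Poisson event streams over the whole test.
#'
#' @param cfg [sim_config()].
#' @return `behavior_log`: list with `events` (time-sorted data.frame
#'   `t`, `kind`, `pup_id`), `n_pups`, `test_duration`, and `truth`
#'   (failure count, retrieval times, rear/sniff times).
#' @export
gen_behavior_log <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_pups < 1L) stop("n_pups must be >= 1")
  set.seed(substream_seed(cfg$seed, "behavior"))
  td <- cfg$test_duration
  ev_t <- numeric(0); ev_k <- character(0); ev_p <- integer(0)

  t <- 0
  retrieved <- 0L
  n_fail <- 0L
  retrieval_times <- numeric(0)
  while (retrieved < cfg$n_pups) {
    t <- t + stats::rexp(1, cfg$approach_rate)
    if (t >= td) break
    pup <- retrieved + 1L
    if (stats::runif(1) < cfg$p_fail) {
      n_fail <- n_fail + 1L
      kind <- if (stats::runif(1) < 0.5) "approach_no_retrieve" else "drop"
    } else {
      kind <- "retrieve"
      retrieved <- retrieved + 1L
      retrieval_times <- c(retrieval_times, t)
    }
    ev_t <- c(ev_t, t); ev_k <- c(ev_k, kind); ev_p <- c(ev_p, pup)
  }

  rears <- sim_poisson_train(cfg$rear_rate / 60, 0, td)
  sniffs <- sim_poisson_train(cfg$sniff_rate / 60, 0, td)
  ev_t <- c(ev_t, rears, sniffs)
  ev_k <- c(ev_k, rep("rear", length(rears)), rep("sniff", length(sniffs)))
  ev_p <- c(ev_p, rep(NA_integer_, length(rears) + length(sniffs)))

  o <- order(ev_t)
  log <- structure(list(
    events = data.frame(t = ev_t[o], kind = ev_k[o], pup_id = ev_p[o],
                        stringsAsFactors = FALSE),
    n_pups = cfg$n_pups,
    test_duration = td,
    truth = list(n_failures = n_fail,
                 n_retrieved = retrieved,
                 retrieval_times = retrieval_times,
                 rear_times = rears,
                 sniff_times = sniffs)
  ), class = "behavior_log")
  validate_behavior_log(log)
  log
}

validate_behavior_log <- function(log) {
  stopifnot(inherits(log, "behavior_log"),
            is.data.frame(log$events),
            all(c("t", "kind") %in% names(log$events)))
  ev <- log$events
  if (any(ev$t < 0 | ev$t > log$test_duration))
    stop("event times must lie within [0, test_duration]")
  if (is.unsorted(ev$t)) stop("events must be time-sorted")
  if (sum(ev$kind == "retrieve") > log$n_pups)
    stop("more retrieve events than pups")
  invisible(log)
}

#' @export
print.behavior_log <- function(x, ...) {
  cat("behavior_log: ", nrow(x$events), " events, ", x$n_pups,
      " pups, ", x$test_duration, " s test\n", sep = "")
  print(table(x$events$kind))
  invisible(x)
}
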