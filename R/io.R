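#' Tabular interchange readers and writers
#'
#' Plain-CSV carriers for the pipeline's inputs: spike times
#' (`unit_id, t_s`), behavioral events (`t_s, kind, pup_id`), USV contours
#' (`call_id, litter_id, pup_id, t_s, freq_hz, amp`) and marker cell
#' tables.  All writers round-trip losslessly through the matching reader.
#'
#' @param trains list of `spike_train` objects.
#' @param path file path.
#' @return the reader returns the reconstructed object(s); writers return
#'   `path` invisibly.
#' @name matcare-io
NULL

#' @rdname matcare-io
#' @export
write_spike_times <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(unit_id = tr$unit_id,
               t_s = sprintf("%.17g", tr$spike_times))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname matcare-io
#' @export
read_spike_times <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df$t_s, df$unit_id), function(t)
    structure(list(unit_id = NULL, spike_times = sort(as.numeric(t)),
                   waveform = NULL, dt_us = NULL),
              class = "spike_train"))
}

#' @rdname matcare-io
#' @param log `behavior_log`.
#' @export
write_events <- function(log, path) {
  utils::write.csv(data.frame(t_s = sprintf("%.17g", log$events$t),
                              kind = log$events$kind,
                              pup_id = log$events$pup_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname matcare-io
#' @param n_pups,test_duration assay constants for the rebuilt log.
#' @export
read_events <- function(path, n_pups, test_duration = 300) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  behavior_log(data.frame(t = df$t_s, kind = df$kind, pup_id = df$pup_id),
               n_pups = n_pups, test_duration = test_duration)
}

#' @rdname matcare-io
#' @param calls list of `usv_call` objects.
#' @export
write_contours <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(cl)
    data.frame(call_id = cl$call_id, litter_id = cl$litter_id,
               pup_id = cl$pup_id,
               t_s = sprintf("%.17g", cl$contour$t),
               freq_hz = sprintf("%.17g", cl$contour$freq_hz),
               amp = sprintf("%.17g", cl$contour$amp))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matcare-io
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$call_id), function(d)
    usv_call(data.frame(t = d$t_s, freq_hz = d$freq_hz, amp = d$amp),
             call_id = d$call_id[1], litter_id = d$litter_id[1],
             pup_id = d$pup_id[1]))
}

#' @rdname matcare-io
#' @param table cell table data.frame.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matcare-io
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname matcare-io
#' @param cfg [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_sim_config requires the jsonlite package")
  validate_sim_config(cfg)
  x <- unclass(cfg)
  # named vectors must serialize as JSON objects, not bare arrays
  for (f in c("width_means", "width_sds", "epoch_gain"))
    x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname matcare-io
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("read_sim_config requires the jsonlite package")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("width_means", "width_sds", "epoch_gain"))
    raw[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$expr_fractions))
    raw$expr_fractions <- as.data.frame(raw$expr_fractions)
  do.call(sim_config, raw)
}

#' @rdname matcare-io
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param counts_path,meta_path output CSVs for the counts (genes x cells)
#'   and the per-cell metadata.
#' @export
write_expression <- function(sce, counts_path, meta_path) {
  m <- SummarizedExperiment::assay(sce, "counts")
  utils::write.csv(as.data.frame(m), counts_path, row.names = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cbind(cell_id = rownames(cd), cd)
  utils::write.csv(cd, meta_path, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname matcare-io
#' @export
read_expression <- function(counts_path, meta_path) {
  m <- as.matrix(utils::read.csv(counts_path, row.names = 1,
                                 check.names = FALSE))
  storage.mode(m) <- "integer"
  cd <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  rownames(cd) <- cd$cell_id
  cd$cell_id <- NULL
  stopifnot(identical(colnames(m), rownames(cd)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cd))
}
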