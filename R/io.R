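#' @name io
#' @title Plain-text interchange formats
#'
#' @description
#' Every stage reads and writes tab-separated text so intermediate results
#' are diffable and portable: spectral-count tables (`protein_id`,
#' `length_aa`, `spc_*`, `pep_*`), long-format screen plates
#' (`experiment_id`, `bait`, `prey`, `od650`, blank wells encoded as
#' bait = prey = "BLANK", the control column as bait = "AP-only"),
#' pull-down tables (`protein_id`, `spc_bait_*`, `spc_ctrl_*`), BLI series
#' (`concentration_uM`, `response_nm[, ...reps]`), and enrichment result
#' tables (infinite fold changes round-trip as the literal "Inf").
NULL

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read / write a spectral-count table
#' @param table Spectral-count data.frame.
#' @param path File path.
#' @return `read_spectral_counts()` returns the data.frame;
#'   writers return `path` invisibly.
#' @export
write_spectral_counts <- function(table, path) {
  check_count_table(table)
  write_tsv(table, path)
}

#' @rdname write_spectral_counts
#' @export
read_spectral_counts <- function(path) {
  check_count_table(read_tsv(path))
}

#' Write screen experiments in long format
#'
#' One row per well: `experiment_id`, `bait`, `prey`, `od650`. Blank wells
#' are encoded with bait = prey = `"BLANK"`; control wells carry
#' bait = `"AP-only"`.
#'
#' @param experiments List of [screen_experiment()] objects.
#' @param path File path.
#' @export
write_screen_long <- function(experiments, path) {
  rows <- lapply(experiments, function(e) {
    od <- e$od_matrix
    wells <- expand.grid(prey = rownames(od), bait = colnames(od),
                         stringsAsFactors = FALSE)
    rbind(
      data.frame(experiment_id = e$experiment_id, bait = wells$bait,
                 prey = wells$prey, od650 = as.vector(od),
                 stringsAsFactors = FALSE),
      data.frame(experiment_id = e$experiment_id, bait = "BLANK",
                 prey = "BLANK", od650 = e$blank_values,
                 stringsAsFactors = FALSE)
    )
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read screen experiments from long format
#'
#' @param path File written by [write_screen_long()] (or any file honoring
#'   the same contract).
#' @return List of [screen_experiment()] objects, ordered by experiment id.
#' @export
read_screen_long <- function(path) {
  long <- read_tsv(path)
  need <- c("experiment_id", "bait", "prey", "od650")
  if (!all(need %in% names(long))) {
    stop_field("path", "screen file needs experiment_id, bait, prey, od650")
  }
  lapply(split(long, long$experiment_id)[unique(long$experiment_id)],
         function(d) {
           blanks <- d$od650[d$bait == "BLANK" & d$prey == "BLANK"]
           wells <- d[d$bait != "BLANK" & d$prey != "BLANK", , drop = FALSE]
           preys <- sort(unique(wells$prey))
           baits <- c(sort(setdiff(unique(wells$bait), AP_ONLY)), AP_ONLY)
           od <- matrix(NA_real_, length(preys), length(baits),
                        dimnames = list(preys, baits))
           od[cbind(wells$prey, wells$bait)] <- wells$od650
           if (anyNA(od)) stop_field("path", "incomplete bait x prey grid")
           screen_experiment(d$experiment_id[1], od, blanks)
         })
}

#' Read / write a pull-down spectral-count table
#' @param table Pull-down data.frame.
#' @param path File path.
#' @export
write_pulldown <- function(table, path) {
  check_pulldown_table(table)
  write_tsv(table, path)
}

#' @rdname write_pulldown
#' @export
read_pulldown <- function(path) {
  check_pulldown_table(read_tsv(path))
}

#' Read / write a BLI binding series
#'
#' Columns `concentration_uM` then one or more response columns
#' (`response_nm`, `response_nm_rep2`, ...). The optional buffer-only
#' point is stored as a row with concentration 0 and is split back out on
#' reading.
#'
#' @param series A [binding_series()].
#' @param path File path.
#' @export
write_bli_series <- function(series, path) {
  resp <- series$responses
  if (!is.matrix(resp)) resp <- matrix(resp, ncol = 1)
  colnames(resp) <- c("response_nm",
                      if (ncol(resp) > 1) {
                        sprintf("response_nm_rep%d", seq_len(ncol(resp))[-1] )
                      })
  out <- data.frame(concentration_uM = series$concentrations, resp,
                    check.names = FALSE)
  if (!is.null(series$buffer_response)) {
    buf <- out[1, , drop = FALSE]
    buf[1, ] <- c(0, rep(series$buffer_response, ncol(resp)))
    out <- rbind(out, buf)
  }
  write_tsv(out, path)
}

#' @rdname write_bli_series
#' @export
read_bli_series <- function(path) {
  d <- read_tsv(path)
  if (!"concentration_uM" %in% names(d)) {
    stop_field("path", "BLI file needs a concentration_uM column")
  }
  resp_cols <- grep("^response_nm", names(d), value = TRUE)
  if (!length(resp_cols)) stop_field("path", "BLI file needs response_nm column(s)")
  is_buffer <- d$concentration_uM == 0
  buffer <- if (any(is_buffer)) mean(as.matrix(d[is_buffer, resp_cols])) else NULL
  d <- d[!is_buffer, , drop = FALSE]
  resp <- as.matrix(d[, resp_cols, drop = FALSE])
  if (ncol(resp) == 1) resp <- as.numeric(resp)
  binding_series(d$concentration_uM, resp, buffer_response = buffer)
}

#' Read / write an enrichment result table
#'
#' Infinite log2 fold changes (exclusively detected proteins) serialize as
#' the literal strings `"Inf"`/`"-Inf"` and parse back losslessly.
#'
#' @param x An `enrichment_table`.
#' @param path File path.
#' @export
write_enrichment <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  d <- read_tsv(path)
  d$log2fc <- as.numeric(d$log2fc)
  class(d) <- c("enrichment_table", "data.frame")
  d
}

#' Write interaction calls and the network edge list
#'
#' @param calls data.frame from [merge_experiments()] (optionally after
#'   novelty annotation via the network).
#' @param path File path.
#' @export
write_calls <- function(calls, path) {
  write_tsv(calls, path)
}
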