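## Delimited-text readers and writers for the pipeline's tables, with
## schema validation, plus a config echo so every output directory records
## the parameters that produced it.

#' Read a fluorescence trace table
#'
#' Comma-separated with a header row; required columns `cell_id`, `frame`,
#' `time_min`, `donor`, `acceptor`; optional `direct_acceptor`,
#' `background_donor`, `background_acceptor`. Validates column presence,
#' numeric types, and strictly increasing time within each cell, reporting
#' offending rows.
#'
#' @param path file path.
#' @return validated trace table (data frame).
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "frame", "time_min", "donor", "acceptor")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("trace table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in setdiff(names(tab), "cell_id")) {
    if (!is.numeric(tab[[cn]])) stop("column '", cn, "' is not numeric")
  }
  bad <- unlist(lapply(split(seq_len(nrow(tab)), tab$cell_id), function(i) {
    i[c(FALSE, diff(tab$time_min[i]) <= 0)]
  }))
  if (length(bad) > 0) {
    stop("time not strictly increasing within a cell at row(s): ",
         paste(utils::head(sort(bad), 10), collapse = ", "))
  }
  tab
}

#' Write a trace table (or any pipeline table) as CSV
#'
#' @param table data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate-reader growth table
#'
#' Comma-separated with columns `time_h`, `od` and optional `well`; one
#' [growth_curve()] per well.
#'
#' @param path file path.
#' @param blank optional known blank OD applied to every well.
#' @return named list of [growth_curve()] objects.
#' @export
read_growth_table <- function(path, blank = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_h", "od")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("growth table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$well)) tab$well <- "well_1"
  lapply(split(tab, tab$well), function(w) {
    w <- w[order(w$time_h), , drop = FALSE]
    growth_curve(w$time_h, w$od, blank = blank, well = w$well[1])
  })
}

#' Read a flow-cytometry event table
#'
#' Comma-separated with columns `fsc`, `ssc`, `donor_ch`, `fret_ch`,
#' `direct_acceptor_ch`, `strain`, `condition`.
#'
#' @param path file path.
#' @return validated event table.
#' @export
read_flow_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fsc", "ssc", "donor_ch", "fret_ch", "direct_acceptor_ch",
                "strain", "condition")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("flow table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(tab[, c("fsc", "ssc", "donor_ch", "fret_ch",
                                       "direct_acceptor_ch")])))) {
    stop("non-finite channel values in flow table")
  }
  class(tab) <- c("flow_events", "data.frame")
  tab
}

#' Echo a parameter set to a config file
#'
#' Writes the (named, possibly nested) parameter list as YAML next to the
#' outputs it produced, so every artifact is accompanied by the exact
#' configuration behind it.
#'
#' @param params named list.
#' @param path output path (YAML).
#' @return the path, invisibly.
#' @export
write_config <- function(params, path) {
  drop_class <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_class)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  yaml::write_yaml(drop_class(params), path)
  invisible(path)
}
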