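#' Right-censored survival datasets
#'
#' A `survival_dataset` is a data frame with columns `id`, `time` (years,
#' strictly positive), `event` (1 = event observed, 0 = censored), `arm` and
#' `endpoint` (`"OS"`, `"PFS"` or `"TTD"`).
#'
#' @param time positive event/censoring times in years.
#' @param event 0/1 event indicators.
#' @param arm arm label.
#' @param endpoint one of `"OS"`, `"PFS"`, `"TTD"`.
#' @param id optional subject identifiers (default `1:n`).
#' @return a data frame of class `survival_dataset`.
#' @export
survival_dataset <- function(time, event, arm = "arm", endpoint = "OS",
                             id = seq_along(time)) {
  assert_that(length(time) >= 1, "dataset must contain at least one record",
              class = "partsurv_invalid")
  assert_that(all(is.finite(time)) && all(time > 0),
              "all times must be finite and > 0", class = "partsurv_invalid")
  event <- as.integer(event)
  assert_that(length(event) == length(time) && all(event %in% c(0L, 1L)),
              "event must be 0/1 and match time in length",
              class = "partsurv_invalid")
  assert_that(endpoint %in% c("OS", "PFS", "TTD"),
              "endpoint must be OS, PFS or TTD", class = "partsurv_invalid")
  out <- data.frame(id = id, time = as.numeric(time), event = event,
                    arm = as.character(arm), endpoint = endpoint,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_dataset", "data.frame")
  out
}

as_survival_dataset <- function(df) {
  survival_dataset(df$time, df$event,
                   arm = df$arm[1] %||% "arm",
                   endpoint = df$endpoint[1] %||% "OS",
                   id = df$id %||% seq_len(nrow(df)))
}

#' Digitised Kaplan-Meier curve
#'
#' The form in which survival evidence is extracted from a publication figure:
#' step coordinates of the published KM curve plus the numbers-at-risk table
#' printed beneath it, and (optionally) the total event count reported in the
#' text. Numbers at risk at a reported time `t > 0` count subjects still under
#' observation strictly beyond `t`, i.e. after any events plotted at `t`.
#'
#' @param coords data frame with columns `time`, `surv`; must start at
#'   `(0, 1)` with non-increasing survival.
#' @param risk_table data frame with columns `time`, `n_risk`; non-increasing,
#'   first entry positive.
#' @param total_events optional total number of events, if reported.
#' @return an object of class `digitized_curve`.
#' @export
digitized_curve <- function(coords, risk_table, total_events = NULL) {
  coords <- as.data.frame(coords)[, c("time", "surv")]
  risk_table <- as.data.frame(risk_table)[, c("time", "n_risk")]
  assert_that(nrow(coords) >= 1 && coords$time[1] == 0 && coords$surv[1] == 1,
              "coords must start at (0, 1)", class = "partsurv_invalid")
  assert_that(!is.unsorted(coords$time, strictly = TRUE),
              "coord times must be strictly increasing",
              class = "partsurv_invalid")
  assert_that(all(diff(coords$surv) <= 1e-12),
              "digitised survival must be non-increasing",
              class = "partsurv_invalid")
  assert_that(all(coords$surv >= -1e-12 & coords$surv <= 1 + 1e-12),
              "survival must lie in [0, 1]", class = "partsurv_invalid")
  assert_that(nrow(risk_table) >= 1 && risk_table$n_risk[1] > 0,
              "risk table needs a positive first entry",
              class = "partsurv_invalid")
  assert_that(!is.unsorted(risk_table$time, strictly = TRUE),
              "risk-table times must be strictly increasing",
              class = "partsurv_invalid")
  assert_that(all(diff(risk_table$n_risk) <= 0),
              "numbers at risk must be non-increasing",
              class = "partsurv_invalid")
  if (!is.null(total_events))
    assert_that(is_number(total_events) && total_events >= 0,
                "total_events must be a non-negative number",
                class = "partsurv_invalid")
  structure(list(coords = coords, risk_table = risk_table,
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("<digitized_curve> ", nrow(x$coords), " coordinates, ",
      nrow(x$risk_table), " risk-table entries",
      if (!is.null(x$total_events)) paste0(", ", x$total_events, " events"),
      "\n", sep = "")
  invisible(x)
}

#' Read / write survival datasets and digitised curves
#'
#' Delimited-text interchange formats: a `survival_dataset` is one
#' tab-separated table (`id`, `time`, `event`, `arm`, `endpoint`); a
#' `digitized_curve` is two tables (coordinates and risk table) plus an
#' optional event-count comment line.
#'
#' @param x object to write.
#' @param path file path (for curves, a stem: `<stem>_coords.tsv` and
#'   `<stem>_risk.tsv`).
#' @return the path (write) or the object (read).
#' @export
write_survival_dataset <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_dataset
#' @export
read_survival_dataset <- function(path) {
  as_survival_dataset(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname write_survival_dataset
#' @export
write_digitized_curve <- function(x, path) {
  utils::write.table(x$coords, paste0(path, "_coords.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rt <- x$risk_table
  if (!is.null(x$total_events)) rt$total_events <-
      c(x$total_events, rep(NA, nrow(rt) - 1))
  utils::write.table(rt, paste0(path, "_risk.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_dataset
#' @export
read_digitized_curve <- function(path) {
  coords <- utils::read.delim(paste0(path, "_coords.tsv"))
  rt <- utils::read.delim(paste0(path, "_risk.tsv"))
  te <- if ("total_events" %in% names(rt)) rt$total_events[1]
  rt <- rt[, c("time", "n_risk")]
  if (!is.null(te) && is.na(te)) te <- NULL
  digitized_curve(coords, rt, total_events = te)
}
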