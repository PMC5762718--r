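# CSV/YAML/JSON interfaces. All CSV outputs carry a provenance header line
# "# turnwatch config_hash=<md5>" computed from the configuration that
# produced them; readers skip comment lines.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

write_with_header <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# turnwatch config_hash=%s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_csv_skip_comments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) <= 1)
    stop("empty table in ", path, " (a header alone is not a cohort)")
  utils::read.csv(text = lines, stringsAsFactors = FALSE)
}

#' Write position traces to CSV
#'
#' One row per sample, columns \code{patient_id}, \code{timestamp} (ISO-8601
#' UTC), \code{t_s}, \code{angle_deg}, \code{posture}.
#'
#' @param traces Named list of [patient_trace()] objects.
#' @param path Output CSV path.
#' @param config Optional configuration object hashed into the provenance
#'   header.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(traces, path, config = NULL) {
  rows <- lapply(traces, function(tr) {
    t0 <- attr(tr, "start_time")
    data.frame(patient_id = attr(tr, "patient_id"),
               timestamp = format(t0 + tr$t_s, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               t_s = tr$t_s, angle_deg = tr$angle_deg, posture = tr$posture,
               stringsAsFactors = FALSE)
  })
  write_with_header(do.call(rbind, rows), path, config_hash(config))
  invisible(path)
}

#' Read position traces from CSV
#'
#' Inverse of [write_trace_csv()]: validates required columns, per-patient
#' timestamp ordering and duplicates (reporting the offending row), and
#' returns one [patient_trace()] per patient.
#'
#' @param path CSV path.
#' @param sample_interval_s Sampling interval used for validation.
#' @return Named list of [patient_trace()] objects.
#' @export
read_trace_csv <- function(path, sample_interval_s = 10) {
  df <- read_csv_skip_comments(path)
  need <- c("patient_id", "timestamp", "t_s", "angle_deg", "posture")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (pid in unique(df$patient_id)) {
    sub <- df[df$patient_id == pid, , drop = FALSE]
    d <- diff(sub$t_s)
    if (any(d <= 0)) {
      i <- which(d <= 0)[1]
      row <- rownames(sub)[i + 1]
      stop(sprintf(
        "%s timestamps for patient %s at file row %s (t_s = %g after %g)",
        if (d[i] == 0) "duplicate" else "out-of-order",
        pid, row, sub$t_s[i + 1], sub$t_s[i]))
    }
    t0 <- as.POSIXct(sub$timestamp[1], format = "%Y-%m-%dT%H:%M:%SZ",
                     tz = "UTC") - sub$t_s[1]
    out[[pid]] <- patient_trace(sub$t_s, sub$angle_deg, sub$posture,
                                patient_id = pid, start_time = t0,
                                sample_interval_s = sample_interval_s)
  }
  out
}

#' Write/read exemption-interval and patient-record CSVs
#'
#' @param exemptions Named list (by patient id) of [exemption_intervals()]
#'   tables.
#' @param records Patient-record data frame.
#' @param path CSV path.
#' @param config Optional configuration hashed into the provenance header.
#' @return The path (writers, invisibly); a named list of exemption tables or
#'   a data frame (readers).
#' @name exemption_io
NULL

#' @rdname exemption_io
#' @export
write_exemption_csv <- function(exemptions, path, config = NULL) {
  rows <- lapply(names(exemptions), function(pid) {
    ex <- exemptions[[pid]]
    if (nrow(ex) == 0) return(NULL)
    cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE), ex)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), start_s = numeric(),
               end_s = numeric(), reason = character())
  write_with_header(df, path, config_hash(config))
  invisible(path)
}

#' @rdname exemption_io
#' @export
read_exemption_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  split_ex <- split(df, df$patient_id)
  lapply(split_ex, function(sub)
    exemption_intervals(sub$start_s, sub$end_s, sub$reason))
}

#' @rdname exemption_io
#' @export
write_record_csv <- function(records, path, config = NULL) {
  write_with_header(records, path, config_hash(config))
  invisible(path)
}

#' @rdname exemption_io
#' @export
read_record_csv <- function(path) {
  read_csv_skip_comments(path)
}

#' Write a compliance timeline to CSV
#'
#' Columns \code{patient_id}, \code{start_s}, \code{end_s}, \code{state},
#' \code{display}.
#'
#' @param timelines Named list of [compliance_timeline()] objects.
#' @param path CSV path.
#' @param config Optional configuration hashed into the provenance header.
#' @return The path, invisibly.
#' @export
write_timeline_csv <- function(timelines, path, config = NULL) {
  rows <- lapply(names(timelines), function(pid) {
    tl <- timelines[[pid]]
    data.frame(patient_id = pid, start_s = tl$start_s, end_s = tl$end_s,
               state = tl$state, display = tl$display,
               stringsAsFactors = FALSE)
  })
  write_with_header(do.call(rbind, rows), path, config_hash(config))
  invisible(path)
}
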