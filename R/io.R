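# Delimited-text and TIFF input/output for the pipeline's data dialects.
# Event logs:   subject_id, session_id, group, event_type, time_s
# Traces:       time_s + one column per ROI
# Cell clouds:  animal_id, group, x_um, y_um, z_um, intensity, size_voxels
# Density matrices: first column = region, header = animal ids, groups in a
#                   '# groups:' comment line.

#' Write / read an event log
#'
#' Tab-delimited with header `subject_id, session_id, group, event_type,
#' time_s`.  Any file with the same header is accepted on read.
#'
#' @param stream an `event_stream` or a data.frame with those columns.
#' @param path file path.
#' @return `read_event_log` returns an `event_stream` (with unknown schedule
#'   and `press_labels` NA).
#' @export
write_event_log <- function(stream, path) {
  df <- if (inherits(stream, "event_stream")) stream$events else stream
  need <- c("subject_id", "session_id", "group", "event_type", "time_s")
  stopifnot(all(need %in% names(df)))
  utils::write.table(df[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "group", "event_type", "time_s")
  if (!all(need %in% names(df)))
    stop("event log must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$time_s), ]
  rownames(df) <- NULL
  structure(list(events = df,
                 press_labels = rep(NA_integer_,
                                    sum(df$event_type == "press")),
                 n_rewards = sum(df$event_type == "reward"),
                 session_end = if (nrow(df)) max(df$time_s) else 0,
                 schedule = NULL),
            class = "event_stream")
}

#' Write / read fluorescence traces
#'
#' Tab-delimited: `time_s` column followed by one column per ROI.
#'
#' @param traces frames x ROIs numeric matrix.
#' @param time frame times in seconds.
#' @param path file path.
#' @return `read_traces` returns a list with `traces`, `time`, and
#'   `sampling_rate` inferred from the time column.
#' @export
write_traces <- function(traces, time, path) {
  stopifnot(nrow(traces) == length(time))
  df <- data.frame(time_s = time, traces, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("trace file must start with a time_s column", call. = FALSE)
  time <- df$time_s
  traces <- as.matrix(df[-1])
  sr <- if (length(time) > 1L) 1 / stats::median(diff(time)) else NA_real_
  list(traces = traces, time = time, sampling_rate = sr)
}

#' Write / read a cell cloud
#'
#' Tab-delimited with header `animal_id, group, x_um, y_um, z_um, intensity,
#' size_voxels`.
#'
#' @param cloud data.frame with those columns.
#' @param path file path.
#' @export
write_cell_cloud <- function(cloud, path) {
  need <- c("animal_id", "group", "x_um", "y_um", "z_um", "intensity",
            "size_voxels")
  for (nm in setdiff(need, names(cloud))) cloud[[nm]] <- NA
  utils::write.table(cloud[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_cloud
#' @export
read_cell_cloud <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a region density matrix
#'
#' Tab-delimited: header row of animal ids (first column `region`), one row
#' per region; per-animal group labels kept in a `# groups:` comment line.
#'
#' @param mat a `region_density` matrix.
#' @param path file path.
#' @export
write_density_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "region_density"))
  con <- file(path, "w")
  on.exit(close(con))
  groups <- attr(mat, "groups") %||% rep(NA_character_, ncol(mat))
  writeLines(paste0("# groups: ", paste(groups, collapse = "\t")), con)
  writeLines(paste0("# zscored: ", isTRUE(attr(mat, "zscored"))), con)
  df <- data.frame(region = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_matrix
#' @export
read_density_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  groups <- NULL
  zscored <- FALSE
  g <- grep("^# groups: ", hdr, value = TRUE)
  if (length(g)) groups <- strsplit(sub("^# groups: ", "", g[1]), "\t")[[1]]
  z <- grep("^# zscored: ", hdr, value = TRUE)
  if (length(z)) zscored <- identical(sub("^# zscored: ", "", z[1]), "TRUE")
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$region
  structure(m, groups = groups, zscored = zscored,
            class = c("region_density", "matrix", "array"))
}

#' Write / read a movie or volume as multi-page TIFF
#'
#' Values are stored as 32-bit floats scaled by `scale` into the TIFF's
#' \[0, 1\] range; the same `scale` must be supplied on read to recover the
#' original units.
#'
#' @param a 3-D array (rows x cols x pages).
#' @param path file path.
#' @param scale intensity that maps to 1.0 (default the array max).
#' @return `read_stack` returns the array; `write_stack` returns the scale
#'   used, invisibly.
#' @export
write_stack <- function(a, path, scale = NULL) {
  stopifnot(length(dim(a)) == 3L)
  scale <- scale %||% max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(i) pmin(pmax(a[, , i] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  arr
}
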