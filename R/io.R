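#' Read and write transducer coordinate tables
#'
#' Delimited text with header `index,x_mm,y_mm,z_mm[,delay_us]`, one row
#' per element, preceded by a `#` comment stating the units. Coordinates
#' are always mm and delays us in files.
#'
#' @param x an [array_geometry], a `calibration_result`, or a data.frame
#'   with the columns above.
#' @param path file path.
#' @param estimated for a `calibration_result`/geometry, write the
#'   estimated positions (default) rather than the designed ones.
#' @return `write_transducer_positions` returns `path` invisibly;
#'   `read_transducer_positions` returns a data.frame with columns
#'   `index`, `x_mm`, `y_mm`, `z_mm` and (if present) `delay_us`.
#' @export
write_transducer_positions <- function(x, path, estimated = TRUE) {
  if (inherits(x, "calibration_result")) {
    g <- x$geometry
    pos <- if (estimated) x$positions else g$positions
    df <- data.frame(index = g$index, x_mm = pos[, 1], y_mm = pos[, 2],
                     z_mm = pos[, 3], delay_us = g$receive_delays)
  } else if (inherits(x, "array_geometry")) {
    pos <- if (estimated && !is.null(x$estimated_positions)) {
      x$estimated_positions
    } else x$positions
    df <- data.frame(index = x$index, x_mm = pos[, 1], y_mm = pos[, 2],
                     z_mm = pos[, 3], delay_us = x$receive_delays)
  } else {
    df <- as.data.frame(x)
    need <- c("index", "x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(df))) {
      stop("invalid input: need columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# transducer coordinates; positions in mm, delays in us", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transducer_positions
#' @export
read_transducer_positions <- function(path) {
  df <- .read_units_csv(path, c("index", "x_mm", "y_mm", "z_mm"))
  df
}

#' Read and write point-source grid tables
#'
#' Delimited text with header `index,x_mm,y_mm,z_mm` (stage-frame
#' coordinates in mm).
#'
#' @param grid a [point_source_grid] or a matrix of positions.
#' @param path file path.
#' @return `read_source_grid` returns a [point_source_grid].
#' @export
write_source_grid <- function(grid, path) {
  pos <- if (inherits(grid, "point_source_grid")) grid$positions else .as_xyz(grid, "grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# point-source grid; stage-frame coordinates in mm", con)
  utils::write.csv(data.frame(index = seq_len(nrow(pos)), x_mm = pos[, 1],
                              y_mm = pos[, 2], z_mm = pos[, 3]),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_source_grid
#' @export
read_source_grid <- function(path) {
  df <- .read_units_csv(path, c("index", "x_mm", "y_mm", "z_mm"))
  point_source_grid(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

#' Read and write time-of-arrival tables
#'
#' Long delimited text, one row per (source, transducer) pair:
#' `source_index,transducer_index,toa_us,valid`.
#'
#' @param toas a [toa_matrix].
#' @param path file path.
#' @return `read_toa_table` returns a [toa_matrix].
#' @export
write_toa_table <- function(toas, path) {
  stopifnot(inherits(toas, "toa_matrix"))
  m <- nrow(toas$times); n <- ncol(toas$times)
  df <- data.frame(source_index = rep(seq_len(m), n),
                   transducer_index = rep(seq_len(n), each = m),
                   toa_us = as.numeric(toas$times),
                   valid = as.logical(toas$valid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# times of arrival in us", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_toa_table
#' @export
read_toa_table <- function(path) {
  df <- .read_units_csv(path, c("source_index", "transducer_index",
                                "toa_us", "valid"))
  m <- max(df$source_index); n <- max(df$transducer_index)
  times <- matrix(NA_real_, m, n)
  valid <- matrix(FALSE, m, n)
  idx <- cbind(df$source_index, df$transducer_index)
  times[idx] <- df$toa_us
  valid[idx] <- as.logical(df$valid)
  toa_matrix(times, valid)
}

#' Read and write waveform sets and volumes
#'
#' Binary round-trip storage of the large array containers using R's
#' native serialization. Readers validate the class of the stored object.
#'
#' @param x a [waveform_set] or `volume`.
#' @param path file path (conventionally `.rds`).
#' @return readers return the stored object; writers return `path`
#'   invisibly.
#' @export
write_waveform_set <- function(x, path) {
  stopifnot(inherits(x, "waveform_set"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_waveform_set
#' @export
read_waveform_set <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "waveform_set")) {
    stop("I/O error: ", path, " does not contain a waveform_set", call. = FALSE)
  }
  x
}

#' @rdname write_waveform_set
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "volume"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_waveform_set
#' @export
read_volume <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "volume")) {
    stop("I/O error: ", path, " does not contain a volume", call. = FALSE)
  }
  x
}

# csv with a leading "# units" comment; errors carry line numbers
.read_units_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  body <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (!length(body)) {
    stop("I/O error: ", path, ": no data (line 1)", call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(text = lines[body], stringsAsFactors = FALSE),
    error = function(e) {
      stop("I/O error: ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("I/O error: ", path, " (line ", body[1], "): missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(required, "valid")
  for (cc in num) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad)) {
      stop("I/O error: ", path, " (line ", body[1 + bad[1]],
           "): non-numeric value in column ", cc, call. = FALSE)
    }
    df[[cc]] <- v
  }
  df
}
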