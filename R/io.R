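#' Read a TRC-dialect marker file
#'
#' Tab-delimited marker trajectories with the conventional two-line header
#' pair (field names + values, including \code{DataRate}, \code{NumFrames},
#' \code{NumMarkers}, \code{Units}), a marker-name row with X/Y/Z triplet
#' columns, and a \code{Frame#}/\code{Time} body. Only the sagittal x/y
#' components are used; z is carried as written. Malformed headers,
#' duplicated labels, inconsistent column counts and non-monotonic time
#' raise parse errors naming the offending line.
#'
#' @param path file path.
#' @return a \code{\link{marker_series}}.
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 6) stop("parse error (", path, "): truncated header")
  hdr_fields <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_fields[seq_along(hdr_vals)])
  rate <- as.numeric(hdr$DataRate)
  if (!is.finite(rate)) stop("parse error (", path, ", line 3): bad DataRate")
  name_row <- strsplit(lines[4], "\t")[[1]]
  markers <- name_row[-(1:2)]
  markers <- markers[nzchar(markers)]
  if (anyDuplicated(markers))
    stop("parse error (", path, ", line 4): duplicated marker label '",
         markers[duplicated(markers)][1], "'")
  body_start <- 6L
  while (body_start <= length(lines) && !nzchar(trimws(lines[body_start])))
    body_start <- body_start + 1L
  rows <- lines[body_start:length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  ncols <- 2 + 3 * length(markers)
  parsed <- lapply(seq_along(rows), function(i) {
    f <- strsplit(rows[i], "\t")[[1]]
    if (length(f) != ncols)
      stop("parse error (", path, ", line ", body_start + i - 1,
           "): expected ", ncols, " columns, found ", length(f))
    as.numeric(f)
  })
  M <- do.call(rbind, parsed)
  time <- M[, 2]
  if (any(diff(time) <= 0))
    stop("parse error (", path, "): non-monotonic time column")
  n <- nrow(M)
  xy <- array(NA_real_, c(n, length(markers), 2))
  for (m in seq_along(markers)) {
    xy[, m, 1] <- M[, 2 + 3 * (m - 1) + 1]
    xy[, m, 2] <- M[, 2 + 3 * (m - 1) + 2]
  }
  marker_series(time, xy, markers)
}

#' Write a TRC-dialect marker file
#'
#' @param markers a \code{\link{marker_series}}.
#' @param path output path.
#' @param provenance optional named character vector appended to the
#'   header value row is not possible in TRC; it is recorded in a trailing
#'   comment-free sidecar field of the PathFileType line.
#' @export
write_trc <- function(markers, path, provenance = NULL) {
  n <- length(markers$time)
  m <- length(markers$names)
  rate <- markers$rate
  l1 <- paste("PathFileType", 4, "(X/Y/Z)", basename(path),
              if (!is.null(provenance))
                paste(names(provenance), provenance, sep = "=", collapse = ";"),
              sep = "\t")
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  l3 <- paste(sprintf("%.2f", rate), sprintf("%.2f", rate), n, m, "m",
              sprintf("%.2f", rate), 1, n, sep = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(markers$names, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", as.vector(t(outer(seq_len(m), c("X", "Y", "Z"),
                                          function(i, a) paste0(a, i))))),
              collapse = "\t")
  body <- vapply(seq_len(n), function(i) {
    vals <- as.vector(rbind(markers$xy[i, , 1], markers$xy[i, , 2], 0))
    paste(c(i, sprintf("%.12g", markers$time[i]), sprintf("%.12g", vals)),
          collapse = "\t")
  }, "")
  writeLines(c(l1, l2, l3, l4, l5, "", body), path)
  invisible(path)
}

#' Read a MOT/STO-dialect time-series file
#'
#' Header block of \code{key=value} lines terminated by \code{endheader},
#' then a tab-delimited table whose first column is \code{time}.
#'
#' @param path file path.
#' @return data.frame with attribute \code{header} (named list).
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (length(end) != 1)
    stop("parse error (", path, "): missing endheader line")
  hdr <- list(name = lines[1])
  for (ln in lines[seq(2, max(2, end - 1))]) {
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      hdr[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  labels <- strsplit(lines[end + 1], "\t")[[1]]
  if (anyDuplicated(labels))
    stop("parse error (", path, ", line ", end + 1,
         "): duplicated column label '", labels[duplicated(labels)][1], "'")
  rows <- lines[(end + 2):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  parsed <- lapply(seq_along(rows), function(i) {
    f <- strsplit(rows[i], "\t")[[1]]
    if (length(f) != length(labels))
      stop("parse error (", path, ", line ", end + 1 + i, "): expected ",
           length(labels), " columns, found ", length(f))
    as.numeric(f)
  })
  out <- as.data.frame(do.call(rbind, parsed))
  names(out) <- labels
  if ("time" %in% labels && any(diff(out$time) <= 0))
    stop("parse error (", path, "): non-monotonic time column")
  attr(out, "header") <- hdr
  out
}

#' Write a MOT/STO-dialect time-series file
#'
#' @param series data.frame whose first column is \code{time}.
#' @param path output path.
#' @param name dataset name written on line 1.
#' @param in_degrees whether angle columns are in degrees.
#' @param provenance named character vector of extra \code{key=value}
#'   header lines (e.g. config hash, defaults versions).
#' @export
write_mot <- function(series, path, name = basename(path),
                      in_degrees = TRUE, provenance = NULL) {
  stopifnot(is.data.frame(series), names(series)[1] == "time")
  hdr <- c(name,
           "version=1",
           paste0("nRows=", nrow(series)),
           paste0("nColumns=", ncol(series)),
           paste0("inDegrees=", if (in_degrees) "yes" else "no"))
  if (!is.null(provenance))
    hdr <- c(hdr, paste0(names(provenance), "=", provenance))
  body <- vapply(seq_len(nrow(series)), function(i) {
    paste(sprintf("%.12g", as.numeric(series[i, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, "endheader", paste(names(series), collapse = "\t"), body),
             path)
  invisible(path)
}

metrics_schema <- c("participant_id", "limb", "trial", "peak_pfj_bw",
                    "knee_angle_deg", "quad_force_bw", "approach_velocity_ms")

#' Read a metrics table (CSV)
#'
#' Comment lines starting with \code{#} (provenance) are skipped; the
#' required schema is validated.
#'
#' @param path CSV path.
#' @return metrics data.frame.
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(metrics_schema, names(d))
  if (length(missing))
    stop("parse error (", path, "): missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(d$limb), c("ACLR", "contralateral", "control"))
  if (length(bad))
    stop("parse error (", path, "): unknown limb label(s): ",
         paste(bad, collapse = ", "))
  d
}

#' Write a metrics table (CSV) with provenance comments
#'
#' @param metrics metrics data.frame (per-trial rows).
#' @param path output path.
#' @param provenance named character vector written as \code{# key=value}.
#' @export
write_metrics_csv <- function(metrics, path, provenance = NULL) {
  metrics <- normalize_metrics_table(metrics)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), "=", provenance), con)
  utils::write.csv(metrics[, intersect(c(metrics_schema,
                                         setdiff(names(metrics), metrics_schema)),
                                       names(metrics))],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write analysis results as full-precision JSON
#'
#' @param result a \code{limb_comparison}, \code{limb_report}, or plain
#'   list.
#' @param path output path.
#' @param provenance named list merged into the JSON under
#'   \code{provenance}.
#' @export
write_results_json <- function(result, path, provenance = NULL) {
  payload <- if (inherits(result, "limb_report")) {
    list(results = lapply(result$results, unclass_deep),
         summary = result$summary)
  } else unclass_deep(result)
  out <- list(provenance = provenance, payload = payload)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
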