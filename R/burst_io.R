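# -- burst container -----------------------------------------------------

new_acc_bursts <- function(meta, samples, log = list()) {
  stopifnot(is.data.frame(meta), is.list(samples),
            nrow(meta) == length(samples))
  rownames(meta) <- NULL
  structure(list(meta = meta, samples = samples),
            run_log = log, class = "acc_bursts")
}

#' Construct a set of acceleration bursts from in-memory data
#'
#' A burst is one fixed-length recording interval of a tri-axial
#' accelerometer (by default 110 samples per axis at 33.33 Hz, i.e. 3.3 s),
#' recorded on a duty cycle rather than continuously.
#'
#' @param meta Data frame with one row per burst: columns `burst_id`
#'   (unique), `animal_id`, `burst_start` (POSIXct, UTC), `sampling_rate`
#'   (Hz) and optionally `label`.
#' @param samples List of numeric matrices, one per burst, each with
#'   columns `x`, `y`, `z` and one row per sample.
#' @return An object of class `"acc_bursts"`.
#' @export
acc_bursts <- function(meta, samples) {
  req <- c("burst_id", "animal_id", "burst_start", "sampling_rate")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("meta is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"label" %in% names(meta)) meta$label <- NA_character_
  if (anyDuplicated(meta$burst_id)) stop("burst_id values must be unique")
  samples <- lapply(samples, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stop("each sample matrix must have 3 axis columns")
    colnames(m) <- c("x", "y", "z")
    storage.mode(m) <- "double"
    m
  })
  meta$n <- vapply(samples, nrow, integer(1))
  o <- order(meta$animal_id, meta$burst_start)
  new_acc_bursts(meta[o, , drop = FALSE], samples[o])
}

#' @export
print.acc_bursts <- function(x, ...) {
  n <- nrow(x$meta)
  cat("<acc_bursts> ", n, " bursts, ",
      length(unique(x$meta$animal_id)), " animal(s)\n", sep = "")
  if (n) {
    cat("  samples/axis: ", paste(unique(x$meta$n), collapse = ", "),
        "; sampling rate: ",
        paste(unique(x$meta$sampling_rate), collapse = ", "), " Hz\n", sep = "")
    lab <- x$meta$label
    if (any(!is.na(lab))) {
      tab <- table(lab[!is.na(lab)])
      cat("  labelled: ", sum(!is.na(lab)), " (",
          paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
length.acc_bursts <- function(x) nrow(x$meta)

#' Subset a burst set
#' @param x An `acc_bursts` object.
#' @param i Index vector over bursts (logical, integer or burst_id character).
#' @param ... Unused.
#' @return An `acc_bursts` object with the selected bursts.
#' @export
`[.acc_bursts` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$burst_id)
  new_acc_bursts(x$meta[i, , drop = FALSE], x$samples[i],
                 log = attr(x, "run_log"))
}

#' Duration of each burst in seconds
#'
#' Duration is the number of samples per axis divided by the sampling rate;
#' the canonical tag schedule (110 samples at 33.33 Hz) gives 3.3 s.
#'
#' @param bursts An `acc_bursts` object.
#' @return Numeric vector of durations (s), one per burst.
#' @examples
#' round(110 / 33.33, 2)  # 3.3
#' @export
burst_duration <- function(bursts) {
  bursts$meta$n / bursts$meta$sampling_rate
}

# -- structured run log --------------------------------------------------

#' Retrieve the structured run log of an object
#'
#' Readers and pipeline steps never drop records silently: every dropped or
#' excluded record is appended to a structured log carried on the returned
#' object.
#'
#' @param x An object returned by a reader or pipeline step.
#' @return A list of log entries (each a named list with at least `event`).
#' @export
run_log <- function(x) {
  lg <- attr(x, "run_log")
  if (is.null(lg)) list() else lg
}

append_log <- function(log, event, ...) {
  c(log, list(c(list(event = event), list(...))))
}

#' Write a run log as JSON lines
#'
#' @param log A list of log entries (see [run_log()]).
#' @param path Output file path; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (entry in log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  invisible(path)
}

# -- reading / writing ---------------------------------------------------

#' Default column mapping for long-format burst tables
#'
#' The canonical on-disk layout is a long CSV with one row per sample:
#' columns for animal id, burst id, burst start timestamp, within-burst
#' sample index and the three axis readings. A wide per-burst dialect
#' (one row per burst, sample columns `x_1..x_n`, `y_1..`, `z_1..`) is
#' accepted via `layout = "wide"` in [read_bursts()].
#'
#' @param animal_id,burst_id,burst_start,t_index,x,y,z Column names in the
#'   file for the respective fields.
#' @return Named character vector mapping canonical fields to file columns.
#' @export
burst_schema <- function(animal_id = "animal_id", burst_id = "burst_id",
                         burst_start = "burst_start", t_index = "t_index",
                         x = "x", y = "y", z = "z") {
  c(animal_id = animal_id, burst_id = burst_id, burst_start = burst_start,
    t_index = t_index, x = x, y = y, z = z)
}

parse_utc <- function(s) {
  t <- as.POSIXct(as.character(s), tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  t
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")

#' Read burst accelerometry from CSV
#'
#' Reads a long-format (one row per sample) or wide-format (one row per
#' burst) table, applies a per-collar clock offset to the burst start
#' timestamps, validates completeness, and returns bursts sorted by
#' (animal id, burst start). Bursts whose axes do not all have the expected
#' number of samples are dropped and counted in the run log — tag
#' timestamp drift itself is not corrected automatically; the offset is a
#' user supplied, per-file constant.
#'
#' @param path CSV file path (headered, UTF-8, ISO-8601 UTC timestamps).
#' @param schema Column mapping from [burst_schema()].
#' @param clock_offset Seconds added to every burst start time (default 0).
#' @param sampling_rate Sampling rate in Hz used when the file has no
#'   `sampling_rate` column (default 33.33).
#' @param n_expected Expected samples per axis; bursts of any other length
#'   are dropped. `NULL` (default) uses the modal burst length in the file.
#' @param layout `"long"` (canonical) or `"wide"`.
#' @return An `acc_bursts` object; dropped bursts are recorded in
#'   [run_log()].
#' @export
read_bursts <- function(path, schema = burst_schema(), clock_offset = 0,
                        sampling_rate = 33.33, n_expected = NULL,
                        layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  log <- list()

  if (layout == "wide") {
    need <- schema[c("animal_id", "burst_id", "burst_start")]
    miss <- setdiff(unname(need), names(df))
    if (length(miss))
      stop("schema error: missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    axis_cols <- function(axis) {
      cols <- grep(paste0("^", axis, "_\\d+$"), names(df), value = TRUE)
      cols[order(as.integer(sub(paste0(axis, "_"), "", cols)))]
    }
    xs <- axis_cols("x"); ys <- axis_cols("y"); zs <- axis_cols("z")
    if (!length(xs) || length(xs) != length(ys) || length(xs) != length(zs))
      stop("schema error: wide layout needs matching x_*, y_*, z_* columns")
    long <- data.frame(
      animal_id = rep(df[[need["animal_id"]]], each = length(xs)),
      burst_id = rep(as.character(df[[need["burst_id"]]]), each = length(xs)),
      burst_start = rep(df[[need["burst_start"]]], each = length(xs)),
      t_index = rep(seq_along(xs) - 1L, nrow(df)),
      x = as.vector(t(as.matrix(df[xs]))),
      y = as.vector(t(as.matrix(df[ys]))),
      z = as.vector(t(as.matrix(df[zs]))),
      stringsAsFactors = FALSE)
    if ("sampling_rate" %in% names(df))
      long$sampling_rate <- rep(df$sampling_rate, each = length(xs))
    df <- long
    schema <- burst_schema()
  }

  miss <- setdiff(unname(schema), names(df))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))

  for (ax in c("x", "y", "z")) {
    v <- df[[schema[ax]]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("parse error: non-numeric ", ax, " sample at row ", bad[1])
      df[[schema[ax]]] <- num
    }
  }

  bid <- as.character(df[[schema["burst_id"]]])
  ord <- order(match(bid, unique(bid)), df[[schema["t_index"]]])
  df <- df[ord, , drop = FALSE]
  bid <- bid[ord]
  idx <- split(seq_len(nrow(df)), factor(bid, levels = unique(bid)))

  rate_col <- if ("sampling_rate" %in% names(df)) df$sampling_rate else NULL
  meta_list <- vector("list", length(idx))
  samples <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    meta_list[[k]] <- data.frame(
      burst_id = names(idx)[k],
      animal_id = as.character(df[[schema["animal_id"]]][rows[1]]),
      burst_start = parse_utc(df[[schema["burst_start"]]][rows[1]]) +
        clock_offset,
      sampling_rate = if (is.null(rate_col)) sampling_rate else
        rate_col[rows[1]],
      stringsAsFactors = FALSE)
    samples[[k]] <- cbind(x = df[[schema["x"]]][rows],
                          y = df[[schema["y"]]][rows],
                          z = df[[schema["z"]]][rows])
  }
  meta <- do.call(rbind, meta_list)
  meta$label <- if ("label" %in% names(df))
    vapply(idx, function(rows) as.character(df$label[rows[1]]), character(1))
  else NA_character_

  n <- vapply(samples, nrow, integer(1))
  if (is.null(n_expected)) {
    tab <- table(n)
    n_expected <- as.integer(names(tab)[which.max(tab)])
  }
  bad <- which(n != n_expected)
  if (length(bad)) {
    log <- append_log(log, "bursts_dropped_incomplete",
                      n_dropped = length(bad),
                      burst_ids = meta$burst_id[bad],
                      expected_n = n_expected)
    keep <- setdiff(seq_along(samples), bad)
    meta <- meta[keep, , drop = FALSE]
    samples <- samples[keep]
  }
  if (clock_offset != 0)
    log <- append_log(log, "clock_offset_applied", seconds = clock_offset)

  out <- acc_bursts(meta, samples)
  attr(out, "run_log") <- log
  out
}

#' Write bursts to long-format CSV
#'
#' Inverse of [read_bursts()] for the canonical long layout: sample values
#' and timestamps round-trip (timestamps to 1 ms).
#'
#' @param bursts An `acc_bursts` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path) {
  meta <- bursts$meta
  n <- meta$n
  df <- data.frame(
    animal_id = rep(meta$animal_id, n),
    burst_id = rep(meta$burst_id, n),
    burst_start = rep(format_utc(meta$burst_start), n),
    sampling_rate = rep(meta$sampling_rate, n),
    t_index = unlist(lapply(n, function(k) seq_len(k) - 1L)),
    x = unlist(lapply(bursts$samples, function(m) m[, "x"])),
    y = unlist(lapply(bursts$samples, function(m) m[, "y"])),
    z = unlist(lapply(bursts$samples, function(m) m[, "z"])),
    stringsAsFactors = FALSE)
  if (any(!is.na(meta$label))) df$label <- rep(meta$label, n)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Attach observed behaviour labels to bursts
#'
#' Ground-truthing: each direct observation is linked to its burst by exact
#' timestamp match (after any clock offset applied at read time). A burst
#' receives a label iff exactly one observation matches its start time.
#' Observations listing more than one behaviour (separated by
#' `multi_sep`) mark mixed bursts, which are excluded entirely — they are
#' not characteristic of any single class.
#'
#' @param bursts An `acc_bursts` object.
#' @param observations Data frame with columns `animal_id`, `time`
#'   (POSIXct or ISO-8601 string) and `behaviour`.
#' @param ethogram An [ethogram()]; behaviours outside it are an error.
#' @param multi_sep Separator marking multi-behaviour observations
#'   (default `";"`).
#' @return An `acc_bursts` object containing the labelled bursts and the
#'   unmatched (unlabelled) bursts; mixed-behaviour bursts are removed and
#'   logged. Never invents labels: labelled count <= observation count.
#' @export
attach_labels <- function(bursts, observations, ethogram = NULL,
                          multi_sep = ";") {
  if (is.null(ethogram)) ethogram <- accbehav::ethogram()
  stopifnot(is_ethogram(ethogram))
  obs <- observations
  req <- c("animal_id", "time", "behaviour")
  miss <- setdiff(req, names(obs))
  if (length(miss))
    stop("observations missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(obs$time, "POSIXct")) obs$time <- parse_utc(obs$time)

  key_obs <- paste(obs$animal_id, round(as.numeric(obs$time) * 1000))
  if (anyDuplicated(key_obs))
    stop("observation timestamps must be unique per animal")

  single <- !grepl(multi_sep, obs$behaviour, fixed = TRUE)
  bad <- setdiff(obs$behaviour[single], ethogram$classes)
  if (length(bad))
    stop("label error: behaviour(s) not in ethogram: ",
         paste(unique(bad), collapse = ", "))

  meta <- bursts$meta
  key_b <- paste(meta$animal_id, round(as.numeric(meta$burst_start) * 1000))
  m <- match(key_b, key_obs)
  matched <- !is.na(m)
  mixed <- matched & !single[ifelse(is.na(m), 1L, m)]

  log <- run_log(bursts)
  if (any(mixed))
    log <- append_log(log, "bursts_excluded_mixed_behaviour",
                      n_excluded = sum(mixed),
                      burst_ids = meta$burst_id[mixed])

  label <- meta$label
  label[matched & !mixed] <- obs$behaviour[m[matched & !mixed]]
  keep <- !mixed
  meta$label <- label
  out <- new_acc_bursts(meta[keep, , drop = FALSE], bursts$samples[keep],
                        log = log)
  out
}

#' Read GPS fixes from CSV
#'
#' @param path CSV with columns `animal_id`, `time` (ISO-8601 UTC),
#'   `lat`, `lon` (decimal degrees).
#' @return Data frame of fixes sorted by (animal_id, time), with `time` as
#'   POSIXct UTC. Latitude/longitude range violations are an error.
#' @export
read_gps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("animal_id", "time", "lat", "lon"), names(df))
  if (length(miss))
    stop("GPS file missing column(s): ", paste(miss, collapse = ", "))
  df$time <- parse_utc(df$time)
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude out of range [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180))
    stop("longitude out of range [-180, 180]")
  df <- df[order(df$animal_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write GPS fixes to CSV
#' @param fixes Data frame as returned by [read_gps()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gps <- function(fixes, path) {
  fixes$time <- format_utc(fixes$time)
  utils::write.csv(fixes, path, row.names = FALSE)
  invisible(path)
}
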