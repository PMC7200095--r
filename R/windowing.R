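# Moving-window augmentation: every burst of n samples/axis yields all
# contiguous sub-segments of a fixed window length, stepped by one sample,
# so that a single labelled burst contributes n - w + 1 training examples
# while preserving sample order (required for the FFT predictors).

#' Define a moving-window plan
#'
#' @param window_size Window length `w` in samples per axis.
#' @param step Step between consecutive window starts (default 1, the
#'   canonical augmentation; exposed for sensitivity studies).
#' @return Object of class `"window_plan"`.
#' @examples
#' window_count(110, window_plan(79))  # 32
#' @export
window_plan <- function(window_size, step = 1L) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (window_size < 1) stop("window_size must be >= 1")
  if (step < 1) stop("step must be >= 1")
  structure(list(window_size = window_size, step = step),
            class = "window_plan")
}

#' Number of windows a burst of length n yields
#'
#' `floor((n - w) / step) + 1`; for step 1 this is `n - w + 1`
#' (110-sample bursts at w = 79 give 32 windows).
#'
#' @param n Burst length (samples per axis).
#' @param plan A [window_plan()].
#' @return Integer window count.
#' @export
window_count <- function(n, plan) {
  if (plan$window_size > n) stop("window too large: w > n")
  as.integer((n - plan$window_size) %/% plan$step + 1L)
}

#' Extract the moving windows of one burst
#'
#' Returns the list of windows: `w` consecutive samples per axis starting
#' at offsets 0, step, 2*step, ... The first window spans samples
#' 1..w; each subsequent window drops the earliest sample and appends the
#' next one (for step 1), until the window includes the last sample.
#'
#' @param burst Either an `acc_bursts` object of length 1 or a numeric
#'   matrix with columns x, y, z.
#' @param plan A [window_plan()].
#' @return List of `w` x 3 matrices, one per window, with attribute
#'   `"offsets"` (0-based start indices).
#' @export
slide <- function(burst, plan) {
  mat <- if (inherits(burst, "acc_bursts")) {
    if (length(burst) != 1) stop("slide() expects a single burst")
    burst$samples[[1]]
  } else as.matrix(burst)
  n <- nrow(mat)
  w <- plan$window_size
  if (w > n) stop("window too large: w (", w, ") > burst length (", n, ")")
  offsets <- seq(0L, n - w, by = plan$step)
  out <- lapply(offsets, function(o) mat[(o + 1):(o + w), , drop = FALSE])
  attr(out, "offsets") <- offsets
  out
}

#' Stratified burst-level train/test split
#'
#' Bursts are split per behaviour class, at the burst level, before any
#' windowing — windows from one burst are near-duplicates, so a
#' window-level split would leak information across the partition. The
#' per-class training count is `round-half-up(train_frac * class count)`,
#' with at least one test burst forced per class so both partitions remain
#' evaluable.
#'
#' @param bursts A labelled `acc_bursts` object (every burst labelled).
#' @param train_frac Fraction of bursts per class assigned to training
#'   (default 0.7).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with `acc_bursts` elements `train` and `test`.
#' @export
stratified_split <- function(bursts, train_frac = 0.7, seed = 1L) {
  lab <- bursts$meta$label
  if (any(is.na(lab))) stop("all bursts must be labelled before splitting")
  counts <- table(lab)
  if (any(counts < 2))
    stop("stratification error: class(es) with < 2 bursts: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(lab == cl)
    k <- floor(train_frac * length(idx) + 0.5)  # round half up
    k <- min(k, length(idx) - 1L)               # force >= 1 test burst
    k <- max(k, 1L)
    train_idx <- c(train_idx, sample(idx, k))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(lab), train_idx)
  list(train = bursts[train_idx], test = bursts[test_idx])
}

#' Expand bursts into a windowed feature table
#'
#' Applies the moving window to every burst and computes the full
#' predictor set ([feature_names()]) for each window. Row count is the sum
#' of per-burst window counts; each row carries its burst id, window
#' offset and the burst's label.
#'
#' @param bursts An `acc_bursts` object; all bursts must be at least
#'   `w` samples long and share one length (feature dimensionality must be
#'   constant across a table).
#' @param plan A [window_plan()].
#' @return Data frame: `burst_id`, `window_offset`, `label`, then the
#'   predictors. Attribute `"window_size"` records `w`.
#' @export
expand <- function(bursts, plan) {
  w <- plan$window_size
  meta <- bursts$meta
  nb <- nrow(meta)
  nf <- length(feature_names(w))
  if (nb == 0) {
    out <- data.frame(burst_id = character(0), window_offset = integer(0),
                      label = character(0))
    out[feature_names(w)] <- lapply(feature_names(w), function(i) numeric(0))
    attr(out, "window_size") <- w
    return(out)
  }
  if (length(unique(meta$n)) > 1)
    stop("dimensionality error: bursts of differing length in one table")
  if (any(meta$n < w)) stop("window too large for burst length")
  nwins <- vapply(meta$n, function(n) window_count(n, plan), integer(1))
  total <- sum(nwins)
  X <- matrix(NA_real_, total, nf)
  off_all <- integer(total)
  pos <- 0L
  for (b in seq_len(nb)) {
    offsets <- seq(0L, meta$n[b] - w, by = plan$step)
    X[pos + seq_along(offsets), ] <- featurize_windows(bursts$samples[[b]],
                                                       offsets, w)
    off_all[pos + seq_along(offsets)] <- offsets
    pos <- pos + length(offsets)
  }
  colnames(X) <- feature_names(w)
  out <- data.frame(burst_id = rep(meta$burst_id, nwins),
                    window_offset = off_all,
                    label = rep(meta$label, nwins),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  attr(out, "window_size") <- w
  out
}

#' Column names of the predictor block of an expanded feature table
#' @param features A data frame from [expand()].
#' @return Character vector of predictor column names.
#' @export
predictor_columns <- function(features) {
  setdiff(names(features), c("burst_id", "window_offset", "label"))
}

#' Write / read feature tables with window-length metadata
#'
#' Feature tables are CSVs with a leading comment line
#' `# accbehav feature table v1, window_size=<w>` so that models can check
#' dimensional compatibility.
#'
#' @param features Data frame from [expand()].
#' @param path CSV path.
#' @return `path` invisibly (write) or the feature table (read).
#' @export
write_features <- function(features, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# accbehav feature table v1, window_size=%d",
                     attr(features, "window_size")), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 1)
  w <- as.integer(sub(".*window_size=(\\d+).*", "\\1", hdr))
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "window_size") <- w
  out
}
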