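# Small programmatic fixtures shared across test files.

# a tiny burst set with explicit sample values
make_bursts <- function(n_bursts = 2, n = 110, animal = "fox1",
                        start = as.POSIXct("2016-03-01 12:00:00", tz = "UTC"),
                        labels = NULL, seed = 42) {
  set.seed(seed)
  meta <- data.frame(
    burst_id = sprintf("%s_b%03d", animal, seq_len(n_bursts)),
    animal_id = animal,
    burst_start = start + (seq_len(n_bursts) - 1) * 120,
    sampling_rate = 33.33,
    label = if (is.null(labels)) NA_character_ else labels,
    stringsAsFactors = FALSE)
  samples <- replicate(n_bursts,
                       matrix(rnorm(3 * n), n, 3,
                              dimnames = list(NULL, c("x", "y", "z"))),
                       simplify = FALSE)
  acc_bursts(meta, samples)
}

# write a long-format burst CSV by hand (independent of write_bursts)
write_long_csv <- function(path, bursts_df) {
  write.csv(bursts_df, path, row.names = FALSE)
  path
}

# gaussian blob features for direct classifier tests: k well-separated
# classes in p dimensions
make_blobs <- function(n_per_class = 50, k = 2, p = 4, sep = 8, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per_class * p, mean = i * sep), n_per_class, p)))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(paste0("class", seq_len(k)), each = n_per_class))
}
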