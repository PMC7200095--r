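berlin <- list(lat = 52.52, lon = 13.40)

# fixes laid out at given metre offsets east of a base point
fixes_at <- function(east_m, t0 = as.POSIXct("2018-06-01", tz = "UTC"),
                     dt = 240) {
  data.frame(animal_id = "w",
             time = t0 + (seq_along(east_m) - 1) * dt,
             lat = berlin$lat,
             lon = berlin$lon + east_m /
               (111320 * cos(berlin$lat * pi / 180)))
}

test_that("all fixes within the radius form one cluster", {
  f <- fixes_at(c(0, 10, 20, 30, 45))
  cl <- segment_clusters(f, radius_m = 50)
  expect_equal(unique(cl$cluster_id), 1L)
  expect_equal(attr(cl, "clusters")$n_fixes, 5L)
})

test_that("fixes beyond the radius each anchor a new cluster", {
  f <- fixes_at(c(0, 60, 120))
  cl <- segment_clusters(f, radius_m = 50)
  expect_equal(cl$cluster_id, 1:3)
  expect_equal(attr(cl, "clusters")$n_fixes, rep(1L, 3))
})

test_that("segmentation matches a brute-force oracle and partitions", {
  set.seed(60)
  for (rep in 1:5) {
    east <- cumsum(rnorm(80, sd = 30))
    f <- fixes_at(east)
    cl <- segment_clusters(f, radius_m = 50)
    # brute-force re-implementation of the rule
    ids <- integer(80); ids[1] <- 1L; anchor <- 1L
    for (i in 2:80) {
      d <- geosphere::distHaversine(
        c(f$lon[anchor], f$lat[anchor]), c(f$lon[i], f$lat[i]),
        r = 6371008.8)
      if (d > 50) { ids[i] <- ids[i - 1] + 1L; anchor <- i }
      else ids[i] <- ids[i - 1]
    }
    expect_equal(cl$cluster_id, ids)
    expect_equal(sum(attr(cl, "clusters")$n_fixes), 80L)
  }
  empty <- data.frame(animal_id = character(0),
                      time = as.POSIXct(character(0), tz = "UTC"),
                      lat = numeric(0), lon = numeric(0))
  expect_equal(nrow(segment_clusters(empty)), 0)
})

test_that("GPS speed matches distance over time", {
  # ~100 m apart, 50 s apart -> 2 m/s
  f <- fixes_at(c(0, 100), dt = 50)
  sp <- gps_speed(f)
  expect_equal(sp$speed_ms, 2, tolerance = 5e-3)
  f2 <- fixes_at(c(0, 0), dt = 50)
  expect_equal(gps_speed(f2)$speed_ms, 0)
  f3 <- fixes_at(c(0, 10)); f3$time <- rep(f3$time[1], 2)
  expect_error(gps_speed(f3), "degenerate interval")
})

test_that("haversine speeds agree with an independent great-circle oracle", {
  set.seed(61)
  lat <- berlin$lat + cumsum(rnorm(20, sd = 0.001))
  lon <- berlin$lon + cumsum(rnorm(20, sd = 0.001))
  f <- data.frame(animal_id = "w",
                  time = as.POSIXct("2018-06-01", tz = "UTC") +
                    (1:20) * 240,
                  lat = lat, lon = lon)
  sp <- gps_speed(f)
  # spherical law of cosines on the same radius
  R <- 6371008.8
  for (i in 1:19) {
    p1 <- c(lat[i], lon[i]) * pi / 180
    p2 <- c(lat[i + 1], lon[i + 1]) * pi / 180
    d <- R * acos(pmin(1, sin(p1[1]) * sin(p2[1]) +
                         cos(p1[1]) * cos(p2[1]) * cos(p2[2] - p1[2])))
    expect_equal(sp$distance_m[i], d, tolerance = 1e-3 * max(d, 1))
  }
})

test_that("speed matching respects the 10-second window, boundary closed", {
  f <- fixes_at(c(0, 240, 480), dt = 120)  # 2 m/s throughout
  t0 <- f$time[1]
  preds <- data.frame(
    burst_id = c("b1", "b2", "b3"),
    burst_start = c(t0 + 125, t0 + 110, t0 + 180),  # +5 s, -10 s, +60 s
    behaviour = c("trotting", "trotting", "walking"))
  m <- match_speed_to_behaviour(preds, f, max_dt = 10)
  expect_equal(nrow(m), 2)  # the +60 s burst is unmatched
  expect_equal(m$behaviour, c("trotting", "trotting"))
  lg <- attr(m, "run_log")
  expect_equal(lg[[1]]$n_unmatched, 1)
})

test_that("cluster coherence needs min_items and is monotone in it", {
  t0 <- as.POSIXct("2018-06-01", tz = "UTC")
  # one stationary cluster spanning 2 h, then travel singletons
  f <- fixes_at(c(rep(0, 30), seq(100, 2000, by = 100)))
  cl <- segment_clusters(f, radius_m = 50)
  # 20 resting predictions inside the cluster span, trotting outside
  preds <- data.frame(
    burst_id = sprintf("b%02d", 1:40),
    burst_start = c(t0 + seq(60, by = 120, length.out = 20),
                    t0 + 30 * 240 + seq(60, by = 120, length.out = 20)),
    behaviour = rep(c("resting", "trotting"), each = 20))
  coh <- cluster_behaviour_coherence(preds, cl, min_items = 10)
  expect_equal(coh$proportion[coh$behaviour == "resting"], 1)
  expect_equal(coh$proportion[coh$behaviour == "trotting"], 0)
  # a cluster with 9 items does not qualify
  preds9 <- preds[c(1:9, 21:40), ]
  coh9 <- cluster_behaviour_coherence(preds9, cl, min_items = 10)
  expect_equal(coh9$proportion[coh9$behaviour == "resting"], 0)
  # lowering min_items never decreases any proportion
  for (rep in 1:3) {
    set.seed(rep + 70)
    sub <- preds[sample(40, 25), ]
    p_hi <- cluster_behaviour_coherence(sub, cl, min_items = 15)
    p_lo <- cluster_behaviour_coherence(sub, cl, min_items = 5)
    merged <- merge(p_hi, p_lo, by = "behaviour")
    expect_true(all(merged$proportion.y >= merged$proportion.x))
  }
})

test_that("diel composition counts bins and flags short months", {
  t0 <- as.POSIXct("2018-06-01 00:00:00", tz = "UTC")
  preds <- data.frame(
    burst_id = sprintf("b%03d", 1:144),
    burst_start = t0 + seq(0, by = 7200, length.out = 144),  # 12 days
    behaviour = "resting")
  comp <- diel_composition(preds)
  months <- attr(comp, "months")
  expect_equal(months$days_covered, 12L)
  expect_false(months$interpretable)
  on_bins <- comp[comp$count > 0, ]
  expect_true(all(on_bins$proportion == 1))  # single behaviour everywhere
})

test_that("sun times are plausible for Berlin midsummer and midwinter", {
  s <- sun_times(as.Date(c("2018-06-21", "2018-12-21")),
                 berlin$lat, berlin$lon)
  # UTC sunrise ~02:43, sunset ~19:33 in June; ~07:14 / 14:53 in December
  expect_lt(s$sunrise_min[1], 4 * 60)
  expect_gt(s$sunset_min[1], 19 * 60)
  expect_gt(s$sunrise_min[2], 6.5 * 60)
  expect_lt(s$sunset_min[2], 16 * 60)
  # day length longer in June than December
  expect_gt(s$sunset_min[1] - s$sunrise_min[1],
            s$sunset_min[2] - s$sunrise_min[2])
})

test_that("actograms grid days by time bins, keep gap days blank", {
  t0 <- as.POSIXct("2018-06-01 10:00:00", tz = "UTC")
  times <- c(t0, t0 + 3600, t0 + 3 * 86400)  # gap on days 2 and 3
  act <- actogram(times, c(0, 0, 0), bin_minutes = 30)
  expect_equal(dim(act$grid), c(4L, 48L))
  expect_true(all(act$grid == 0, na.rm = TRUE))
  expect_true(all(is.na(act$grid[2, ])))
  # nocturnal activity: night bins carry higher mean ODBA
  set.seed(75)
  times2 <- t0 + seq(0, 6 * 86400, by = 1800)
  hrs <- as.integer(format(times2, "%H", tz = "UTC"))
  night <- hrs >= 20 | hrs < 4
  vals <- ifelse(night, 1.5, 0.1) + rnorm(length(times2), sd = 0.01)
  act2 <- actogram(times2, vals, lat = berlin$lat, lon = berlin$lon)
  bins_h <- act2$bins / 60
  night_cols <- bins_h >= 20 | bins_h < 4
  expect_gt(mean(act2$grid[, night_cols], na.rm = TRUE),
            mean(act2$grid[, !night_cols], na.rm = TRUE))
  expect_equal(nrow(act2$sun), 7)
})
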