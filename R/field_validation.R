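# Indirect credibility checks for behaviour assignments on free-ranging
# animals, where no direct observation exists: (i) diel behaviour
# composition, (ii) consistency across days/individuals (actograms),
# (iii) coherence with GPS clusters and GPS-based speed, (iv) coherence
# with movement intensity (ODBA). Distances use the haversine on a sphere
# of radius 6371.0088 km; at the 50 m scale the ellipsoid choice is
# irrelevant.

EARTH_RADIUS_M <- 6371008.8

hav_dist <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Segment a GPS track into sequential 50 m clusters
#'
#' Single-pass rule: the first fix anchors a cluster; each subsequent fix
#' within `radius_m` of the current anchor joins it; the first fix beyond
#' the radius closes the cluster and anchors a new one. Singleton clusters
#' are allowed. The clusters partition the fix sequence, so spatially
#' stationary bouts (e.g. resting at a den) appear as long clusters while
#' directed travel produces runs of singletons.
#'
#' @param fixes Data frame of one animal's fixes, time-sorted, with
#'   columns `time`, `lat`, `lon`.
#' @param radius_m Cluster radius in metres (default 50).
#' @return The fixes with an added `cluster_id` column, of class
#'   `"gps_clusters"`, with attribute `"clusters"`: a summary data frame
#'   (`cluster_id`, `anchor_time`, `last_time`, `n_fixes`, `anchor_lat`,
#'   `anchor_lon`).
#' @export
segment_clusters <- function(fixes, radius_m = 50) {
  n <- nrow(fixes)
  if (is.null(n) || n == 0) {
    out <- cbind(fixes, cluster_id = integer(0))
    attr(out, "clusters") <- data.frame(
      cluster_id = integer(0), anchor_time = as.POSIXct(character(0),
                                                        tz = "UTC"),
      last_time = as.POSIXct(character(0), tz = "UTC"),
      n_fixes = integer(0), anchor_lat = numeric(0), anchor_lon = numeric(0))
    class(out) <- c("gps_clusters", class(out))
    return(out)
  }
  if (is.unsorted(fixes$time)) stop("fixes must be time-sorted")
  cluster_id <- integer(n)
  cluster_id[1] <- 1L
  anchor <- 1L
  cur <- 1L
  for (i in seq_len(n)[-1]) {
    d <- hav_dist(fixes$lon[anchor], fixes$lat[anchor],
                  fixes$lon[i], fixes$lat[i])
    if (d > radius_m) {
      cur <- cur + 1L
      anchor <- i
    }
    cluster_id[i] <- cur
  }
  out <- fixes
  out$cluster_id <- cluster_id
  idx <- split(seq_len(n), cluster_id)
  summ <- data.frame(
    cluster_id = as.integer(names(idx)),
    anchor_time = fixes$time[vapply(idx, `[`, integer(1), 1)],
    last_time = fixes$time[vapply(idx, function(v) v[length(v)], integer(1))],
    n_fixes = lengths(idx),
    anchor_lat = fixes$lat[vapply(idx, `[`, integer(1), 1)],
    anchor_lon = fixes$lon[vapply(idx, `[`, integer(1), 1)])
  rownames(summ) <- NULL
  attr(out, "clusters") <- summ
  class(out) <- c("gps_clusters", class(out))
  out
}

#' Per-behaviour proportion of assignments inside GPS clusters
#'
#' Each behaviour assignment is mapped to the cluster whose time span
#' (anchor time to last-member time, half-open on the right) contains its
#' burst start. Only clusters holding at least `min_items` assignments
#' count as spatially clustered — this keeps runs of travel singletons
#' from qualifying. The result, per behaviour, is the fraction of all its
#' assignments that fall into a qualifying cluster; stationary behaviours
#' (resting) are expected high, locomotion (trotting) low.
#'
#' @param predictions Data frame from [predict_bursts()] (needs
#'   `burst_start` and `behaviour`).
#' @param clusters A [segment_clusters()] result.
#' @param min_items Minimum assignments per qualifying cluster
#'   (default 10).
#' @return Data frame: `behaviour`, `n_total`, `n_in_cluster`,
#'   `proportion`.
#' @export
cluster_behaviour_coherence <- function(predictions, clusters,
                                        min_items = 10) {
  summ <- attr(clusters, "clusters")
  behaviours <- sort(unique(predictions$behaviour))
  if (nrow(summ) == 0 || nrow(predictions) == 0) {
    warning("no temporal overlap between predictions and clusters")
    return(data.frame(behaviour = character(0), n_total = integer(0),
                      n_in_cluster = integer(0), proportion = numeric(0)))
  }
  t <- as.numeric(predictions$burst_start)
  a <- as.numeric(summ$anchor_time)
  b <- as.numeric(summ$last_time)
  # assign each prediction to the cluster with a <= t < b (spans are
  # disjoint and ordered, so findInterval on anchors then a span check)
  j <- findInterval(t, a)
  in_span <- j >= 1 & ifelse(j >= 1, t < b[pmax(j, 1)], FALSE)
  cl <- ifelse(in_span, j, NA_integer_)
  items_per_cluster <- table(factor(cl, levels = summ$cluster_id))
  qualifying <- as.integer(names(items_per_cluster))[
    as.integer(items_per_cluster) >= min_items]
  in_qual <- !is.na(cl) & cl %in% qualifying
  out <- do.call(rbind, lapply(behaviours, function(bh) {
    sel <- predictions$behaviour == bh
    data.frame(behaviour = bh, n_total = sum(sel),
               n_in_cluster = sum(sel & in_qual),
               proportion = sum(sel & in_qual) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' GPS-based speed between consecutive fixes
#'
#' Speed of interval i is the haversine distance between fix i and fix
#' i+1 divided by the time difference.
#'
#' @param fixes Time-sorted data frame with `time`, `lat`, `lon`
#'   (single animal); strictly increasing timestamps.
#' @return Data frame with one row per interval: `t0`, `t1`,
#'   `distance_m`, `dt_s`, `speed_ms`.
#' @export
gps_speed <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2)
    return(data.frame(t0 = fixes$time[0], t1 = fixes$time[0],
                      distance_m = numeric(0), dt_s = numeric(0),
                      speed_ms = numeric(0)))
  dt <- diff(as.numeric(fixes$time))
  if (any(dt <= 0)) stop("degenerate interval: duplicate or unsorted timestamps")
  d <- hav_dist(fixes$lon[-n], fixes$lat[-n], fixes$lon[-1], fixes$lat[-1])
  data.frame(t0 = fixes$time[-n], t1 = fixes$time[-1],
             distance_m = d, dt_s = dt, speed_ms = d / dt)
}

#' Join behaviour assignments to GPS speed
#'
#' GPS and acceleration schedules are independent, so only bursts
#' recorded within `max_dt` seconds of a GPS fix are used (boundary
#' included). Each assignment joins the speed of the interval ending at
#' its nearest fix (the interval leaving the first fix when that fix is
#' nearest); each assignment is matched at most once. Unmatched
#' assignments are dropped and counted in the run log.
#'
#' @param predictions Data frame from [predict_bursts()].
#' @param fixes Time-sorted GPS fixes (single animal).
#' @param max_dt Maximum |burst start - fix time| in seconds (default 10).
#' @return Data frame `behaviour`, `speed_ms`, `dt_s` (signed offset to
#'   the matched fix); unmatched count available via [run_log()].
#' @export
match_speed_to_behaviour <- function(predictions, fixes, max_dt = 10) {
  sp <- gps_speed(fixes)
  ft <- as.numeric(fixes$time)
  bt <- as.numeric(predictions$burst_start)
  nearest <- pmax(1, pmin(length(ft), findInterval(bt, ft)))
  # findInterval gives the fix at or before; the one after may be closer
  after <- pmin(nearest + 1, length(ft))
  use_after <- abs(ft[after] - bt) < abs(ft[nearest] - bt)
  nearest[use_after] <- after[use_after]
  dt <- bt - ft[nearest]
  matched <- abs(dt) <= max_dt
  interval <- ifelse(nearest >= 2, nearest - 1, 1)
  ok <- matched & nrow(sp) >= 1
  out <- data.frame(behaviour = predictions$behaviour[ok],
                    speed_ms = sp$speed_ms[interval[ok]],
                    dt_s = dt[ok], stringsAsFactors = FALSE)
  attr(out, "run_log") <- list(list(event = "predictions_unmatched_to_gps",
                                    n_unmatched = sum(!matched),
                                    max_dt = max_dt))
  out
}

#' Diel composition of behaviour assignments
#'
#' Counts assignments per (month, time-of-day bin, behaviour) so the
#' 24-hour structure of the output can be inspected month by month.
#' Months with fewer than `min_days` distinct days of data are flagged as
#' not interpretable (at least half a month of coverage is required).
#'
#' @param predictions Data frame from [predict_bursts()].
#' @param bin_minutes Width of the time-of-day bins (default 30).
#' @param tz_offset_hours Offset added to UTC for local time of day
#'   (default 0).
#' @param min_days Minimum distinct days per interpretable month
#'   (default 15).
#' @return Data frame of class `"composition_table"`: `month`,
#'   `bin_start_min`, `behaviour`, `count`, `proportion`; attribute
#'   `"months"` summarises `days_covered` and `interpretable` per month.
#' @export
diel_composition <- function(predictions, bin_minutes = 30,
                             tz_offset_hours = 0, min_days = 15) {
  t_local <- predictions$burst_start + tz_offset_hours * 3600
  month <- format(t_local, "%Y-%m", tz = "UTC")
  date <- format(t_local, "%Y-%m-%d", tz = "UTC")
  min_of_day <- as.integer(format(t_local, "%H", tz = "UTC")) * 60 +
    as.integer(format(t_local, "%M", tz = "UTC"))
  bin <- (min_of_day %/% bin_minutes) * bin_minutes
  tab <- as.data.frame(table(month = month, bin_start_min = bin,
                             behaviour = predictions$behaviour),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  tab$bin_start_min <- as.integer(tab$bin_start_min)
  tot <- stats::ave(tab$count, tab$month, tab$bin_start_min, FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$count / tot, 0)
  days <- tapply(date, month, function(d) length(unique(d)))
  months <- data.frame(month = names(days),
                       days_covered = as.integer(days),
                       interpretable = as.integer(days) >= min_days,
                       stringsAsFactors = FALSE)
  rownames(months) <- NULL
  attr(tab, "months") <- months
  class(tab) <- c("composition_table", class(tab))
  tab
}

#' Sunrise and sunset times (minutes of day, UTC)
#'
#' Standard NOAA low-accuracy solar position algorithm (equation of time
#' and solar declination from a Fourier expansion in day of year; zenith
#' 90.833 degrees for atmospheric refraction). Accurate to a couple of
#' minutes, which is ample for actogram overlays.
#'
#' @param dates Date vector.
#' @param lat,lon Location in decimal degrees.
#' @param tz_offset_hours Offset added to UTC (default 0).
#' @return Data frame `date`, `sunrise_min`, `sunset_min` (minutes of
#'   local day; `NA` for polar day/night).
#' @export
sun_times <- function(dates, lat, lon, tz_offset_hours = 0) {
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  g <- 2 * pi / 365 * (doy - 1)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) / (cos(latr) * cos(decl))) -
    tan(latr) * tan(decl)
  ha <- suppressWarnings(acos(pmin(1, pmax(-1, cos_ha)))) * 180 / pi
  polar <- cos_ha > 1 | cos_ha < -1
  sunrise <- 720 - 4 * (lon + ha) - eqtime + tz_offset_hours * 60
  sunset <- 720 - 4 * (lon - ha) - eqtime + tz_offset_hours * 60
  sunrise[polar] <- NA_real_
  sunset[polar] <- NA_real_
  data.frame(date = dates, sunrise_min = sunrise %% 1440,
             sunset_min = sunset %% 1440)
}

#' Build an actogram grid
#'
#' A day-by-time-of-day raster of either a scalar (ODBA per burst,
#' averaged within bins) or a behaviour indicator (1 when the focal
#' behaviour was classified in the bin). Sunrise/sunset are attached per
#' day when a location is given, or may be supplied precomputed.
#'
#' @param times POSIXct timestamps (UTC).
#' @param values Numeric values (ODBA) or 0/1 indicators, same length.
#' @param bin_minutes Bin width (default 30).
#' @param lat,lon Optional location for sun-time overlays.
#' @param sun Optional precomputed data frame as from [sun_times()].
#' @param tz_offset_hours Offset added to UTC (default 0).
#' @param aggregate `"mean"` (scalar values) or `"max"` (indicators).
#' @return Object of class `"actogram"`: list with `grid` (days x bins
#'   matrix, `NA` where no data; gap days kept as blank rows), `bins`
#'   (bin start minutes), `dates`, and `sun` (or `NULL`).
#' @export
actogram <- function(times, values, bin_minutes = 30, lat = NULL,
                     lon = NULL, sun = NULL, tz_offset_hours = 0,
                     aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(times) == length(values))
  t_local <- times + tz_offset_hours * 3600
  date <- as.Date(format(t_local, "%Y-%m-%d", tz = "UTC"))
  min_of_day <- as.integer(format(t_local, "%H", tz = "UTC")) * 60 +
    as.integer(format(t_local, "%M", tz = "UTC"))
  bin <- (min_of_day %/% bin_minutes) * bin_minutes
  dates <- seq(min(date), max(date), by = "day")
  bins <- seq(0, 1439, by = bin_minutes)
  grid <- matrix(NA_real_, length(dates), length(bins),
                 dimnames = list(as.character(dates), bins))
  key <- paste(date, bin)
  agg <- tapply(values, key, if (aggregate == "mean") mean else max)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  grid[cbind(match(parts[, 1], as.character(dates)),
             match(as.integer(parts[, 2]), bins))] <- as.numeric(agg)
  if (is.null(sun) && !is.null(lat) && !is.null(lon))
    sun <- sun_times(dates, lat, lon, tz_offset_hours)
  structure(list(grid = grid, bins = bins, dates = dates, sun = sun),
            class = "actogram")
}

#' @export
plot.actogram <- function(x, main = "Actogram", ...) {
  z <- x$grid
  z[is.na(z)] <- 0
  graphics::image(x = x$bins / 60, y = seq_along(x$dates), z = t(z),
                  col = grDevices::grey(seq(1, 0, length.out = 64)),
                  xlab = "Time of day (h)", ylab = "Day", main = main, ...)
  if (!is.null(x$sun)) {
    graphics::lines(x$sun$sunrise_min / 60, seq_along(x$dates), col = "red")
    graphics::lines(x$sun$sunset_min / 60, seq_along(x$dates), col = "red")
  }
  invisible(x)
}
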