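# Synthetic burst and track generator. Every class is a simple additive
# signal: a static orientation (gravity direction in device units), an
# optional periodic gait component (sinusoid at a class-typical stride
# frequency, split across axes), and Gaussian sensor noise. The classes
# are parameterized so that the moment, posture and FFT predictors
# separate them at the default settings: resting is still and quiet,
# grooming is broadband noise without periodicity, walking/trotting are
# periodic at increasing frequency and amplitude, feeding/caching are
# intermediate mixtures. All generators are pure functions of their
# parameters and seed.

#' Per-class signal model for synthetic bursts
#'
#' @param overrides Named list of per-class parameter lists to merge over
#'   the defaults; each class has `orient` (unit-ish gravity vector in
#'   device units), `freq` (Hz), `amp` (device units), `noise_sd`
#'   (device units) and `amp_jitter` (relative bound of the per-burst
#'   uniform amplitude jitter).
#' @return Named list of class `"behaviour_signal_model"`.
#' @export
behaviour_signal_model <- function(overrides = list()) {
  defaults <- list(
    feeding = list(orient = c(0.10, 0.60, 0.79), freq = 1.0, amp = 0.25,
                   noise_sd = 0.20, amp_jitter = 0.2),
    grooming = list(orient = c(0.30, 0.20, 0.93), freq = 0, amp = 0,
                    noise_sd = 0.50, amp_jitter = 0),
    resting = list(orient = c(0.00, 0.00, 1.00), freq = 0, amp = 0,
                   noise_sd = 0.02, amp_jitter = 0),
    caching = list(orient = c(0.25, 0.40, 0.88), freq = 2.0, amp = 0.55,
                   noise_sd = 0.25, amp_jitter = 0.2),
    trotting = list(orient = c(0.00, 0.50, 0.87), freq = 3.0, amp = 1.20,
                    noise_sd = 0.15, amp_jitter = 0.2),
    walking = list(orient = c(0.00, 0.30, 0.95), freq = 1.5, amp = 0.40,
                   noise_sd = 0.08, amp_jitter = 0.2))
  for (cl in names(overrides))
    defaults[[cl]] <- utils::modifyList(defaults[[cl]] %||% list(),
                                        overrides[[cl]])
  structure(defaults, class = "behaviour_signal_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# axis weights of the periodic gait component (sway, surge, heave)
PERIODIC_WEIGHTS <- c(x = 0.2, y = 0.6, z = 1.0)

#' Generate one synthetic burst
#'
#' @param class Behaviour class name (must exist in `model`).
#' @param model A [behaviour_signal_model()].
#' @param n Samples per axis (default 110).
#' @param rate Sampling rate in Hz (default 33.33).
#' @param seed Optional integer seed for exact reproducibility.
#' @return `n` x 3 numeric matrix with columns x, y, z.
#' @examples
#' b <- generate_burst("trotting", seed = 1)
#' odba(b[, 1], b[, 2], b[, 3]) > 0
#' @export
generate_burst <- function(class, model = behaviour_signal_model(),
                           n = 110, rate = 33.33, seed = NULL) {
  p <- model[[class]]
  if (is.null(p)) stop("unknown behaviour class: ", class)
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- p$amp * stats::runif(1, 1 - p$amp_jitter, 1 + p$amp_jitter)
  per <- if (p$freq > 0) {
    cbind(PERIODIC_WEIGHTS["x"] * sin(2 * pi * p$freq * t + phase),
          PERIODIC_WEIGHTS["y"] * sin(2 * pi * p$freq * t + phase + pi / 2),
          PERIODIC_WEIGHTS["z"] * sin(2 * pi * p$freq * t + phase)) * amp
  } else matrix(0, n, 3)
  noise <- matrix(stats::rnorm(3 * n, sd = p$noise_sd), n, 3)
  out <- rep(p$orient, each = n) + per + noise
  colnames(out) <- c("x", "y", "z")
  out
}

#' Generate a mixed burst (behaviour change mid-burst)
#'
#' Splices two classes within one burst: the first `frac` of samples from
#' `class_a`, the remainder from `class_b`. Mixed bursts are not
#' characteristic of either class and exercise the rejection-threshold /
#' majority-vote path.
#'
#' @param class_a,class_b Behaviour classes.
#' @param frac Fraction of samples from `class_a` (default 0.5).
#' @inheritParams generate_burst
#' @return `n` x 3 numeric matrix.
#' @export
generate_mixed_burst <- function(class_a, class_b, frac = 0.5,
                                 model = behaviour_signal_model(),
                                 n = 110, rate = 33.33, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- round(frac * n)
  rbind(generate_burst(class_a, model, n = k, rate = rate),
        generate_burst(class_b, model, n = n - k, rate = rate))
}

#' Generate a labelled captive-style training set
#'
#' Default class counts mirror a realistic ground-truthed captive data
#' set with strong imbalance (resting dominant, walking rare), 4159
#' bursts in total. Counts are honoured exactly; bursts get sequential
#' timestamps on the duty cycle.
#'
#' @param counts Named integer vector of bursts per class.
#' @param model A [behaviour_signal_model()].
#' @param n,rate Burst geometry (110 samples at 33.33 Hz by default).
#' @param seed Integer seed.
#' @param animal_id Animal identifier for the metadata.
#' @param start Timestamp of the first burst (POSIXct UTC).
#' @param cadence_s Seconds between burst starts (default 120).
#' @return A labelled `acc_bursts` object.
#' @export
generate_captive_dataset <- function(counts = c(feeding = 367,
                                                grooming = 1140,
                                                resting = 2114,
                                                caching = 197,
                                                trotting = 179,
                                                walking = 162),
                                     model = behaviour_signal_model(),
                                     n = 110, rate = 33.33, seed = 1L,
                                     animal_id = "captive1",
                                     start = as.POSIXct("2016-01-01 00:00:00",
                                                        tz = "UTC"),
                                     cadence_s = 120) {
  if (any(counts < 1)) stop("counts must be >= 1 per class")
  set.seed(seed)
  labels <- sample(rep(names(counts), counts))
  total <- length(labels)
  samples <- lapply(labels, function(cl)
    generate_burst(cl, model, n = n, rate = rate))
  meta <- data.frame(
    burst_id = sprintf("%s_b%05d", animal_id, seq_len(total)),
    animal_id = animal_id,
    burst_start = start + (seq_len(total) - 1) * cadence_s,
    sampling_rate = rate,
    label = labels,
    stringsAsFactors = FALSE)
  acc_bursts(meta, samples)
}

#' Default diel activity schedule
#'
#' Hourly behaviour probabilities emulating a nocturnal-crepuscular
#' predator: resting dominates the daylight hours, trotting and feeding
#' the night, with mixed activity at dawn and dusk. Rows (hours 0-23)
#' sum to 1.
#'
#' @return 24 x 6 matrix, rows = hours, columns = behaviour classes.
#' @export
default_diel_schedule <- function() {
  classes <- c("feeding", "grooming", "resting", "caching", "trotting",
               "walking")
  sched <- matrix(0, 24, 6, dimnames = list(0:23, classes))
  night <- c(20:23, 0:4)
  crepuscular <- c(5:7, 17:19)
  day <- 8:16
  sched[as.character(night), ] <-
    matrix(rep(c(0.20, 0.05, 0.05, 0.05, 0.50, 0.15), each = length(night)),
           length(night))
  sched[as.character(crepuscular), ] <-
    matrix(rep(c(0.15, 0.10, 0.25, 0.05, 0.15, 0.30),
               each = length(crepuscular)), length(crepuscular))
  sched[as.character(day), ] <-
    matrix(rep(c(0.05, 0.10, 0.85, 0.00, 0.00, 0.00), each = length(day)),
           length(day))
  sched
}

#' Define a wild-track scenario
#'
#' @param days Days of data to simulate (default 7).
#' @param cadence_s Seconds between bursts (default 120, the tag duty
#'   cycle).
#' @param gps_interval_s Seconds between GPS fixes (default 240).
#' @param stickiness Probability that a burst slot repeats the previous
#'   behaviour state rather than redrawing from the schedule
#'   (default 0.9; creates multi-slot bouts and hence GPS clusters).
#' @param schedule 24 x classes matrix of hourly behaviour
#'   probabilities; rows must sum to 1.
#' @param lat0,lon0 Starting location (default central Berlin).
#' @param dwell_radius_m Radius of the stationary jitter during resting
#'   bouts (default 15 m, safely inside the 50 m cluster rule).
#' @param speeds Named list of `c(min, max)` travel speeds (m/s) per
#'   class; defaults order resting ~ 0 < walking < trotting.
#' @param start First burst time (POSIXct UTC).
#' @param animal_id Animal identifier.
#' @return Object of class `"wild_scenario"`.
#' @export
wild_scenario <- function(days = 7, cadence_s = 120, gps_interval_s = 240,
                          stickiness = 0.9,
                          schedule = default_diel_schedule(),
                          lat0 = 52.52, lon0 = 13.40,
                          dwell_radius_m = 15,
                          speeds = list(feeding = c(0.05, 0.3),
                                        grooming = c(0, 0.1),
                                        resting = c(0, 0.02),
                                        caching = c(0.1, 0.4),
                                        trotting = c(1.8, 3.0),
                                        walking = c(0.7, 1.3)),
                          start = as.POSIXct("2018-06-01 00:00:00",
                                             tz = "UTC"),
                          animal_id = "wild1") {
  if (any(abs(rowSums(schedule) - 1) > 1e-8))
    stop("schedule rows must sum to 1")
  structure(list(days = days, cadence_s = cadence_s,
                 gps_interval_s = gps_interval_s, stickiness = stickiness,
                 schedule = schedule, lat0 = lat0, lon0 = lon0,
                 dwell_radius_m = dwell_radius_m, speeds = speeds,
                 start = start, animal_id = animal_id),
            class = "wild_scenario")
}

#' Simulate a wild individual: bursts, GPS track and withheld truth
#'
#' The behaviour state is simulated per burst slot from the hourly
#' schedule with bout persistence (`stickiness`). The animal's position
#' advances each slot at a state-typical speed with a persistent random
#' heading; during resting bouts it stays jittering within
#' `dwell_radius_m` of the bout anchor, so resting produces the
#' stationary GPS clusters the validation procedures look for. GPS fixes
#' are emitted on their own schedule. The emitted bursts are unlabelled;
#' the true behaviour per burst is returned separately.
#'
#' @param scenario A [wild_scenario()].
#' @param model A [behaviour_signal_model()].
#' @param n,rate Burst geometry.
#' @param seed Integer seed.
#' @return List with `bursts` (unlabelled `acc_bursts`), `gps` (data
#'   frame `animal_id`, `time`, `lat`, `lon`) and `truth` (data frame
#'   `burst_id`, `behaviour`).
#' @export
generate_wild_track <- function(scenario = wild_scenario(),
                                model = behaviour_signal_model(),
                                n = 110, rate = 33.33, seed = 1L) {
  set.seed(seed)
  sc <- scenario
  classes <- colnames(sc$schedule)
  n_slots <- as.integer(sc$days * 86400 / sc$cadence_s)
  times <- sc$start + (seq_len(n_slots) - 1) * sc$cadence_s
  hours <- as.integer(format(times, "%H", tz = "UTC"))

  state <- character(n_slots)
  state[1] <- sample(classes, 1, prob = sc$schedule[hours[1] + 1, ])
  for (i in seq_len(n_slots)[-1]) {
    state[i] <- if (stats::runif(1) < sc$stickiness) state[i - 1]
    else sample(classes, 1, prob = sc$schedule[hours[i] + 1, ])
  }

  # position simulation in local metres, converted to lat/lon at the end
  pos <- matrix(0, n_slots, 2)
  heading <- stats::runif(1, 0, 2 * pi)
  anchor <- c(0, 0)
  resting_bout <- FALSE
  for (i in seq_len(n_slots)[-1]) {
    cl <- state[i]
    if (cl == "resting") {
      if (!resting_bout) { anchor <- pos[i - 1, ]; resting_bout <- TRUE }
      jit <- stats::runif(1, 0, sc$dwell_radius_m / 3)
      ang <- stats::runif(1, 0, 2 * pi)
      pos[i, ] <- anchor + jit * c(cos(ang), sin(ang))
    } else {
      resting_bout <- FALSE
      heading <- heading + stats::rnorm(1, sd = 0.4)
      sp <- stats::runif(1, sc$speeds[[cl]][1], sc$speeds[[cl]][2])
      step <- sp * sc$cadence_s
      pos[i, ] <- pos[i - 1, ] + step * c(cos(heading), sin(heading))
    }
  }
  lat <- sc$lat0 + pos[, 2] / 111320
  lon <- sc$lon0 + pos[, 1] / (111320 * cos(sc$lat0 * pi / 180))

  samples <- lapply(state, function(cl)
    generate_burst(cl, model, n = n, rate = rate))
  meta <- data.frame(
    burst_id = sprintf("%s_b%06d", sc$animal_id, seq_len(n_slots)),
    animal_id = sc$animal_id,
    burst_start = times,
    sampling_rate = rate,
    label = NA_character_,
    stringsAsFactors = FALSE)
  bursts <- acc_bursts(meta, samples)

  gps_every <- max(1L, as.integer(sc$gps_interval_s / sc$cadence_s))
  gi <- seq(1, n_slots, by = gps_every)
  gps <- data.frame(animal_id = sc$animal_id, time = times[gi],
                    lat = lat[gi], lon = lon[gi],
                    stringsAsFactors = FALSE)
  truth <- data.frame(burst_id = meta$burst_id, behaviour = state,
                      stringsAsFactors = FALSE)
  list(bursts = bursts, gps = gps, truth = truth)
}
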