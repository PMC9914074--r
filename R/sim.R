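#' Simulator configuration for synthetic excretion events
#'
#' Defines the generative model used in place of bedside data collection:
#' for each event class, true channel excursions are drawn uniformly from
#' the detection-table intervals (unbounded sides capped at physically
#' generous excursions: urine temperature < 4 degC, humidity < 45 \%RH,
#' ammonia < 10 ppm); "none" events have zero true excursion. The excursion
#' is constant within a session (the excretion happened once); every
#' individual read then passes through the sensor observation model
#' ([apply_sensor_model()]) with Gaussian noise and datasheet clipping.
#'
#' @param baseline named numeric indoor environment (`temperature` degC,
#'   `humidity` \%RH, ambient `ammonia` ppm).
#' @param class_deltas per-class, per-channel `c(lo, hi)` ranges of the true
#'   excursion.
#' @param noise_sd named numeric per-read Gaussian noise SD per channel.
#' @param cycles,reads_per_cycle session geometry (default 3 cycles of 2
#'   reads, i.e. reads at nearby moments repeated over three cycles).
#' @param spec a [sensor_spec()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(baseline = c(temperature = 22, humidity = 40,
                                    ammonia = 0),
                       class_deltas = default_class_deltas(),
                       noise_sd = c(temperature = 0.4, humidity = 4,
                                    ammonia = 0.6),
                       cycles = 3, reads_per_cycle = 2,
                       spec = sensor_spec()) {
  baseline <- .named_channels(baseline, "baseline")
  noise_sd <- .named_channels(noise_sd, "noise_sd")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(cycles >= 1, reads_per_cycle >= 1)
  for (ev in event_labels()) {
    cd <- class_deltas[[ev]]
    if (is.null(cd)) stop("class_deltas lacks class ", ev, call. = FALSE)
    for (ch in sensor_channels()) {
      r <- cd[[ch]]
      if (length(r) != 2L || r[1] > r[2]) {
        stop(sprintf("bad delta range for %s/%s", ev, ch), call. = FALSE)
      }
    }
  }
  structure(list(baseline = baseline, class_deltas = class_deltas,
                 noise_sd = noise_sd, cycles = cycles,
                 reads_per_cycle = reads_per_cycle, spec = spec),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_class_deltas <- function() {
  list(
    urine = list(temperature = c(1.8, 4), humidity = c(20, 45),
                 ammonia = c(2, 10)),
    stool = list(temperature = c(0.5, 2), humidity = c(5, 12),
                 ammonia = c(1, 2)),
    both  = list(temperature = c(0, 1), humidity = c(12, 20),
                 ammonia = c(1, 2)),
    none  = list(temperature = c(0, 0), humidity = c(0, 0),
                 ammonia = c(0, 0))
  )
}

#' Sensor measurement specification
#'
#' Measurable ranges of the installed sensors: the DHT22 reads humidity over
#' 0-99.9 \%RH and temperature over -40 to 80 degC; the GM-802B ammonia
#' sensor detects 1-300 ppm and reports 0 below its 1 ppm floor; the MPU6050
#' angle sensor covers +/-180 degrees (X/Z axes) and +/-90 degrees (Y).
#'
#' @return an object of class `sensor_spec`.
#' @export
sensor_spec <- function() {
  structure(list(
    temperature = list(range = c(-40, 80)),
    humidity = list(range = c(0, 99.9)),
    ammonia = list(range = c(0, 300), floor = 1),
    angle = list(range = c(-180, 180))
  ), class = "sensor_spec")
}

#' Sensor observation model
#'
#' Adds Gaussian read noise to a true value and applies the datasheet
#' constraints: clipping to the measurable range, and for ammonia the 1 ppm
#' detection floor below which the sensor reports 0.
#'
#' @param true_value numeric vector of true physical values.
#' @param channel one of `"temperature"`, `"humidity"`, `"ammonia"`.
#' @param spec a [sensor_spec()].
#' @param noise_sd Gaussian noise standard deviation (0 for a noiseless
#'   sensor).
#' @return simulated readings, same length as `true_value`.
#' @examples
#' apply_sensor_model(120, "humidity", noise_sd = 0) # clipped to 99.9
#' apply_sensor_model(0.4, "ammonia", noise_sd = 0)  # below floor -> 0
#' @export
apply_sensor_model <- function(true_value, channel, spec = sensor_spec(),
                               noise_sd = 0) {
  channel <- match.arg(channel, sensor_channels())
  s <- spec[[channel]]
  v <- true_value + if (noise_sd > 0) stats::rnorm(length(true_value), 0, noise_sd) else 0
  v <- pmin(pmax(v, s$range[1]), s$range[2])
  if (!is.null(s$floor)) v[v < s$floor] <- 0
  v
}

#' Simulate one labelled reading session
#'
#' Draws one true excursion per channel from the class distribution, adds
#' the environment baselines, and observes it through the sensor model for
#' every cycle and read. Uses R's global random number generator; seed it
#' (or use [simulate_dataset()]) for reproducibility.
#'
#' @param label event class to generate (see [event_labels()]).
#' @param config a [sim_config()].
#' @param session_id identifier for the generated session.
#' @return a single-session data frame carrying `true_label`.
#' @export
simulate_event <- function(label, config = sim_config(), session_id = "S1") {
  label <- as_event_label(label)
  cd <- config$class_deltas[[label]]
  truth <- vapply(sensor_channels(), function(ch) {
    r <- cd[[ch]]
    config$baseline[[ch]] + if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  }, 0)
  grid <- expand.grid(read_index = seq_len(config$reads_per_cycle),
                      channel = sensor_channels(),
                      cycle = seq_len(config$cycles),
                      stringsAsFactors = FALSE)
  grid$value <- NA_real_
  for (ch in sensor_channels()) {
    i <- grid$channel == ch
    grid$value[i] <- apply_sensor_model(rep(truth[[ch]], sum(i)), ch,
                                        config$spec, config$noise_sd[[ch]])
  }
  reading_session(session_id,
                  grid[c("cycle", "channel", "read_index", "value")],
                  true_label = label)
}

#' Simulate a balanced labelled dataset
#'
#' Generates `n_per_class` sessions for each of the four event classes,
#' shuffled into random order, reproducibly from `seed`.
#'
#' @param n_per_class sessions per class (>= 1).
#' @param config a [sim_config()].
#' @param seed integer seed driving all randomness.
#' @return a sessions data frame of `4 * n_per_class` labelled sessions.
#' @examples
#' d <- simulate_dataset(2, seed = 1)
#' length(unique(d$session_id)) # 8
#' @export
simulate_dataset <- function(n_per_class, config = sim_config(), seed = 1) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  labels <- sample(rep(event_labels(), n_per_class))
  ids <- sprintf("S%04d", seq_along(labels))
  out <- do.call(rbind, lapply(seq_along(labels), function(i) {
    simulate_event(labels[i], config, session_id = ids[i])
  }))
  rownames(out) <- NULL
  out
}
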