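#' Actuator schedules for the care workflow
#'
#' A schedule is a table of timed on/off intervals, one row per actuator
#' activation: columns `actuator` (one of `flush_valve_stool`,
#' `flush_valve_urine`, `clean_valve_stool`, `clean_valve_urine`, `pump`,
#' `vacuum`, `heater`, `fan`, `buzzer`), `on_s` and `off_s` (seconds from
#' workflow start). Intervals for one actuator never overlap and always
#' satisfy `off_s > on_s`.
#'
#' @param rows data frame with columns `actuator`, `on_s`, `off_s`.
#' @return an `actuator_schedule` data frame.
#' @export
actuator_schedule <- function(rows) {
  stopifnot(all(c("actuator", "on_s", "off_s") %in% names(rows)))
  known <- c("flush_valve_stool", "flush_valve_urine", "clean_valve_stool",
             "clean_valve_urine", "pump", "vacuum", "heater", "fan", "buzzer")
  bad <- setdiff(rows$actuator, known)
  if (length(bad)) stop("unknown actuator(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(rows$off_s <= rows$on_s)) {
    stop("every interval needs off_s > on_s", call. = FALSE)
  }
  for (a in unique(rows$actuator)) {
    iv <- rows[rows$actuator == a, ]
    iv <- iv[order(iv$on_s), ]
    if (nrow(iv) > 1L && any(iv$on_s[-1] < iv$off_s[-nrow(iv)])) {
      stop("overlapping intervals for actuator ", a, call. = FALSE)
    }
  }
  rows <- rows[order(rows$on_s, rows$actuator), ]
  rownames(rows) <- NULL
  class(rows) <- c("actuator_schedule", "data.frame")
  rows
}

#' @rdname actuator_schedule
#' @param schedule an `actuator_schedule`.
#' @param actuator actuator name.
#' @return `actuator_on_time()` returns the total seconds the actuator is on.
#' @export
actuator_on_time <- function(schedule, actuator) {
  iv <- schedule[schedule$actuator == actuator, ]
  sum(iv$off_s - iv$on_s)
}

#' @rdname actuator_schedule
#' @return `schedule_duration()` returns the end time of the schedule in
#'   seconds.
#' @export
schedule_duration <- function(schedule) max(schedule$off_s)

#' @export
print.actuator_schedule <- function(x, ...) {
  cat("<actuator schedule>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %6.0f-%6.0f s  %s\n", x$on_s[i], x$off_s[i], x$actuator[i]))
  }
  invisible(x)
}

#' Flushing phase of the care workflow
#'
#' For stool (and for combined urine-and-stool, which follows the stool
#' branch because it already opens both water circuits): both flush valves
#' and the pump start immediately; after 5 s the vacuum pump joins; after a
#' further 5 s the pump and valves stop; the vacuum continues alone for 8 s.
#' For urine: a 10 s delay allows re-detection of a following stool event,
#' then the urine flush valve and pump run for 5 s, followed by the vacuum
#' alone for 10 s.
#'
#' @param label event to flush (not `"none"`).
#' @param t0 start time offset in seconds.
#' @return an [actuator_schedule()].
#' @examples
#' s <- run_flush("stool")
#' actuator_on_time(s, "pump")   # 10
#' actuator_on_time(s, "vacuum") # 13
#' @export
run_flush <- function(label, t0 = 0) {
  label <- as_event_label(label)
  if (label == "none") {
    stop("no flushing action for a 'none' event", call. = FALSE)
  }
  rows <- if (label %in% c("stool", "both")) {
    data.frame(
      actuator = c("flush_valve_stool", "flush_valve_urine", "pump", "vacuum"),
      on_s = t0 + c(0, 0, 0, 5),
      off_s = t0 + c(10, 10, 10, 18))
  } else {
    data.frame(
      actuator = c("flush_valve_urine", "pump", "vacuum"),
      on_s = t0 + c(10, 10, 15),
      off_s = t0 + c(15, 15, 25))
  }
  actuator_schedule(rows)
}

#' Cleaning and drying phase of the care workflow
#'
#' After flushing, the excretion site is washed for `clean_s` seconds (both
#' cleaning valves plus pump and vacuum for stool or combined events; the
#' urine cleaning valve plus pump and vacuum for urine-only), then dried:
#' the heater and fan start together, the heater stops after 8 minutes and
#' the fan 2 minutes later.
#'
#' @param label event being handled (not `"none"`).
#' @param t0 start time offset in seconds (typically the flush end).
#' @param clean_s cleaning duration in seconds. The printed control flow
#'   only times the stool branch; the urine branch is assumed symmetric.
#' @param heater_s,fan_extra_s drying times: heater on-time and the extra
#'   fan run after the heater stops.
#' @return an [actuator_schedule()].
#' @examples
#' s <- run_clean_dry("urine")
#' actuator_on_time(s, "heater") # 480
#' actuator_on_time(s, "fan")    # 600
#' @export
run_clean_dry <- function(label, t0 = 0, clean_s = 15, heater_s = 480,
                          fan_extra_s = 120) {
  label <- as_event_label(label)
  if (label == "none") {
    stop("no cleaning action for a 'none' event", call. = FALSE)
  }
  valves <- if (label %in% c("stool", "both")) {
    c("clean_valve_stool", "clean_valve_urine")
  } else "clean_valve_urine"
  clean <- data.frame(actuator = c(valves, "pump", "vacuum"),
                      on_s = t0, off_s = t0 + clean_s)
  dry0 <- t0 + clean_s
  dry <- data.frame(actuator = c("heater", "fan"),
                    on_s = dry0,
                    off_s = dry0 + c(heater_s, heater_s + fan_extra_s))
  actuator_schedule(rbind(clean, dry))
}

#' Full flush-clean-dry workflow for a detected event
#'
#' Chains [run_flush()] and [run_clean_dry()]: cleaning starts when the
#' flush schedule ends. Total durations with the default timings are 633 s
#' for stool or combined events (18 s flush + 15 s clean + 600 s dry) and
#' 640 s for urine (10 s delay + 5 s flush + 10 s suction + 15 s clean +
#' 600 s dry).
#'
#' @inheritParams run_flush
#' @param ... passed to [run_clean_dry()].
#' @return an [actuator_schedule()].
#' @export
run_workflow <- function(label, t0 = 0, ...) {
  flush <- run_flush(label, t0)
  clean <- run_clean_dry(label, t0 = schedule_duration(flush), ...)
  actuator_schedule(rbind(as.data.frame(flush), as.data.frame(clean)))
}

#' Alarm logic of the nursing device
#'
#' The device alarms (via the buzzer) when the patient's side angle leaves
#' the safe range of -30 to 30 degrees, when the clean-water tank level
#' falls below its threshold, or when the dirt tank level rises above its
#' threshold.
#'
#' @param angle side angle in degrees (must be within the +/-180 degree
#'   sensor range).
#' @param clean_level clean-water level as a fraction of its threshold.
#' @param dirt_level dirt-tank level as a fraction of its threshold.
#' @return character vector of active alarms (subset of `"angle"`,
#'   `"clean_water_low"`, `"dirt_high"`), with attribute `buzzer` TRUE when
#'   any alarm is active.
#' @examples
#' check_alarms(45)                  # angle alarm
#' check_alarms(0, 1.2, 0.5)         # nothing
#' @export
check_alarms <- function(angle = 0, clean_level = 1, dirt_level = 0) {
  rng <- sensor_spec()$angle$range
  if (angle < rng[1] || angle > rng[2]) {
    stop("angle outside the +/-180 degree sensor range", call. = FALSE)
  }
  alarms <- character()
  if (angle < -30 || angle > 30) alarms <- c(alarms, "angle")
  if (clean_level < 1) alarms <- c(alarms, "clean_water_low")
  if (dirt_level > 1) alarms <- c(alarms, "dirt_high")
  structure(alarms, buzzer = length(alarms) > 0)
}

#' Write an actuator schedule as CSV
#'
#' @param schedule an [actuator_schedule()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
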