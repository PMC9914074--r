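test_that("stool flushing follows the printed pump/vacuum phasing", {
  s <- run_flush("stool")
  expect_equal(actuator_on_time(s, "pump"), 10)   # 5 s alone + 5 s with vacuum
  expect_equal(actuator_on_time(s, "vacuum"), 13) # 5 s joint + 8 s alone
  expect_equal(actuator_on_time(s, "flush_valve_stool"), 10)
  expect_equal(actuator_on_time(s, "flush_valve_urine"), 10)
  expect_equal(schedule_duration(s), 18)
  # combined urine-and-stool events take the stool branch
  expect_identical(as.data.frame(run_flush("both")), as.data.frame(s))
})

test_that("urine flushing waits for re-detection then flushes and suctions", {
  s <- run_flush("urine")
  expect_equal(min(s$on_s), 10) # 10 s re-detection delay
  expect_equal(actuator_on_time(s, "pump"), 5)
  expect_equal(actuator_on_time(s, "vacuum"), 10)
  expect_false("flush_valve_stool" %in% s$actuator)
  expect_equal(schedule_duration(s), 25)
  expect_error(run_flush("none"), "no flushing action")
})

test_that("cleaning runs 15 s and drying heats 8 min with 2 min fan overrun", {
  for (lab in c("stool", "urine", "both")) {
    s <- run_clean_dry(lab)
    expect_equal(actuator_on_time(s, "heater"), 480)
    expect_equal(actuator_on_time(s, "fan"), 600)
    expect_equal(actuator_on_time(s, "pump"), 15)
    expect_equal(actuator_on_time(s, "vacuum"), 15)
  }
  expect_true("clean_valve_stool" %in% run_clean_dry("stool")$actuator)
  expect_false("clean_valve_stool" %in% run_clean_dry("urine")$actuator)
  expect_error(run_clean_dry("none"), "no cleaning action")
})

test_that("workflow totals and phase exclusivity hold", {
  stool <- run_workflow("stool")
  expect_equal(schedule_duration(stool), 633) # 18 + 15 + 600
  urine <- run_workflow("urine")
  expect_equal(schedule_duration(urine), 640) # 10 + 5 + 10 + 15 + 600
  for (s in list(stool, urine)) {
    pump <- s[s$actuator == "pump", ]
    heater <- s[s$actuator == "heater", ]
    # the pump never runs while the heater dries
    for (i in seq_len(nrow(pump))) {
      expect_true(all(pump$off_s[i] <= heater$on_s |
                        pump$on_s[i] >= heater$off_s))
    }
  }
})

test_that("schedules reject malformed intervals", {
  expect_error(actuator_schedule(data.frame(actuator = "pump", on_s = 5,
                                            off_s = 5)), "off_s > on_s")
  expect_error(actuator_schedule(data.frame(actuator = c("pump", "pump"),
                                            on_s = c(0, 4),
                                            off_s = c(5, 9))), "overlapping")
  expect_error(actuator_schedule(data.frame(actuator = "warp_drive", on_s = 0,
                                            off_s = 1)), "unknown actuator")
})

test_that("alarms fire on side angle and tank levels and drive the buzzer", {
  expect_identical(as.character(check_alarms(45)), "angle")
  expect_identical(as.character(check_alarms(-31)), "angle")
  expect_length(check_alarms(0, clean_level = 1, dirt_level = 0), 0L)
  expect_false(attr(check_alarms(0), "buzzer"))
  expect_identical(as.character(check_alarms(0, dirt_level = 1.2)),
                   "dirt_high")
  expect_identical(as.character(check_alarms(0, clean_level = 0.5)),
                   "clean_water_low")
  a <- check_alarms(90, clean_level = 0.2, dirt_level = 1.5)
  expect_length(a, 3L)
  expect_true(attr(a, "buzzer"))
  expect_error(check_alarms(200), "sensor range")
})
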