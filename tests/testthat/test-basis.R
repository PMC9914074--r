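crisp <- detection_basis(softness = 0)

test_that("excursions subtract the configured environment baseline", {
  b <- detection_basis(baseline = c(temperature = 15.1, humidity = 22.9,
                                    ammonia = 0))
  expect_equal(compute_deltas(c(16.1, 27.9, 1.0), b),
               c(temperature = 1.0, humidity = 5.0, ammonia = 1.0))
  expect_equal(unname(compute_deltas(c(15.1, 22.9, 0), b)), c(0, 0, 0))
  # ammonia cannot fall below ambient
  expect_equal(compute_deltas(c(16, 23, -0.5), b)[["ammonia"]], 0)
  nb <- detection_basis(baseline = c(temperature = NA, humidity = NA,
                                     ammonia = NA))
  expect_error(compute_deltas(c(16, 23, 0), nb), "baseline")
})

test_that("crisp memberships honour the printed intervals and boundaries", {
  # a humidity excursion of 25 %RH is unambiguous urine
  expect_equal(unclass(build_bpa(25, "humidity", crisp)), c(1, 0, 0, 0),
               ignore_attr = TRUE)
  # a zero excursion is owned by 'none'
  expect_equal(unclass(build_bpa(0, "temperature", crisp)), c(0, 0, 0, 1),
               ignore_attr = TRUE)
  # shared boundaries go to the class above: exactly 2 ppm is urine
  expect_equal(unclass(build_bpa(2, "ammonia", crisp)), c(1, 0, 0, 0),
               ignore_attr = TRUE)
  mu <- channel_membership(2, "ammonia", crisp)
  expect_equal(unname(mu), c(1, 0, 0, 0))
})

test_that("stool/both ambiguity is split proportionally or sent to the union", {
  # ammonia between 1 and 2 ppm is listed for both stool and stool-and-urine
  prop <- detection_basis(softness = 0, bpa_alloc = "proportional")
  expect_equal(unclass(build_bpa(1.5, "ammonia", prop)), c(0, 0.5, 0.5, 0),
               ignore_attr = TRUE)
  # the consonant allocation treats the shared evidence as ignorance
  # between the nested sets {s} and {u,s} and assigns it to the union
  expect_equal(unclass(build_bpa(1.5, "ammonia", crisp)), c(0, 0, 1, 0),
               ignore_attr = TRUE)
})

test_that("membership is bounded, continuous, and peaks on the true event", {
  b <- detection_basis() # default noise-matched softness
  for (ch in sensor_channels()) {
    grid <- seq(-2, 30, by = 0.01)
    mu <- vapply(grid, channel_membership, numeric(4), channel = ch, basis = b)
    expect_true(all(mu >= 0 & mu <= 1 + 1e-12))
    # no jumps: bounded difference between neighbouring grid points
    expect_lt(max(abs(t(apply(mu, 1, diff)))), 0.05)
  }
  # excursions interior to exactly one event's interval classify to it
  cases <- list(
    list(1.4, "temperature", "stool"), list(8, "humidity", "stool"),
    list(16, "humidity", "both"), list(30, "humidity", "urine"),
    list(5, "ammonia", "urine"), list(0.3, "temperature", "both"))
  for (cs in cases) {
    m <- build_bpa(cs[[1]], cs[[2]], crisp)
    expect_identical(ds_decide(m), cs[[3]])
  }
})

test_that("direct classification majority-votes the printed intervals", {
  b <- detection_basis()
  expect_identical(direct_classify(c(1.0, 8, 1.5), b), "stool")
  expect_identical(direct_classify(c(2.5, 25, 3), b), "urine")
  expect_identical(direct_classify(c(0, 0, 0), b), "none")
  expect_identical(direct_classify(c(0.6, 15, 1.5), b), "both")
  # nothing matches anywhere -> none
  expect_identical(direct_classify(c(-3, -20, 0.9), b), "none")
})

test_that("a detection basis round-trips through YAML", {
  b <- detection_basis(baseline = c(temperature = 18, humidity = 35,
                                    ammonia = 0.2))
  path <- tempfile(fileext = ".yaml")
  write_basis(b, path)
  b2 <- read_basis(path)
  expect_equal(b2$intervals, b$intervals)
  expect_equal(b2$baseline, b$baseline)
  expect_equal(b2$softness, b$softness, tolerance = 1e-6) # YAML precision
  expect_identical(b2$bpa_alloc, b$bpa_alloc)

  # the packaged default basis matches the in-code defaults
  pkg <- read_basis(system.file("extdata", "table1.yaml", package = "dsnurse"))
  expect_equal(pkg$intervals, detection_basis()$intervals)
  expect_equal(pkg$baseline, detection_basis()$baseline)
})
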