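test_that("conflict coefficient matches hand-expanded worked cases", {
  m <- mass_function(rep(0.25, 4))
  expect_equal(conflict_coefficient(m, m), 0.5)

  m1 <- mass_function(c(0.2, 0.3, 0.4, 0.1))
  m2 <- mass_function(c(0, 0, 1, 0))
  expect_equal(conflict_coefficient(m1, m2), 0.9) # only D x C is empty

  a <- mass_function(c(1, 0, 0, 0))
  b <- mass_function(c(0, 1, 0, 0))
  expect_equal(conflict_coefficient(a, b), 0)
  expect_error(ds_combine(a, b), "total conflict")

  # K is one minus the mass on empty intersections (lattice cross-check)
  set.seed(42)
  for (i in 1:50) {
    x <- random_mass(); y <- random_mass()
    expect_equal(conflict_coefficient(x, y), oracle_conflict(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Dempster combination reproduces worked examples", {
  certain <- mass_function(c(1, 0, 0, 0))
  spread <- mass_function(c(0.5, 0.2, 0.2, 0.1))
  expect_equal(unclass(ds_combine(certain, spread)), c(1, 0, 0, 0),
               ignore_attr = TRUE)

  u <- mass_function(rep(0.25, 4))
  expect_equal(unclass(ds_combine(u, u)), c(0.375, 0.375, 0.125, 0.125),
               ignore_attr = TRUE)

  m1 <- mass_function(c(0.2, 0.3, 0.4, 0.1))
  m2 <- mass_function(c(0, 0, 1, 0))
  expect_equal(unclass(ds_combine(m1, m2)), c(2, 3, 4, 0) / 9,
               ignore_attr = TRUE)
})

test_that("combination is a valid, commutative, associative operation", {
  set.seed(7)
  for (i in 1:200) {
    x <- floor_mass(random_mass())
    y <- floor_mass(random_mass())
    z <- floor_mass(random_mass())
    xy <- ds_combine(x, y)
    expect_true(all(unclass(xy) >= 0))
    expect_equal(sum(xy), 1, tolerance = 1e-12)
    expect_equal(unclass(xy), unclass(ds_combine(y, x)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(unclass(ds_combine(xy, z)),
                 unclass(ds_combine(x, ds_combine(y, z))),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # n-ary fusion is the left fold
    expect_equal(unclass(ds_fuse(list(x, y, z))),
                 unclass(ds_combine(ds_combine(x, y), z)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  single <- random_mass()
  expect_identical(ds_fuse(list(single)), single)
  expect_error(ds_fuse(list()), "non-empty")
})

test_that("combine agrees with a generic subset-lattice Dempster oracle", {
  set.seed(1)
  n <- 10000
  max_err <- 0
  agree <- TRUE
  for (i in seq_len(n)) {
    x <- random_mass(); y <- random_mass()
    got <- tryCatch(ds_combine(x, y), error = function(e) NULL)
    want <- tryCatch(oracle_combine(x, y), error = function(e) NULL)
    agree <- agree && identical(is.null(got), is.null(want))
    if (!is.null(got) && !is.null(want)) {
      max_err <- max(max_err, max(abs(unclass(got) - unclass(want))))
    }
  }
  expect_true(agree)
  expect_lt(max_err, 1e-9)
})

test_that("a certain singleton is absorbing unless totally conflicting", {
  certain <- mass_function(c(0, 1, 0, 0)) # sure of stool
  set.seed(11)
  for (i in 1:100) {
    other <- floor_mass(random_mass()) # flooring guarantees K > 0
    expect_equal(unclass(ds_combine(certain, other)), c(0, 1, 0, 0),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("iterated self-fusion polarizes and can flip a union-heavy decision", {
  # repeated fusion cycles are claimed to only sharpen the result; that is
  # true for singleton-led masses but falsifiable when the union event C
  # leads, because C only retains its diagonal product
  m <- mass_function(c(0.3, 0.15, 0.4, 0.15))
  expect_identical(ds_decide(m), "both")
  twice <- ds_combine(m, m)
  expect_identical(ds_decide(twice), "urine") # decision flipped away from C

  # singleton-led masses do sharpen without flipping
  s <- mass_function(c(0.6, 0.2, 0.1, 0.1))
  s2 <- ds_combine(s, s)
  expect_identical(ds_decide(s2), "urine")
  expect_gt(s2[["urine"]], s[["urine"]])
})

test_that("decision takes the maximal mass with severity tie-breaking", {
  expect_identical(ds_decide(mass_function(c(0.1, 0.2, 0.6, 0.1))), "both")
  expect_identical(ds_decide(mass_function(c(0.4, 0.4, 0.1, 0.1))), "stool")
  expect_identical(ds_decide(mass_function(c(0, 0, 0, 1))), "none")
  expect_identical(ds_decide(mass_function(rep(0.25, 4))), "both")
})

test_that("mass functions validate and serialize round-trip", {
  expect_error(mass_function(c(0.5, 0.5, 0.5, -0.5)), "non-negative")
  expect_error(mass_function(c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(mass_function(c(0.5, 0.5)), "4 masses")

  m <- mass_function(c(0.2, 0.3, 0.4, 0.1))
  d <- as.data.frame(m)
  expect_named(d, c("m_A", "m_B", "m_C", "m_D"))
  back <- masses_from_df(d)[[1]]
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)

  expect_identical(as_event_label(c("A", "b", "both", "NONE")),
                   c("urine", "stool", "both", "none"))
  expect_error(as_event_label("wet"), "unknown event")
})
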