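test_that("degree-pixel conversion reproduces the calibrated sizes", {
  g <- screen_geometry()
  expect_identical(deg_to_px(5, g), 270L)    # calibration pair, exact
  expect_identical(deg_to_px(2.5, g), 135L)  # recurrence radius
  expect_identical(deg_to_px(0, g), 0L)
  expect_error(deg_to_px(-1, g), "non-negative")
  expect_error(deg_to_px(NaN, g), "finite")
})

test_that("conversion is strictly increasing and px_to_deg inverts it", {
  g <- screen_geometry()
  angles <- seq(0.1, 20, by = 0.1)
  raw_px <- 2 * g$distance_mm * tan(angles * pi / 360) / g$pitch_mm
  expect_true(all(diff(raw_px) > 0))
  # inverse within one pixel's angular size after rounding
  one_px_deg <- px_to_deg(1, g)
  back <- px_to_deg(deg_to_px(angles, g), g)
  expect_true(all(abs(back - angles) <= one_px_deg))
  # exact inverse before rounding
  expect_equal(px_to_deg(raw_px, g), angles, tolerance = 1e-12)
})

test_that("geometry rejects impossible inputs", {
  expect_error(screen_geometry(width_px = 0), "positive")
  expect_error(screen_geometry(distance_mm = -5), "positive")
  expect_error(screen_geometry(calib_deg = 0), "calibration")
})

test_that("fixation report reader groups rows and validates onsets", {
  f <- tempfile(fileext = ".tsv")
  lines <- c(
    "participant\ttrial\tphase\tcondition\tcategory\tonset_ms\tduration_ms\tx_px\ty_px",
    "p01\tt01\tencoding\tFP\tindoor\t0\t200\t100.00\t100.00",
    "p01\tt01\tencoding\tFP\tindoor\t300\t250\t500.50\t400.25",
    "p01\tt01\tencoding\tFP\tindoor\t600\t180\t900.00\t200.00")
  writeLines(lines, f)
  sps <- read_fixation_report(f, GEOM)
  expect_length(sps, 1)
  expect_equal(n_fixations(sps[[1]]), 3)
  expect_equal(sps[[1]]$fixations$x_px[2], 500.5)
  expect_equal(sps[[1]]$condition, "FP")

  # write(read(f)) is byte-identical on the canonical dialect
  f2 <- tempfile(fileext = ".tsv")
  write_fixation_report(sps, f2)
  expect_identical(readLines(f2), lines)

  # non-monotone onsets within a group name the group
  writeLines(c(lines[1],
               "p01\tt01\tencoding\tFP\tindoor\t100\t200\t100.00\t100.00",
               "p01\tt01\tencoding\tFP\tindoor\t50\t200\t200.00\t200.00"), f)
  expect_error(read_fixation_report(f, GEOM), "p01/t01/encoding")

  # missing mandatory column is named
  writeLines(c("participant\ttrial\tphase\tcondition\tcategory\tonset_ms\tduration_ms\tx_px",
               "p01\tt01\tencoding\tFP\tindoor\t0\t200\t100.00"), f)
  expect_error(read_fixation_report(f, GEOM), "y_px")
})

test_that("writer handles empty input and round-trips random scanpaths", {
  f <- tempfile(fileext = ".tsv")
  write_fixation_report(list(), f)
  expect_length(readLines(f), 1)  # header only

  sp <- quick_scanpath(c(10.25, 20.5), c(30, 40.75), dur = c(150, 300))
  write_fixation_report(sp, f)
  expect_length(readLines(f), 3)

  set.seed(11)
  sps <- lapply(1:4, function(i) {
    sp <- random_clustered_scanpath(10)
    sp$fixations$x_px <- round(sp$fixations$x_px, 2)
    sp$fixations$y_px <- round(sp$fixations$y_px, 2)
    sp$participant <- sprintf("p%02d", i)
    sp
  })
  write_fixation_report(sps, f)
  back <- read_fixation_report(f, GEOM)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(back[[i]]$fixations$x_px, sps[[i]]$fixations$x_px)
    expect_equal(back[[i]]$fixations$onset_ms, sps[[i]]$fixations$onset_ms)
  }
  # second write is identical to the first (reader/writer fixed point)
  f3 <- tempfile(fileext = ".tsv")
  write_fixation_report(back, f3)
  expect_identical(readLines(f3), readLines(f))
})

test_that("comma-separated dialect is accepted on read", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("participant,trial,phase,condition,category,onset_ms,duration_ms,x_px,y_px",
               "p01,t01,imagery,AS,outdoor,0,200,10.00,20.00",
               "p01,t01,imagery,AS,outdoor,300,200,30.00,40.00"), f)
  sps <- read_fixation_report(f, GEOM)
  expect_equal(n_fixations(sps[[1]]), 2)
  expect_equal(sps[[1]]$phase, "imagery")
})

test_that("raw track io round-trips and validates", {
  tr <- raw_track(0:9, seq(100, 109), rep(500, 10),
                  c(rep(TRUE, 5), FALSE, rep(TRUE, 4)))
  f <- tempfile(fileext = ".tsv")
  write_raw_track(tr, f)
  back <- read_raw_track(f)
  expect_equal(back$x_px, tr$x_px)
  expect_equal(back$valid, tr$valid)
  expect_error(raw_track(c(0, 1, 1), 1:3, 1:3), "strictly increasing")
  expect_error(raw_track(0:2, 1:2, 1:3), "equal length")
})

test_that("scanpath constructor enforces its invariants", {
  expect_error(quick_scanpath(c(1, 2), c(1, 2), onset = c(100, 50)),
               "strictly increasing")
  expect_error(quick_scanpath(1, 1, dur = 0), "positive")
  expect_error(scanpath(data.frame(onset_ms = 0, duration_ms = 1, x_px = 1),
                        geometry = GEOM), "y_px")
  expect_error(quick_scanpath(1, 1, condition = "XX"), "condition")
})
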