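ctx <- physical_context(298.15)

test_that("CV files round-trip data and metadata losslessly", {
  w <- wave_params(-0.3, -0.45, 1, 0.5)
  v <- make_cv(w, ctx)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cv(v, path)
  back <- read_cv(path)
  expect_equal(back$potential, v$potential, tolerance = 1e-9)
  expect_equal(back$current, v$current, tolerance = 1e-9)
  expect_equal(back$meta$pH, v$meta$pH)
  expect_equal(back$meta$reference, v$meta$reference)
  expect_equal(back$meta$sequence_index, v$meta$sequence_index)
})

test_that("CV parser flags malformed files and converts mV tags", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# role: blank", "potential", "0.1", "0.2"), path)
  expect_error(read_cv(path), "current")
  writeLines(c("# potential_unit: mV", "potential\tcurrent",
               paste(seq(-500, 100, length.out = 20) ,
                     seq(-1, 1, length.out = 20), sep = "\t")), path)
  v <- read_cv(path)
  expect_equal(range(v$potential), c(-0.5, 0.1))
  expect_error(read_cv(withr::local_tempfile(fileext = ".csv")), "not found")
})

test_that("SCE to SHE conversion shifts by +241 mV and is idempotent", {
  w <- wave_params(-0.3, -0.45, 1, 0.5)
  v <- make_cv(w, ctx,
               meta = list(role = "blank", reference = "SCE"))
  v$potential[1] <- v$potential[1]  # no-op; keep grid
  conv <- to_she(v)
  expect_equal(conv$potential, v$potential + 0.241)
  expect_equal(conv$meta$reference, "SHE")
  expect_identical(to_she(conv)$potential, conv$potential)
  v$meta$reference <- NULL
  expect_error(to_she(v), "unknown|cannot convert")
  v$meta$reference <- "Ag/AgCl"
  expect_error(to_she(v), "unknown")
})

test_that("sweep averaging cancels direction-antisymmetric offsets", {
  w <- wave_params(-0.3, -0.45, 1, 0.5)
  n <- 300
  down <- seq(0.05, -1, length.out = n)
  E <- c(down, rev(down)[-1])
  i_model <- steady_state_current(E, w, ctx)
  direction <- c(rep(-1, n), rep(1, n - 1))
  v <- voltammogram(E, i_model + 0.07 * direction, list(role = "blank"))
  avg <- split_and_average_sweeps(v)
  # the vertex itself is sampled in one direction only, so the offset
  # survives there; everywhere else the average cancels it
  inner <- avg$potential > min(avg$potential)
  expect_equal(avg$current[inner],
               steady_state_current(avg$potential[inner], w, ctx),
               tolerance = 1e-6)
  # hysteresis-free signal: average equals either sweep
  v2 <- voltammogram(E, i_model, list(role = "blank"))
  avg2 <- split_and_average_sweeps(v2)
  expect_equal(avg2$current,
               steady_state_current(avg2$potential, w, ctx),
               tolerance = 1e-9)
  # monotone program has no vertex
  v3 <- voltammogram(down, steady_state_current(down, w, ctx),
                     list(role = "blank"))
  expect_error(split_and_average_sweeps(v3), "vertex")
})

test_that("blank subtraction removes a known background polynomial", {
  w <- wave_params(-0.3, -0.45, 1, 0.5)
  E <- seq(-1, 0.05, length.out = 500)
  bg <- 0.04 - 0.12 * E + 0.3 * E^2
  sample <- voltammogram(E, steady_state_current(E, w, ctx) + bg,
                         list(role = "blank"))
  blank <- voltammogram(E, bg, list(role = "blank"))
  clean <- subtract_blank(sample, blank)
  expect_equal(clean$current,
               steady_state_current(clean$potential, w, ctx),
               tolerance = 1e-8)
  # blank equal to sample: all-zero current
  zero <- subtract_blank(sample, sample)
  expect_true(all(abs(zero$current) < 1e-14))
  # disjoint and under-overlapping ranges are rejected
  blank_far <- voltammogram(E + 2, bg, list(role = "blank"))
  expect_error(subtract_blank(sample, blank_far), "disjoint")
  blank_part <- voltammogram(E[E > -0.4], bg[E > -0.4], list(role = "blank"))
  expect_error(subtract_blank(sample, blank_part), "50%")
})

test_that("film-loss normalization restores plateaus from reference scans", {
  w <- wave_params(-0.3, -0.45, 1, 0.5)
  lambda <- 0.05
  make_scan <- function(idx, role) {
    E <- seq(-1, 0.05, length.out = 300)
    i <- exp(-lambda * (idx - 1)) * steady_state_current(E, w, ctx)
    voltammogram(E, i, list(role = role, sequence_index = idx, pH = 7,
                            temperature_K = 298.15, h2_mM = 1,
                            scan_rate_V_s = 0.02, reference = "SHE"))
  }
  series <- list(make_scan(1, "reference_check"),
                 make_scan(2, "sample"),
                 make_scan(3, "reference_check"),
                 make_scan(4, "sample"),
                 make_scan(5, "reference_check"))
  out <- film_loss_normalize(series)
  expect_true(attr(out, "film_loss_normalized"))
  plateaus <- vapply(out, function(v)
    pfewave:::plateau_current(v, "top"), numeric(1))
  expect_true(all(abs(plateaus / plateaus[1] - 1) < 0.01))
  # stable film: identity
  stable <- list(make_scan(1, "reference_check"), make_scan(1, "sample"),
                 make_scan(1, "reference_check"))
  stable <- lapply(seq_along(stable), function(k) {
    stable[[k]]$meta$sequence_index <- k
    stable[[k]]
  })
  out2 <- film_loss_normalize(stable)
  expect_equal(out2[[2]]$current, stable[[2]]$current)
  # references only at the ends: log-linear interpolation still recovers
  # the intermediate decay exactly (exponential loss is linear in log)
  ends <- list(make_scan(1, "reference_check"), make_scan(2, "sample"),
               make_scan(3, "sample"), make_scan(4, "reference_check"))
  out3 <- film_loss_normalize(ends)
  p3 <- vapply(out3, function(v) pfewave:::plateau_current(v, "top"),
               numeric(1))
  expect_equal(p3 / p3[1], rep(1, 4), tolerance = 1e-9)
  # no references: warn and pass through
  expect_warning(out4 <- film_loss_normalize(list(make_scan(1, "sample"),
                                                  make_scan(2, "sample"))),
                 "skipped")
  expect_false(attr(out4, "film_loss_normalized"))
})

test_that("voltammogram constructor enforces the container invariants", {
  expect_error(voltammogram(1:20 / 20, 1:19), "same length")
  expect_error(voltammogram(1:10 / 10, 1:10), "16")
  expect_error(voltammogram(seq(0, 0.05, length.out = 20), 1:20), "0.1 V")
  expect_error(voltammogram(seq(0, 1, length.out = 20), 1:20,
                            list(role = "sample", pH = 7)),
               "incomplete")
})
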