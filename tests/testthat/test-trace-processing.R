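test_that("trace correction is exact and unbiased", {
  raw <- data.frame(frame = 1:4, I_D = c(500, 400, 300, 200),
                    I_A = c(500, 600, 700, 800))
  # alpha = 0, bkg = 0: identity
  corr <- correct_trace(raw, 0, 0, 0)
  expect_equal(corr$I_D, raw$I_D)
  expect_equal(corr$I_A, raw$I_A)
  # known leakage: corrected E bias < 0.01 against the generating truth
  states <- data.frame(label = "X", mean_E = 0.42, sd_E = 0.03,
                       acceptor_dark = FALSE, wander = FALSE)
  path <- data.frame(state = "X", t_start = 0, t_end = 500)
  phys <- photophysics(n_frames = 5000, leakage = 0.07,
                       bleach_hazard_D = 0, bleach_hazard_A = 0)
  tr <- render_trace(path, states, phys, seed = 3)
  e <- fret_efficiency(correct_trace(tr, phys$bkg_D, phys$bkg_A, 0.07))
  expect_lt(abs(mean(e) - 0.42), 0.01)
  # an all-background trace is flagged unusable
  dark <- data.frame(frame = 1:100, I_D = rnorm(100, 50, 5),
                     I_A = rnorm(100, 50, 5))
  flagged <- correct_trace(dark, 50, 50, 0)
  expect_false(attr(flagged, "usable"))
  expect_equal(attr(flagged, "reason"), "below_noise_floor")
  expect_error(correct_trace(raw, 0, 0, leakage = 1), "leakage")
})

test_that("fret_efficiency is the elementwise intensity ratio", {
  corr <- data.frame(I_D = c(300, 500, 0, 20), I_A = c(300, 0, 400, 30))
  e <- fret_efficiency(corr, min_total = 100)
  expect_equal(e[1], 0.5)
  expect_equal(e[2], 0)
  expect_equal(e[3], 1)
  expect_true(is.na(e[4]))   # below threshold
  # randomized fixture against direct hand computation
  set.seed(9)
  id <- runif(50, 100, 900); ia <- runif(50, 100, 900)
  expect_equal(fret_efficiency(data.frame(I_D = id, I_A = ia), 0),
               ia / (id + ia), tolerance = 1e-12)
})

test_that("adjacent averaging follows the stated truncation rule", {
  expect_equal(smooth_adjacent_average(rep(0.4, 20)), rep(0.4, 20))
  imp <- rep(0, 11); imp[6] <- 1
  sm <- smooth_adjacent_average(imp, 5)
  expect_equal(sm[4:8], rep(0.2, 5))
  expect_equal(sum(sm), 1)                   # mean-preserving interior
  edge <- c(1, rep(0, 10))
  expect_equal(smooth_adjacent_average(edge, 5)[1], 1 / 3)
  expect_error(smooth_adjacent_average(imp, 4), "odd")
  expect_equal(smooth_adjacent_average(imp, 1), imp)
  # missing frames are excluded, not interpolated
  x <- c(0.2, NA, 0.4)
  sm <- smooth_adjacent_average(x, 3)
  expect_true(is.na(sm[2]))
  expect_equal(sm[1], 0.2)
  expect_equal(sm[3], 0.4)
})

test_that("trajectory selection applies its rules with reason codes", {
  mk <- function(e, valid = length(e), truth = NULL, id = "t") {
    structure(list(E = e, valid_window = valid, frame_s = 0.1,
                   smoothed = FALSE, usable = TRUE, id = id, truth = truth),
              class = "fret_trace")
  }
  clean <- mk(rep(0.5, 200), id = "clean")
  short <- mk(rep(0.5, 200), valid = 10, id = "short")
  blink <- mk(replace(rep(0.5, 200), c(50, 120), NA), id = "blink")
  quench <- mk(replace(rep(0.5, 200), 60:70, NA), id = "quench")
  dbleach <- mk(rep(0.5, 200), id = "dbleach",
                truth = list(bleach_A = 40L, bleach_D = 900L))
  sel <- select_trajectories(list(clean, short, blink, quench, dbleach))
  expect_equal(sel$log$pass, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(sel$log$reason,
               c(NA, "short_window", NA, "quenching", "acceptor_dead"))
  # a clean fixture set passes in full
  all_clean <- lapply(1:5, function(i) mk(rep(0.5, 200), id = paste0("c", i)))
  expect_length(select_trajectories(all_clean)$kept, 5L)
})

test_that("population contours are column-normalised and synchronised", {
  mk <- function(e) structure(list(E = e, valid_window = length(e),
                                   frame_s = 0.1, smoothed = FALSE,
                                   usable = TRUE, id = "t", truth = NULL),
                              class = "fret_trace")
  # identical step traces with different pre-binding delays: after
  # synchronisation all mass lies on the common step path
  step <- function(delay) mk(c(rep(0.02, delay), rep(0.5, 100), rep(0.9, 100)))
  traces <- lapply(c(5, 20, 40), step)
  ct <- build_contour(traces, e_bins = seq(0, 1, 0.1),
                      time_bins = seq(0, 20, 2))
  expect_equal(colSums(ct$density), rep(1, ncol(ct$density)))
  expect_false(any(is.nan(ct$density)))
  # first time bins: all mass in the E = 0.5 bin
  expect_equal(ct$density[6, 1], 1)
  # no binding event anywhere -> error
  flat <- list(mk(rep(0.02, 300)))
  expect_error(build_contour(flat), "synchronisation event")
  # empty late bins stay zero without NaN
  shorttr <- list(mk(c(rep(0.02, 5), rep(0.6, 20))))
  ct2 <- build_contour(shorttr, time_bins = seq(0, 50, 5))
  expect_true(all(ct2$density[, ncol(ct2$density)] == 0))
})

test_that("binding detection needs a sustained rise", {
  e <- c(rep(0.05, 10), 0.5, rep(0.05, 10), rep(0.6, 5), rep(0.05, 5))
  expect_equal(detect_binding(e, 0.15, 3), 22L)   # single-frame spike skipped
  expect_true(is.na(detect_binding(rep(0.05, 50), 0.15, 3)))
})
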