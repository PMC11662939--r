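test_that("gillespie paths are seeded, exact and exponential", {
  # zero-rate scheme: one dwell covering the whole horizon
  z <- cleavage_scheme(cleavage_rates(0, 0, 0, 0))
  g <- simulate_state_path(z, duration_s = 50, seed = 1)
  expect_equal(nrow(g$jumps), 0L)
  seg <- path_segments(g, 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$t_end - seg$t_start, 50)
  # identical seeds give bit-identical ensembles
  fs <- fret_scheme()
  g1 <- simulate_state_path(fs, 100, seed = 7, n = 50)
  g2 <- simulate_state_path(fs, 100, seed = 7, n = 50)
  expect_identical(g1$jumps, g2$jumps)
  # two-state chain at k = 1/s: mean first-jump time 1 within 3 SE
  n <- 10000
  g <- simulate_state_path(two_state_scheme(1), duration_s = 50, seed = 2,
                           n = n)
  first <- g$jumps$time[!duplicated(g$jumps$path)]
  expect_length(first, n)
  expect_lt(abs(mean(first) - 1), 3 / sqrt(n))
})

test_that("simulated dwell times follow the scheme's exit rates", {
  k <- 0.4
  n <- 1000
  g <- simulate_state_path(two_state_scheme(k), duration_s = 1000, seed = 3,
                           n = n)
  dwell <- g$jumps$time[!duplicated(g$jumps$path)]
  ks <- stats::ks.test(dwell, "pexp", rate = k)
  expect_gt(ks$p.value, 0.01)
})

test_that("low Mg attenuates PAM-distal release", {
  n <- 2000
  frac_released <- function(mg) {
    sch <- fret_scheme(mg_mM = mg)
    g <- simulate_state_path(sch, duration_s = 170, seed = 5, n = n)
    st <- states_at(g, 170)
    mean(g$state_names[st] == "RELEASED")
  }
  expect_gt(frac_released(10), frac_released(1) + 0.2)
})

test_that("the trace renderer obeys its noise-free identities", {
  states <- data.frame(label = "X", mean_E = 0.5, sd_E = 0,
                       acceptor_dark = FALSE, wander = FALSE)
  path <- data.frame(state = "X", t_start = 0, t_end = 10)
  phys <- photophysics(n_frames = 100, bkg_D = 0, bkg_A = 0, leakage = 0,
                       noise_sd = 0, bleach_hazard_D = 0,
                       bleach_hazard_A = 0)
  tr <- render_trace(path, states, phys, seed = 1)
  expect_equal(tr$I_A, tr$I_D, tolerance = 1e-12)
  expect_equal(tr$I_A + tr$I_D, rep(phys$total_intensity, 100))
})

test_that("release extinguishes the acceptor signal", {
  fs <- fret_scheme()
  path <- data.frame(state = c("S2", "S3", "RELEASED"),
                     t_start = c(0, 40, 50), t_end = c(40, 50, 150))
  phys <- photophysics(bleach_hazard_D = 0, bleach_hazard_A = 0)
  tr <- render_trace(path, fs$states, phys, seed = 2)
  corr <- correct_trace(tr, phys$bkg_D, phys$bkg_A, phys$leakage)
  e <- fret_efficiency(corr)
  expect_gt(mean(e[300:390]), 0.4)           # S2 plateau
  expect_lt(mean(e[600:1400]), 0.05)         # acceptor lost after release
  expect_gt(mean(corr$I_D[600:1400]), 0.9 * phys$total_intensity)
})

test_that("rendered dwell means round-trip through the correction", {
  fs <- fret_scheme()
  # one long dwell per (non-wandering) state
  path <- data.frame(state = c("S1", "pS2", "S2prime", "S3"),
                     t_start = c(0, 40, 80, 120),
                     t_end = c(40, 80, 120, 150))
  phys <- photophysics(bleach_hazard_D = 0, bleach_hazard_A = 0)
  tr <- render_trace(path, fs$states, phys, seed = 4)
  e <- fret_efficiency(correct_trace(tr, phys$bkg_D, phys$bkg_A,
                                     phys$leakage))
  truth <- fs$states$mean_E[match(path$state, fs$states$label)]
  frames <- list(1:395, 405:795, 805:1195, 1205:1495)
  for (i in seq_along(frames))
    expect_lt(abs(mean(e[frames[[i]]]) - truth[i]), 0.02)
})

test_that("emission calibration: long constant-state traces match mean and sd", {
  states <- data.frame(label = "S2prime", mean_E = 0.6, sd_E = 0.035,
                       acceptor_dark = FALSE, wander = FALSE)
  path <- data.frame(state = "S2prime", t_start = 0, t_end = 1000)
  phys <- photophysics(n_frames = 10000, bkg_D = 0, bkg_A = 0, leakage = 0,
                       noise_sd = 2, bleach_hazard_D = 0,
                       bleach_hazard_A = 0)
  tr <- render_trace(path, states, phys, seed = 6)
  e <- fret_efficiency(correct_trace(tr))
  expect_lt(abs(mean(e) / 0.6 - 1), 0.02)
  expect_lt(abs(stats::sd(e) / 0.035 - 1), 0.02)
})

test_that("traces with donor-before-acceptor bleach are flagged by truth", {
  fs <- fret_scheme()
  phys <- photophysics(bleach_hazard_D = 0.01, bleach_hazard_A = 0)
  path <- data.frame(state = "S2prime", t_start = 0, t_end = 150)
  tr <- render_trace(path, fs$states, phys, seed = 8)
  expect_false(is.na(attr(tr, "truth")$bleach_D))
})

test_that("noisy band timecourses reduce to the deterministic solution", {
  sch <- cleavage_scheme()
  m3 <- map_nts3()
  tt <- c(0, 10, 60, 300)
  clean <- simulate_band_timecourse(sch, m3, tt, noise_sd = 0, seed = 1)
  ref <- project_bands(propagate(sch, tt), m3, sch)
  expect_equal(clean$fractions, ref$fractions)
  noisy <- simulate_band_timecourse(sch, m3, tt, noise_sd = 0.05, seed = 1)
  expect_equal(noisy$intact[1], 1)                  # t = 0 row noise-free
  expect_equal(unname(noisy$fractions[1, ]), rep(0, 5))
  expect_true(all(noisy$fractions >= 0 & noisy$fractions <= 1))
  noisy2 <- simulate_band_timecourse(sch, m3, tt, noise_sd = 0.05, seed = 1)
  expect_identical(noisy$fractions, noisy2$fractions)
})

test_that("trace files round-trip with their truth sidecar", {
  fs <- fret_scheme()
  traces <- simulate_fret_experiment(fs, n = 2, seed = 10)
  f <- tempfile(fileext = ".tsv")
  write_trace(traces[[1]], f)
  back <- read_trace(f)
  expect_equal(back$I_D, traces[[1]]$I_D, tolerance = 1e-8)
  expect_equal(attr(back, "truth")$state, attr(traces[[1]], "truth")$state)
  unlink(c(f, paste0(f, ".json")))
})
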