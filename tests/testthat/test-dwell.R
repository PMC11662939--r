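mk_ideal <- function(states, mu, frame_s = 0.1, id = "t") {
  r <- rle(states)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  structure(list(states = states,
                 segments = data.frame(state = r$values, start = starts,
                                       end = ends,
                                       censored_left = starts == 1L,
                                       censored_right = ends == length(states)),
                 mu = mu, frame_s = frame_s, id = id),
            class = "idealized_trace")
}

test_that("dwells are extracted exactly from a known path", {
  mu <- c(0.02, 0.55, 0.9)
  classes <- c("S1", "S2", "S3")
  # 30 frames S1, 50 frames S2, 20 frames S3, release back to baseline
  ide <- mk_ideal(c(rep(1L, 30), rep(2L, 50), rep(3L, 20), rep(1L, 100)),
                  mu)
  dw <- extract_dwells(list(ide), classes)
  expect_equal(dw$class, c("S1", "S2", "S3"))
  expect_equal(dw$dwell_s, c(3.0, 5.0, 2.0))
  expect_equal(dw$censored, rep(FALSE, 3))
  # S2 <-> pS2 excursions count toward t2; S3 interruptions do not
  classes4 <- c("S1", "pS2", "S2", "S3")
  mu4 <- c(0.02, 0.3, 0.55, 0.9)
  ide2 <- mk_ideal(c(rep(1L, 10), rep(2L, 20), rep(3L, 30), rep(2L, 10),
                     rep(3L, 10), rep(4L, 15), rep(1L, 50)), mu4)
  dw2 <- extract_dwells(list(ide2), classes4)
  expect_equal(dw2$dwell_s[dw2$class == "S2"], 7.0)  # 20+30+10+10 frames
  expect_equal(dw2$dwell_s[dw2$class == "S3"], 1.5)
})

test_that("dwells truncated by the trace boundary are censored", {
  mu <- c(0.02, 0.55, 0.9)
  classes <- c("S1", "S2", "S3")
  never_bound <- mk_ideal(rep(1L, 1500), mu)
  dw <- extract_dwells(list(never_bound), classes)
  expect_equal(dw$class, "S1")
  expect_true(dw$censored)
  expect_equal(dw$dwell_s, 150)
  still_s3 <- mk_ideal(c(rep(1L, 10), rep(2L, 10), rep(3L, 80)), mu)
  dw3 <- extract_dwells(list(still_s3), classes)
  expect_true(dw3$censored[dw3$class == "S3"])
})

test_that("transition density plots conserve mass and mark reversals", {
  mu <- c(0.02, 0.55, 0.9)
  # no transitions: an all-zero density, not NaN
  none <- mk_ideal(rep(2L, 100), mu)
  tdp0 <- build_tdp(list(none))
  expect_equal(sum(tdp0$density), 0)
  expect_false(any(is.nan(tdp0$density)))
  # two-state switching: two symmetric off-diagonal blobs
  sw <- mk_ideal(rep(c(rep(1L, 10), rep(2L, 10)), 10), mu)
  tdp <- build_tdp(list(sw))
  expect_equal(sum(tdp$density), 1)
  bin <- function(e) findInterval(e, tdp$bins, rightmost.closed = TRUE,
                                  all.inside = TRUE)
  up <- tdp$density[bin(0.02), bin(0.55)]
  down <- tdp$density[bin(0.55), bin(0.02)]
  expect_gt(up, 0)
  expect_equal(abs(up - down) <= 1 / tdp$n_transitions, TRUE)
  expect_equal(sum(diag(tdp$density)), 0)    # no self-transitions
})

test_that("low Mg enhances the S3 -> S2 rewinding density", {
  tdp_at <- function(mg, seed) {
    sch <- fret_scheme(mg_mM = mg)
    g <- simulate_state_path(sch, 170, seed = seed, n = 150)
    mu <- sch$states$mean_E
    ideal <- lapply(seq_len(150), function(i) {
      seg <- path_segments(g, i)
      frames <- pmax(1L, round((seg$t_end - seg$t_start) / 0.1))
      mk_ideal(rep(match(seg$state, sch$states$label), frames), mu)
    })
    build_tdp(ideal, bins = seq(0, 1, 0.1))
  }
  t10 <- tdp_at(10, 21)
  t5 <- tdp_at(5, 22)
  rewind <- function(t) t$density[10, 6]     # (0.9 -> 0.55) bin
  expect_gt(rewind(t5), rewind(t10))
})

test_that("survival analysis matches the empirical and exponential oracles", {
  # with no censoring the Kaplan-Meier curve is the empirical survival
  dw <- data.frame(dwell_s = c(2, 5, 5, 9), censored = rep(FALSE, 4))
  sc <- survival_curve(dw)
  expect_equal(sc$surv, c(1, 0.75, 0.25, 0))
  expect_equal(sc$time, c(0, 2, 5, 9))
  # censoring-aware exponential MLE: closed-form check
  dwc <- data.frame(dwell_s = c(2, 4, 6), censored = c(FALSE, TRUE, FALSE))
  fe <- fit_exponential(dwc)
  expect_equal(fe$tau, 12 / 2)
  expect_equal(fe$n_events, 2L)
  expect_error(fit_exponential(data.frame(dwell_s = 3, censored = TRUE)),
               "no events")
  # large-sample recovery within 3 standard errors
  set.seed(5)
  big <- data.frame(dwell_s = rexp(10000, 1 / 20), censored = FALSE)
  fe2 <- fit_exponential(big)
  expect_lt(abs(fe2$tau - 20), 3 * 20 / sqrt(10000))
  expect_true(fe2$ci[1] < 20 && 20 < fe2$ci[2])
})

test_that("state fractions summarise the ensemble with seeded bootstrap", {
  mu <- c(0.02, 0.3, 0.55, 0.9)
  classes <- c("S1", "pS2", "S2", "S3")
  released <- mk_ideal(c(rep(1L, 10), rep(3L, 20), rep(4L, 10), rep(1L, 60)),
                       mu)
  stuck <- mk_ideal(c(rep(1L, 10), rep(2L, 90)), mu)
  sf <- state_fractions(list(released, released), classes, n_boot = 20,
                        seed = 2)
  expect_equal(sf$release, 1)
  expect_equal(unname(sf$initial["S2"]), 1)
  sf2 <- state_fractions(list(released, stuck), classes, n_boot = 20,
                         seed = 2)
  expect_equal(sf2$release, 0.5)
  sf3 <- state_fractions(list(released, stuck), classes, n_boot = 20,
                         seed = 2)
  expect_identical(sf2$sd, sf3$sd)           # bootstrap reproducible
})

test_that("release fractions increase with Mg across the fixture ensembles", {
  frac <- function(mg) {
    sch <- fret_scheme(mg_mM = mg)
    g <- simulate_state_path(sch, 170, seed = 31, n = 300)
    st <- states_at(g, 170)
    mean(g$state_names[st] == "RELEASED")
  }
  f <- vapply(c(1, 3, 10), frac, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("two-group comparisons report Welch t and significance stars", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_groups(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")
  set.seed(7)
  a <- rnorm(100, 10, 2); b <- rnorm(100, 12, 2)
  res <- compare_groups(a, b)
  expect_lt(res$p, 0.001)
  expect_equal(res$stars, "***")
  # censored dwells are excluded
  dwa <- data.frame(dwell_s = c(a, 1000), censored = c(rep(FALSE, 100), TRUE))
  res2 <- compare_groups(dwa, b)
  expect_equal(res2$n_a, 100L)
  # pooled-variance variant is available
  res3 <- compare_groups(a, b, var_equal = TRUE)
  expect_equal(unname(res3$df), 198)
})
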