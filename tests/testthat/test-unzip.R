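p <- elasticity_params()

test_that("polymer elasticity obeys limits and monotonicity", {
  # high-force limit without the stretch term: the contour length
  p0 <- elasticity_params(ss_stretch = Inf, ds_stretch = Inf)
  expect_equal(ssdna_extension(1e6, 100, p0), 100 * p0$ss_contour_nt,
               tolerance = 1e-4)
  expect_equal(dsdna_extension(1e6, 100, p0), 100 * p0$ds_contour_bp,
               tolerance = 1e-2)
  # doubling the length doubles the extension at fixed force
  expect_equal(ssdna_extension(10, 200, p), 2 * ssdna_extension(10, 100, p))
  expect_equal(dsdna_extension(10, 200, p), 2 * dsdna_extension(10, 100, p))
  # monotone increasing in force
  f <- seq(0.5, 60, by = 0.5)
  expect_true(all(diff(ssdna_extension(f, 100, p)) > 0))
  expect_true(all(diff(dsdna_extension(f, 100, p)) > 0))
  expect_error(ssdna_extension(-1, 10, p), "force")
})

test_that("extension inverts to force to near machine precision", {
  f <- c(0.5, 2, 8, 15, 40)
  x <- dsdna_extension(f, 1000, p) + ssdna_extension(f, 240, p)
  f_back <- tether_force(x, 1000, 240, p)
  expect_lt(max(abs(f_back / f - 1)), 1e-9)
})

test_that("extension_to_bp honours the 1 bp -> 2 nt accounting exactly", {
  f <- 14
  handles <- 1000
  for (b in c(0, 1, 37, 200)) {
    ext <- dsdna_extension(f, handles, p) + 2 * b * ssdna_extension(f, 1, p)
    bp <- extension_to_bp(f, ext, handles, p)
    expect_equal(as.numeric(bp), b, tolerance = 1e-9)
  }
  # one more base pair adds exactly two nucleotides of ssDNA contour
  e1 <- dsdna_extension(f, handles, p) + 2 * 50 * ssdna_extension(f, 1, p)
  e2 <- dsdna_extension(f, handles, p) + 2 * 51 * ssdna_extension(f, 1, p)
  expect_equal(e2 - e1, 2 * ssdna_extension(f, 1, p), tolerance = 1e-12)
  # extension below the handle-only prediction clamps to zero with a flag
  low <- extension_to_bp(f, dsdna_extension(f, handles, p) - 5, handles, p)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "clamped"))
})

test_that("a known bp ramp is recovered from a noiseless record", {
  sq <- random_sequence(200)
  cu <- simulate_unzip_curve(sq, p, noise_force = 0, noise_ext = 0, seed = 1)
  bp <- extension_to_bp(cu$force_pN, cu$extension_nm, attr(cu, "handles_bp"), p)
  expect_lt(max(abs(bp - cu$bp_true)), 1)
})

test_that("theoretical unzipping curves reflect the sequence energetics", {
  # uniform sequence: flat force plateau
  flat <- theoretical_unzip_curve(strrep("A", 120), params = p)
  expect_equal(stats::sd(flat$force_pN), 0)
  # AT block unzips at lower force than GC block
  mix <- theoretical_unzip_curve(paste0(strrep("AT", 50), strrep("GC", 50)),
                                 params = p)
  expect_lt(mean(mix$force_pN[5:95]), mean(mix$force_pN[105:195]) - 3)
  # deterministic: bit-identical on repeat
  sq <- random_sequence(150)
  expect_identical(theoretical_unzip_curve(sq, params = p),
                   theoretical_unzip_curve(sq, params = p))
  expect_error(theoretical_unzip_curve("ACGX"), "A, C, G, T")
})

test_that("cross-correlation alignment recovers known offsets", {
  th <- theoretical_unzip_curve(random_sequence(300), params = p)
  # self-alignment: zero offset
  self <- align_crosscorrelation(th[, c("bp", "force_pN")], th,
                                 c(30, 90), c(150, 250))
  expect_equal(self$offset_int, 0L)
  expect_lt(abs(self$offset_bp), 0.1)
  # a +7 bp shifted copy is recovered as -7
  sh <- data.frame(bp = th$bp + 7, force_pN = th$force_pN)
  al <- align_crosscorrelation(sh, th, c(30, 90), c(150, 250))
  expect_equal(al$offset_int, -7L)
  expect_lt(abs(al$offset_bp + 7), 0.1)
  expect_equal(al$aligned$bp, th$bp + 7 + al$offset_bp)
})

test_that("alignment tolerates fixture noise within one base pair", {
  th <- theoretical_unzip_curve(random_sequence(300), params = p)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    sh <- data.frame(bp = th$bp + 7,
                     force_pN = th$force_pN + rnorm(nrow(th), 0, 0.3))
    al <- align_crosscorrelation(sh, th, c(30, 90), c(150, 250))
    abs(al$offset_bp + 7) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("roadblocks and tether breakage are detected where simulated", {
  sq <- random_sequence(300)
  th <- theoretical_unzip_curve(sq, params = p)
  # baseline-only curve: no events
  naked <- simulate_unzip_curve(sq, p, noise_force = 0.2, seed = 2)
  bp <- extension_to_bp(naked$force_pN, naked$extension_nm,
                        attr(naked, "handles_bp"), p)
  d0 <- detect_block(data.frame(bp = bp, force_pN = naked$force_pN), th)
  expect_equal(nrow(d0$blocks), 0L)
  expect_true(is.na(d0$breakage_bp))
  # simulated block at bp 120: localised within +/- 3 bp, then breakage
  blocked <- simulate_unzip_curve(
    sq, p, block = list(bp = 120, barrier_kcal = 2.5, footprint = 10,
                        break_tether = TRUE), seed = 3)
  bp2 <- extension_to_bp(blocked$force_pN, blocked$extension_nm,
                         attr(blocked, "handles_bp"), p)
  d1 <- detect_block(data.frame(bp = bp2, force_pN = blocked$force_pN), th)
  expect_equal(nrow(d1$blocks), 1L)
  expect_lt(abs(d1$blocks$bp_start - 120), 3)
  expect_false(is.na(d1$breakage_bp))
  expect_lt(abs(d1$breakage_bp - 125), 6)
  # breakage without a block
  onlybreak <- data.frame(bp = c(1:50, rep(50, 10)),
                          force_pN = c(th$force_pN[1:50], rep(0.1, 10)))
  d2 <- detect_block(onlybreak, th)
  expect_equal(nrow(d2$blocks), 0L)
  expect_false(is.na(d2$breakage_bp))
})

test_that("reverse unzipping reports the block on the flipped axis", {
  sq <- random_sequence(300)
  rev_cu <- simulate_unzip_curve(sq, p, block = list(bp = 120),
                                 seed = 4, direction = "reverse")
  blk <- attr(rev_cu, "block")
  expect_equal(blk$bp, 300 - 120 + 1)
})
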