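#' Photophysics model of the two-colour TIRF measurement
#'
#' Parameters of the forward model turning a hidden mechanistic state path
#' into donor/acceptor intensity traces: frame interval 0.1 s and 1500
#' frames per trace (100 ms exposure), constant total emission until
#' photobleaching, additive channel backgrounds and Gaussian read noise,
#' donor-to-acceptor leakage, and single-step bleach events with a constant
#' per-frame hazard per dye.  The slow E fluctuation of the S2 state
#' (continuous protospacer trimming) is modelled as an intra-state
#' Ornstein-Uhlenbeck wander of the state mean, not as extra discrete
#' states.
#'
#' @param frame_s frame interval (s), default 0.1.
#' @param n_frames frames per trace, default 1500.
#' @param total_intensity total donor-excited emission (a.u.).
#' @param bkg_D,bkg_A channel backgrounds (a.u. per frame).
#' @param leakage donor-into-acceptor leakage fraction, in \[0, 0.2\].
#' @param noise_sd Gaussian read noise per channel (a.u.).
#' @param bleach_hazard_D,bleach_hazard_A per-frame bleach probability per
#'   dye.
#' @param ou_tau relaxation time (s) of the S2 mean-E wander.
#' @param ou_sd stationary s.d. (E units) of the S2 wander.
#' @return named list of class `"photophysics"`.
#' @export
photophysics <- function(frame_s = 0.1, n_frames = 1500L,
                         total_intensity = 1000, bkg_D = 100, bkg_A = 100,
                         leakage = 0.07, noise_sd = 8,
                         bleach_hazard_D = 5e-5, bleach_hazard_A = 5e-5,
                         ou_tau = 2, ou_sd = 0.08) {
  if (leakage < 0 || leakage > 0.2) stop("leakage must lie in [0, 0.2]")
  stopifnot(frame_s > 0, n_frames >= 1, total_intensity > 0, noise_sd >= 0)
  structure(list(frame_s = frame_s, n_frames = as.integer(n_frames),
                 total_intensity = total_intensity, bkg_D = bkg_D,
                 bkg_A = bkg_A, leakage = leakage, noise_sd = noise_sd,
                 bleach_hazard_D = bleach_hazard_D,
                 bleach_hazard_A = bleach_hazard_A,
                 ou_tau = ou_tau, ou_sd = ou_sd),
            class = "photophysics")
}

# occupancy-weighted state attribute per frame for a piecewise-constant path
frame_average <- function(segments, values, frame_s, n_frames) {
  out <- numeric(n_frames)
  edges <- seq(0, n_frames * frame_s, by = frame_s)
  for (i in seq_len(nrow(segments))) {
    a <- segments$t_start[i]; b <- segments$t_end[i]
    f0 <- max(1L, floor(a / frame_s) + 1L)
    f1 <- min(n_frames, ceiling(b / frame_s))
    if (f0 > f1) next
    fr <- f0:f1
    ov <- pmin(edges[fr + 1L], b) - pmax(edges[fr], a)
    out[fr] <- out[fr] + ov * values[i]
  }
  out / frame_s
}

#' Render a hidden state path into a raw two-colour intensity trace
#'
#' Forward model of the measurement: per frame, the FRET efficiency is the
#' occupancy-weighted mean E of the states visited within that frame (with
#' the S2 intra-state wander superimposed and the state's emission noise
#' added), and the channel intensities are
#' `I_A = T*E + bkg_A + leakage * T*(1 - E) + noise`,
#' `I_D = T*(1 - E) + bkg_D + noise`, with total emission `T` constant
#' until a single-step bleach event.  Acceptor-dark states (RELEASED) and
#' acceptor bleaching return the full emission to the donor channel; donor
#' bleaching extinguishes both signals.
#'
#' @param path dwell segments for one path, as returned by
#'   [path_segments()]; must cover the trace window.
#' @param states the state table of the generating scheme
#'   (e.g. `fret_scheme()$states`).
#' @param phys a [photophysics()] model.
#' @param seed RNG seed.
#' @param id trace identifier.
#' @return object of class `"trace_raw"`: data frame `frame`, `time_s`,
#'   `I_D`, `I_A`, with attributes `truth` (hidden E and state per frame,
#'   bleach frames, the path) and `photophysics`.
#' @export
render_trace <- function(path, states, phys = photophysics(), seed = NULL,
                         id = "trace1") {
  if (!is.null(seed)) set.seed(seed)
  nF <- phys$n_frames
  if (max(path$t_end) < nF * phys$frame_s - 1e-9)
    stop("path does not cover the trace window")
  sidx <- match(path$state, states$label)
  if (anyNA(sidx)) stop("path contains states unknown to the state table")

  mean_e <- states$mean_E[sidx]
  # intra-S2 Ornstein-Uhlenbeck wander of the state mean, sampled per frame
  segs <- path
  e_frame <- frame_average(segs, mean_e, phys$frame_s, nF)
  sd_frame <- frame_average(segs, states$sd_E[sidx], phys$frame_s, nF)
  wander_frac <- frame_average(segs, as.numeric(states$wander[sidx]),
                               phys$frame_s, nF)
  dark_frac <- frame_average(segs, as.numeric(states$acceptor_dark[sidx]),
                             phys$frame_s, nF)
  if (any(wander_frac > 0) && phys$ou_sd > 0) {
    a <- exp(-phys$frame_s / phys$ou_tau)
    w <- numeric(nF)
    innov <- stats::rnorm(nF, 0, phys$ou_sd * sqrt(1 - a^2))
    w[1] <- stats::rnorm(1, 0, phys$ou_sd)
    for (t in 2:nF) w[t] <- a * w[t - 1] + innov[t]
    e_frame <- e_frame + w * wander_frac
  }
  # emission noise is left unclipped here: channel intensities may dip below
  # the ideal signal; clipping to [0, 1] is the analysis side's job
  e_inst <- e_frame + stats::rnorm(nF, 0, sd_frame)
  e_inst <- e_inst * (1 - dark_frac)   # acceptor-dark emits at E = 0

  # single-step photobleaching
  bleach_D <- if (phys$bleach_hazard_D > 0)
    which(stats::runif(nF) < phys$bleach_hazard_D)[1] else NA_integer_
  bleach_A <- if (phys$bleach_hazard_A > 0)
    which(stats::runif(nF) < phys$bleach_hazard_A)[1] else NA_integer_

  T0 <- phys$total_intensity
  donor_on <- if (is.na(bleach_D)) rep(TRUE, nF) else seq_len(nF) < bleach_D
  acceptor_on <- if (is.na(bleach_A)) rep(TRUE, nF) else seq_len(nF) < bleach_A

  e_eff <- ifelse(acceptor_on, e_inst, 0)
  sig_A <- ifelse(donor_on, T0 * e_eff, 0)
  sig_D <- ifelse(donor_on, T0 * (1 - e_eff), 0)
  I_A <- sig_A + phys$bkg_A + phys$leakage * sig_D +
    stats::rnorm(nF, 0, phys$noise_sd)
  I_D <- sig_D + phys$bkg_D + stats::rnorm(nF, 0, phys$noise_sd)

  state_frame <- states$label[sidx][
    findInterval(((seq_len(nF)) - 0.5) * phys$frame_s,
                 c(segs$t_start[1], segs$t_end))]
  out <- data.frame(frame = seq_len(nF),
                    time_s = (seq_len(nF) - 1) * phys$frame_s,
                    I_D = I_D, I_A = I_A)
  attr(out, "id") <- id
  attr(out, "truth") <- list(E = e_frame * (1 - dark_frac),
                             E_inst = e_eff,
                             state = state_frame,
                             bleach_D = bleach_D, bleach_A = bleach_A,
                             path = path)
  attr(out, "photophysics") <- phys
  class(out) <- c("trace_raw", "data.frame")
  out
}

#' Simulate a seeded ensemble of smFRET traces
#'
#' Draws `n` hidden state paths from a mechanistic scheme and renders each
#' into a raw trace.  Per-trace seeds are derived from `seed` so the
#' ensemble is reproducible and individual traces are independent.
#'
#' @param scheme a [fret_scheme()].
#' @param n number of traces.
#' @param phys a [photophysics()] model.
#' @param seed ensemble seed.
#' @return list of `"trace_raw"` objects.
#' @export
simulate_fret_experiment <- function(scheme, n = 60, phys = photophysics(),
                                     seed = 1) {
  duration <- phys$n_frames * phys$frame_s
  paths <- simulate_state_path(scheme, duration_s = duration, seed = seed,
                               n = n)
  lapply(seq_len(n), function(i)
    render_trace(path_segments(paths, i), scheme$states, phys,
                 seed = seed + 7919L * i, id = sprintf("trace%03d", i)))
}

#' Simulate a noisy gel band-fraction timecourse
#'
#' Wraps [propagate()] and [project_bands()] and adds i.i.d. Gaussian band
#' noise (clipped to \[0, 1\]); the t = 0 row is left noise-free so the
#' intact fraction starts at exactly 1.
#'
#' @param scheme a [cleavage_scheme()].
#' @param map a [substrate_map()].
#' @param times time points (s).
#' @param noise_sd Gaussian noise s.d. on each band fraction.
#' @param seed RNG seed.
#' @return a [band_timecourse()].
#' @export
simulate_band_timecourse <- function(scheme, map, times, noise_sd = 0.02,
                                     seed = 1) {
  bt <- project_bands(propagate(scheme, times), map, scheme)
  if (noise_sd > 0) {
    set.seed(seed)
    noisy <- bt$fractions +
      matrix(stats::rnorm(length(bt$fractions), 0, noise_sd),
             nrow(bt$fractions))
    intact <- bt$intact + stats::rnorm(length(bt$intact), 0, noise_sd)
    keep0 <- which(times == 0)
    if (length(keep0)) {
      noisy[keep0, ] <- bt$fractions[keep0, ]
      intact[keep0] <- bt$intact[keep0]
    }
    bt$fractions <- pmin(pmax(noisy, 0), 1)
    bt$intact <- pmin(pmax(intact, 0), 1)
  }
  bt
}
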