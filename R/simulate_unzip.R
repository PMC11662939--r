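#' Simulate a quasi-static DNA unzipping record
#'
#' Generates a noisy force/extension/time record from the theoretical
#' quasi-static landscape of a sequence: the trap advances at constant
#' velocity, the fork opens base pairs at the equilibrium unzipping force,
#' and each opened base pair adds exactly two nucleotides of stretched
#' ssDNA to the tether.  An optional protein roadblock adds an energy
#' barrier over its footprint, raising the unzipping force above the
#' naked-DNA baseline at the binding position; the tether can optionally
#' break inside the block (force collapses to the zero-tether level).
#'
#' @param sequence duplex sequence (>= 50 bp) being unzipped, 5'->3' on the
#'   peeled strand.
#' @param params an [elasticity_params()].
#' @param block optional roadblock: list with `bp` (first blocked base
#'   pair), `barrier_kcal` (extra unzipping energy per bp over the
#'   footprint, default 2), `footprint` (bp, default 10) and
#'   `break_tether` (logical, default FALSE).
#' @param velocity_nm_s pulling velocity (nm/s), default 50.
#' @param handles_bp dsDNA handle length (bp), default 1000.
#' @param noise_force force noise s.d. (pN), default 0.2.
#' @param noise_ext extension noise s.d. (nm), default 1.
#' @param sample_hz sampling rate (Hz), default 20.
#' @param energies nearest-neighbour table (see [nn_energies()]).
#' @param seed RNG seed.
#' @param direction `"forward"` or `"reverse"`; reverse unzips the
#'   reverse complement (probing from the opposite duplex end) and reports
#'   bp on the reversed axis.
#' @return object of class `"unzip_curve"`: data frame `time_s`,
#'   `force_pN`, `extension_nm`, `bp_true`, with attributes `block`,
#'   `handles_bp`, `params`, `theory` (the naked-DNA
#'   [theoretical_unzip_curve()] on the same axis) and `breakage_index`.
#' @export
simulate_unzip_curve <- function(sequence, params = elasticity_params(),
                                 block = NULL, velocity_nm_s = 50,
                                 handles_bp = 1000, noise_force = 0.2,
                                 noise_ext = 1, sample_hz = 20,
                                 energies = nn_energies(), seed = 1,
                                 direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 50) stop("sequence must be at least 50 bp")
  if (direction == "reverse") {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    sequence <- paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
    if (!is.null(block)) block$bp <- n - block$bp + 1L
  }
  set.seed(seed)
  theory <- theoretical_unzip_curve(sequence, energies, params)
  g <- theory$energy_kT
  if (!is.null(block)) {
    block$barrier_kcal <- block$barrier_kcal %||% 2
    block$footprint <- block$footprint %||% 10L
    block$break_tether <- isTRUE(block$break_tether)
    rt_kcal <- 0.0019872 * params$temperature_K
    span <- block$bp:min(n, block$bp + block$footprint - 1L)
    g[span] <- g[span] + block$barrier_kcal / rt_kcal
  }
  kT <- kT_pN_nm(params)
  f_grid <- seq(0.01, 60, by = 0.01)
  x_nt <- ssdna_extension(f_grid, 1, params)
  w <- cumsum(c(0, diff(f_grid) * (x_nt[-1] + x_nt[-length(x_nt)]) / 2)) / kT
  force <- stats::approx(2 * w, f_grid, xout = g, rule = 2)$y

  break_at <- NA_integer_
  if (!is.null(block) && block$break_tether) {
    break_at <- min(n, block$bp + block$footprint %/% 2L)
    keep <- seq_len(break_at)
    force <- force[keep]
  }
  bp <- seq_along(force)
  ext <- dsdna_extension(force, handles_bp, params) +
    2 * bp * ssdna_extension(force, 1, params)
  # enforce a monotone trap trajectory for the time axis
  ext_mono <- cummax(ext)
  time_s <- (ext_mono - ext_mono[1]) / velocity_nm_s
  out <- data.frame(
    time_s = time_s,
    force_pN = force + stats::rnorm(length(force), 0, noise_force),
    extension_nm = ext + stats::rnorm(length(ext), 0, noise_ext),
    bp_true = bp)
  breakage_index <- NA_integer_
  if (!is.na(break_at)) {
    # a few post-breakage samples at the zero-tether level
    tail_n <- 10L
    post <- data.frame(
      time_s = time_s[length(time_s)] + seq_len(tail_n) / sample_hz,
      force_pN = abs(stats::rnorm(tail_n, 0, noise_force)),
      extension_nm = ext[length(ext)] +
        seq_len(tail_n) * velocity_nm_s / sample_hz,
      bp_true = NA_integer_)
    breakage_index <- nrow(out) + 1L
    out <- rbind(out, post)
  }
  attr(out, "block") <- block
  attr(out, "handles_bp") <- handles_bp
  attr(out, "params") <- params
  attr(out, "theory") <- theory
  attr(out, "breakage_index") <- breakage_index
  attr(out, "direction") <- direction
  class(out) <- c("unzip_curve", "data.frame")
  out
}

#' @export
print.unzip_curve <- function(x, ...) {
  cat(sprintf("<unzip_curve> %d points, F in [%.1f, %.1f] pN%s\n",
              nrow(x), min(x$force_pN), max(x$force_pN),
              if (!is.na(attr(x, "breakage_index"))) ", tether breakage"
              else ""))
  invisible(x)
}
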