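#' Polymer elasticity parameters for the unzipping construct
#'
#' Documented fixture defaults for the tether mechanics: unzipped ssDNA is
#' modelled as an extensible freely jointed chain and the dsDNA handles as
#' an extensible worm-like chain.  The exact experimental values are
#' condition-dependent; these defaults are typical of unzipping assays in
#' 100 mM monovalent salt and are fully configurable.
#'
#' @param ss_contour_nt ssDNA contour length per nt (nm), default 0.59.
#' @param ss_kuhn ssDNA Kuhn length (nm), default 1.5.
#' @param ss_stretch ssDNA stretch modulus (pN), default 800.
#' @param ds_persistence dsDNA persistence length (nm), default 45.
#' @param ds_contour_bp dsDNA contour length per bp (nm), default 0.338.
#' @param ds_stretch dsDNA stretch modulus (pN), default 1200.
#' @param temperature_K temperature (K), default 298.
#' @return named list of class `"elasticity_params"`.
#' @export
elasticity_params <- function(ss_contour_nt = 0.59, ss_kuhn = 1.5,
                              ss_stretch = 800, ds_persistence = 45,
                              ds_contour_bp = 0.338, ds_stretch = 1200,
                              temperature_K = 298) {
  p <- list(ss_contour_nt = ss_contour_nt, ss_kuhn = ss_kuhn,
            ss_stretch = ss_stretch, ds_persistence = ds_persistence,
            ds_contour_bp = ds_contour_bp, ds_stretch = ds_stretch,
            temperature_K = temperature_K)
  if (any(unlist(p) <= 0)) stop("all elastic parameters must be positive")
  structure(p, class = "elasticity_params")
}

kT_pN_nm <- function(params) 0.0138065 * params$temperature_K

#' Extension of single-stranded DNA (extensible freely jointed chain)
#'
#' `x(F) = n_nt * l_c * (coth(F b / kT) - kT / (F b)) * (1 + F / S)` with
#' Kuhn length `b`, contour per nt `l_c` and stretch modulus `S` (set
#' `ss_stretch = Inf` for the inextensible chain, whose high-force limit is
#' the contour length).
#'
#' @param force force (pN), > 0 (vectorised).
#' @param n_nt number of nucleotides.
#' @param params an [elasticity_params()].
#' @return extension (nm).
#' @export
ssdna_extension <- function(force, n_nt, params = elasticity_params()) {
  stopifnot(all(force > 0), n_nt >= 0)
  kT <- kT_pN_nm(params)
  y <- force * params$ss_kuhn / kT
  langevin <- 1 / tanh(y) - 1 / y
  stretch <- if (is.infinite(params$ss_stretch)) 1
             else 1 + force / params$ss_stretch
  n_nt * params$ss_contour_nt * langevin * stretch
}

#' Extension of double-stranded DNA handles (extensible worm-like chain)
#'
#' Inverts the Marko-Siggia interpolation with an enthalpic stretching
#' term: the relative extension `l` solves
#' `F = (kT / P) * (1 / (4 (1 - l)^2) - 1/4 + l)` and the extension is
#' `L * (l + F / S)`.
#'
#' @param force force (pN), > 0 (vectorised).
#' @param n_bp number of base pairs in the handles.
#' @param params an [elasticity_params()].
#' @return extension (nm).
#' @export
dsdna_extension <- function(force, n_bp, params = elasticity_params()) {
  stopifnot(all(force > 0), n_bp >= 0)
  if (n_bp == 0) return(rep(0, length(force)))
  kT <- kT_pN_nm(params)
  P <- params$ds_persistence
  L <- n_bp * params$ds_contour_bp
  ms <- function(l) (kT / P) * (1 / (4 * (1 - l)^2) - 0.25 + l)
  l <- vapply(force, function(f)
    stats::uniroot(function(l) ms(l) - f, c(0, 1 - 1e-9),
                   tol = 1e-12)$root, numeric(1))
  stretch <- if (is.infinite(params$ds_stretch)) 0
             else force / params$ds_stretch
  L * (l + stretch)
}

#' Force on a composite tether from its total extension
#'
#' Numerically inverts handles + ssDNA extension at a given architecture
#' (root finding); used by tests as the inverse-consistency oracle and by
#' the simulator.
#'
#' @param extension total extension (nm), vectorised.
#' @param handles_bp dsDNA handle length (bp).
#' @param ss_nt single-stranded nucleotides under tension.
#' @param params an [elasticity_params()].
#' @param interval force search interval (pN).
#' @return force (pN).
#' @export
tether_force <- function(extension, handles_bp, ss_nt,
                         params = elasticity_params(),
                         interval = c(1e-3, 200)) {
  total <- function(f) dsdna_extension(f, handles_bp, params) +
    ssdna_extension(f, ss_nt, params)
  vapply(extension, function(x)
    stats::uniroot(function(f) total(f) - x, interval, tol = 1e-10)$root,
    numeric(1))
}

#' Convert total extension to base pairs unzipped
#'
#' Per point, solves
#' `extension = handles(F) + 2 * bp * ss_nt_extension(F)`:
#' each separated base pair contributes exactly two nucleotides of ssDNA
#' (enforced by the factor 2).  Points whose extension falls below the
#' handle-only prediction are clamped to 0 bp and flagged.
#'
#' @param force force (pN) per point.
#' @param extension total extension (nm) per point.
#' @param handles_bp dsDNA handle length (bp).
#' @param params an [elasticity_params()].
#' @return numeric vector of base pairs unzipped, with attribute
#'   `"clamped"` (logical vector marking points below the handle-only
#'   prediction).
#' @export
extension_to_bp <- function(force, extension, handles_bp,
                            params = elasticity_params()) {
  stopifnot(length(force) == length(extension))
  hx <- dsdna_extension(force, handles_bp, params)
  per_nt <- ssdna_extension(force, 1, params)
  bp <- (extension - hx) / (2 * per_nt)
  clamped <- bp < 0
  bp[clamped] <- 0
  attr(bp, "clamped") <- clamped
  bp
}

#' Nearest-neighbour base-pairing free energies
#'
#' Unzipping free energy per dinucleotide step (kcal/mol, magnitudes of
#' the standard unified nearest-neighbour duplex set at 37 C), keyed by the
#' step read 5'->3' on the strand being peeled; complementary steps share a
#' value.  An additive per-bp offset accommodates ionic-strength
#' correction; both the table and the offset are fixture defaults, not
#' asserted experimental values.
#'
#' @param offset additive per-bp correction (kcal/mol), default 0.
#' @return named numeric vector over the 16 dinucleotide steps.
#' @export
nn_energies <- function(offset = 0) {
  g <- c(AA = 1.00, AT = 0.88, TA = 0.58, CA = 1.45, GT = 1.44,
         CT = 1.28, GA = 1.30, CG = 2.17, GC = 2.24, GG = 1.84)
  # fill complements: step XY on one strand equals step comp(Y)comp(X)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  full <- g
  for (k in names(g)) {
    s <- strsplit(k, "")[[1]]
    rc <- paste0(comp[s[2]], comp[s[1]])
    if (!rc %in% names(full)) full[rc] <- g[k]
  }
  full[sort(names(full))] + offset
}

# per-bp unzip free energy (kT) along a sequence
sequence_energy_kt <- function(sequence, energies, params) {
  s <- strsplit(toupper(sequence), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A, C, G, T")
  n <- length(s)
  if (n < 2) stop("sequence too short")
  steps <- paste0(s[-n], s[-1])
  g_kcal <- c(energies[steps], energies[steps[n - 1]])  # last bp reuses final step
  rt_kcal <- 0.0019872 * params$temperature_K
  unname(g_kcal) / rt_kcal
}

#' Theoretical quasi-static unzipping curve from sequence
#'
#' Computes the equilibrium unzipping force at each base pair: opening bp
#' `j` releases its nearest-neighbour pairing free energy `g_j` and
#' transfers two nucleotides into the stretched ssDNA, so at the slow
#' pulling speeds of the assay the force satisfies
#' `g_j = 2 * w_ss(F)`, where `w_ss(F)` is the stretching free energy per
#' nucleotide (the integral of the ssDNA extension over force).  AT-rich
#' regions therefore unzip at lower force than GC-rich ones.  An optional
#' moving average over `smooth_bp` base pairs mimics the averaging imposed
#' by ssDNA compliance.
#'
#' @param sequence character string of the duplex sequence (the strand
#'   being peeled, 5'->3'), length >= 50 recommended.
#' @param energies nearest-neighbour table from [nn_energies()].
#' @param params an [elasticity_params()].
#' @param smooth_bp odd moving-average window on the energy profile
#'   (default 3).  At slow pulling the fork hops thermally over a few base
#'   pairs, so the measurable force averages the per-bp energies; the
#'   window width emulates that averaging.  Use 1 for the raw profile.
#' @return data frame of class `"unzip_theory"`: `bp`, `force_pN`,
#'   `energy_kT`.
#' @export
theoretical_unzip_curve <- function(sequence, energies = nn_energies(),
                                    params = elasticity_params(),
                                    smooth_bp = 3L) {
  g <- sequence_energy_kt(sequence, energies, params)
  if (smooth_bp > 1L) g <- smooth_adjacent_average(g, smooth_bp)
  kT <- kT_pN_nm(params)
  f_grid <- seq(0.01, 60, by = 0.01)
  x_nt <- ssdna_extension(f_grid, 1, params)
  w <- cumsum(c(0, diff(f_grid) * (x_nt[-1] + x_nt[-length(x_nt)]) / 2)) / kT
  force <- stats::approx(2 * w, f_grid, xout = g, rule = 2)$y
  out <- data.frame(bp = seq_along(g), force_pN = force, energy_kT = g)
  class(out) <- c("unzip_theory", "data.frame")
  out
}

#' Align a measured unzipping curve to its theoretical counterpart
#'
#' Finds the integer base-pair offset maximising the normalised
#' cross-correlation between the measured and theoretical force-versus-bp
#' curves over two user-specified regions (taken before and after the
#' protein-complex disruption so the block itself does not bias the
#' alignment), then refines to sub-bp precision by parabolic interpolation
#' of the correlation peak.
#'
#' @param measured data frame with `bp` and `force_pN`.
#' @param theoretical a [theoretical_unzip_curve()] (or compatible frame).
#' @param region_before,region_after length-2 bp intervals (theoretical
#'   axis) used jointly for the correlation.
#' @param max_shift search half-width (bp), default 30.
#' @return list with `offset_bp` (add to the measured bp axis to align),
#'   `offset_int`, `ncc` (correlation at the optimum) and `aligned`
#'   (measured frame with corrected bp).
#' @export
align_crosscorrelation <- function(measured, theoretical, region_before,
                                   region_after, max_shift = 30L) {
  grid <- c(seq(region_before[1], region_before[2]),
            seq(region_after[1], region_after[2]))
  grid <- grid[grid %in% theoretical$bp]
  if (length(grid) < 4) stop("alignment regions too small")
  th <- theoretical$force_pN[match(grid, theoretical$bp)]
  shifts <- seq(-max_shift, max_shift)
  ncc <- vapply(shifts, function(d) {
    me <- stats::approx(measured$bp, measured$force_pN, xout = grid - d,
                        rule = 1)$y
    ok <- !is.na(me)
    if (sum(ok) < 4 || stats::sd(me[ok]) == 0 || stats::sd(th[ok]) == 0)
      return(-Inf)
    stats::cor(me[ok], th[ok])
  }, numeric(1))
  i <- which.max(ncc)
  off <- shifts[i]
  # parabolic sub-bp refinement on the correlation peak
  refined <- off
  if (i > 1 && i < length(shifts) && all(is.finite(ncc[(i - 1):(i + 1)]))) {
    y1 <- ncc[i - 1]; y2 <- ncc[i]; y3 <- ncc[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) refined <- off + 0.5 * (y1 - y3) / denom
  }
  aligned <- measured
  aligned$bp <- measured$bp + refined
  list(offset_bp = refined, offset_int = off, ncc = ncc[i],
       aligned = aligned)
}

#' Detect protein roadblocks and tether breakage in an unzipping record
#'
#' A block is a contiguous span of at least `min_span` base pairs where
#' the measured force exceeds the naked-DNA baseline by more than
#' `force_threshold`; tether breakage is a collapse of the force to the
#' zero-tether level after the tether has been under load.  Reverse
#' unzipping records (bp axis decreasing) are handled by the direction
#' flag.
#'
#' @param measured data frame with `bp` and `force_pN`.
#' @param baseline naked-DNA reference (data frame `bp`, `force_pN`),
#'   e.g. a [theoretical_unzip_curve()].
#' @param force_threshold excess force defining a block (pN), default 2.
#' @param min_span minimum block span (bp), default 5.
#' @param direction `"forward"` (bp increasing) or `"reverse"`.
#' @param breakage_force force level marking a broken tether (pN),
#'   default 1.
#' @param median_k odd running-median window applied to the excess force
#'   before thresholding (default 5); suppresses isolated spikes from
#'   measurement noise on the steep per-bp landscape without displacing
#'   block edges.
#' @return list with `blocks` (data frame `bp_start`, `bp_end`, `bp_peak`,
#'   `peak_excess_pN`; zero rows if none) and `breakage_bp` (NA if none).
#' @export
detect_block <- function(measured, baseline, force_threshold = 2,
                         min_span = 5, direction = c("forward", "reverse"),
                         breakage_force = 1, median_k = 5) {
  direction <- match.arg(direction)
  m <- measured
  # breakage is chronological: force collapse after the tether was loaded,
  # reported at the last loaded position (converted bp is meaningless once
  # the tether is gone)
  loaded <- measured$force_pN > breakage_force + force_threshold
  broken <- which(measured$force_pN < breakage_force & cumsum(loaded) > 0)
  breakage_bp <- NA_real_
  if (length(broken)) {
    prior <- which(loaded & seq_along(loaded) < broken[1])
    breakage_bp <- if (length(prior))
      measured$bp[prior[length(prior)]] else measured$bp[broken[1]]
  }
  if (direction == "reverse") m <- m[order(m$bp), ]
  base_f <- stats::approx(baseline$bp, baseline$force_pN, xout = m$bp,
                          rule = 2)$y
  excess <- m$force_pN - base_f
  if (median_k > 1 && nrow(m) > median_k)
    excess <- stats::runmed(excess, median_k, endrule = "median")
  # unloaded (broken) points cannot belong to a block
  over <- excess > force_threshold & m$force_pN >= breakage_force
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- data.frame(bp_start = numeric(0), bp_end = numeric(0),
                       bp_peak = numeric(0), peak_excess_pN = numeric(0))
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    span <- abs(m$bp[i1] - m$bp[i0])
    # a block needs both the bp span and enough consecutive supporting
    # points; short point runs are conversion-noise excursions
    if (span + 1 < min_span || r$lengths[k] < min_span) next
    seg <- i0:i1
    pk <- seg[which.max(excess[seg])]
    blocks <- rbind(blocks,
                    data.frame(bp_start = m$bp[i0], bp_end = m$bp[i1],
                               bp_peak = m$bp[pk],
                               peak_excess_pN = excess[pk]))
  }
  list(blocks = blocks, breakage_bp = breakage_bp)
}
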