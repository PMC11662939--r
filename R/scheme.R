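#' Hill-type magnesium scaling of catalytic rates
#'
#' Cleavage and unwinding-coupled steps are Mg2+ dependent; a Hill function
#' theta(Mg) = Mg^h / (K^h + Mg^h) multiplies the affected rate constants.
#' The functional form is a modelling choice (fitted, not asserted): h = 2
#' and K = 4 mM give a response that saturates near 10 mM and is strongly
#' attenuated at 1 mM, matching the qualitative dependence of cleavage on
#' Mg2+ concentration.
#'
#' @param mg_mM magnesium concentration in mM.
#' @param h Hill coefficient (default 2).
#' @param K half-saturation constant in mM (default 4).
#' @return scaling factor in \[0, 1).
#' @export
mg_hill <- function(mg_mM, h = 2, K = 4) {
  stopifnot(mg_mM >= 0, h > 0, K > 0)
  mg_mM^h / (K^h + mg_mM^h)
}

#' Rate specification for the sequential cleavage scheme
#'
#' First-order rate constants (s^-1) for each edge class of the sequential
#' cleavage graph: initial NTS nick at +16, the single-step 3'->5' proximal
#' trim (+16 -> +14), the 5'->3' distal exonucleolytic ladder
#' (+16 -> +18 -> +21 -> +23 -> +25, one shared rate by default or one rate
#' per step), the endonucleolytic TS cut at +23, and complex release.
#' Defaults are the package's documented fixture values at saturating Mg2+.
#'
#' @param k_nick intact -> nick at +16 (s^-1).
#' @param k_trim35 proximal +16 -> +14 trim, one 2-nt step (s^-1).
#' @param k_trim53 distal trimming rate; scalar (shared by the four steps)
#'   or length-4 vector of per-step rates (s^-1).
#' @param k_ts TS cut at +23 (s^-1); only allowed once the distal NTS front
#'   has reached +21 (out-of-protospacer processing underway).
#' @param k_release release of the PAM-distal duplex after the TS cut
#'   (s^-1); `Inf` (default) makes release instantaneous.
#' @return named list of class `"cleavage_rates"`.
#' @export
cleavage_rates <- function(k_nick = 0.10, k_trim35 = 0.05,
                           k_trim53 = 0.10, k_ts = 0.02,
                           k_release = Inf) {
  if (!(length(k_trim53) %in% c(1L, 4L)))
    stop("k_trim53 must be a scalar or a length-4 per-step vector")
  r <- list(k_nick = k_nick, k_trim35 = k_trim35, k_trim53 = k_trim53,
            k_ts = k_ts, k_release = k_release)
  bad <- vapply(r, function(x) any(!is.na(x) & x < 0), logical(1))
  if (any(bad)) stop("negative rate constant: ", paste(names(r)[bad], collapse = ", "))
  structure(r, class = "cleavage_rates")
}

# ladder of distal 5'->3' trimming front positions
.distal_ladder <- c(16L, 18L, 21L, 23L, 25L)
.ts_position <- 23L
.prox_trimmed <- 14L

#' Build the sequential cleavage kinetic scheme
#'
#' Constructs the continuous-time Markov chain over lesion states for the
#' sequential cleavage pathway: intact duplex -> NTS nick at +16 -> parallel
#' 3'->5' trimming to +14 and 5'->3' trimming +16/+18/+21/+23/+25 -> TS cut
#' at +23 (permitted only when the distal front has reached +21, i.e. after
#' out-of-protospacer unwinding) -> release.  All cleavage edges (nick,
#' trimming, TS cut) are unwinding-coupled and scaled by [mg_hill()];
#' release is not.  When `lna_region` is supplied (or taken from `map`),
#' edges whose target cut is blocked per [lna_blocked()] are removed, which
#' truncates the distal ladder at +21 and deletes the TS cut.
#'
#' @param rates a [cleavage_rates()] specification.
#' @param mg_mM magnesium concentration (mM), default 10.
#' @param lna_region optional LNA interval (see [substrate_map()]).
#' @param hill optional list overriding the Hill parameters, e.g.
#'   `list(h = 2, K = 4)`.
#' @return an object of class `"cleavage_scheme"` with elements `states`
#'   (data frame: name, proximal, distal, ts_cut, ts_position, released),
#'   `Q` (generator matrix, `Q[i, j]` = rate i -> j, rows sum to zero),
#'   `rates`, `mg_mM` and `theta`.
#' @examples
#' sch <- cleavage_scheme()
#' sch$states$name
#' @export
cleavage_scheme <- function(rates = cleavage_rates(), mg_mM = 10,
                            lna_region = NULL, hill = list(h = 2, K = 4)) {
  stopifnot(inherits(rates, "cleavage_rates"))
  if (any(!vapply(rates, is.numeric, logical(1))))
    stop("rates must be numeric")
  theta <- mg_hill(mg_mM, hill$h, hill$K)
  blocked <- function(p) !is.null(lna_region) && p > lna_region[1]

  ladder <- .distal_ladder[!vapply(.distal_ladder, blocked, logical(1))]
  ts_allowed <- !blocked(.ts_position) && rates$k_ts > 0
  instant_release <- is.infinite(rates$k_release)

  prox_levels <- c(16L, .prox_trimmed)
  states <- data.frame(proximal = NA_integer_, distal = NA_integer_,
                       ts_cut = FALSE, ts_position = NA_integer_,
                       released = FALSE)
  for (pr in prox_levels) for (d in ladder)
    states <- rbind(states, data.frame(proximal = pr, distal = d,
                                       ts_cut = FALSE,
                                       ts_position = NA_integer_,
                                       released = FALSE))
  if (ts_allowed) {
    for (pr in prox_levels) for (d in ladder[ladder >= 21L]) {
      if (!instant_release)
        states <- rbind(states, data.frame(proximal = pr, distal = d,
                                           ts_cut = TRUE,
                                           ts_position = .ts_position,
                                           released = FALSE))
      states <- rbind(states, data.frame(proximal = pr, distal = d,
                                         ts_cut = TRUE,
                                         ts_position = .ts_position,
                                         released = TRUE))
    }
  }
  states$name <- state_name(states)
  rownames(states) <- states$name
  n <- nrow(states)
  Q <- matrix(0, n, n, dimnames = list(states$name, states$name))
  idx <- function(pr, d, ts, rel) {
    j <- which((is.na(pr) & is.na(states$proximal) |
                  (!is.na(pr) & !is.na(states$proximal) & states$proximal == pr)) &
                 (is.na(d) & is.na(states$distal) |
                    (!is.na(d) & !is.na(states$distal) & states$distal == d)) &
                 states$ts_cut == ts & states$released == rel)
    if (length(j) != 1L) stop("internal: state lookup failed")
    j
  }
  k53 <- if (length(rates$k_trim53) == 1L)
    rep(rates$k_trim53, 4L) else rates$k_trim53

  add <- function(i, j, k) if (k > 0) Q[i, j] <<- Q[i, j] + k
  # nick: intact -> (16, 16)
  add(idx(NA, NA, FALSE, FALSE), idx(16L, 16L, FALSE, FALSE),
      rates$k_nick * theta)
  for (pr in prox_levels) for (d in ladder) {
    i <- idx(pr, d, FALSE, FALSE)
    if (pr == 16L)
      add(i, idx(.prox_trimmed, d, FALSE, FALSE), rates$k_trim35 * theta)
    step <- match(d, .distal_ladder)
    if (step < length(.distal_ladder) &&
        .distal_ladder[step + 1L] %in% ladder)
      add(i, idx(pr, .distal_ladder[step + 1L], FALSE, FALSE),
          k53[step] * theta)
    if (ts_allowed && d >= 21L) {
      j <- if (instant_release) idx(pr, d, TRUE, TRUE) else idx(pr, d, TRUE, FALSE)
      add(i, j, rates$k_ts * theta)
    }
  }
  if (ts_allowed && !instant_release) {
    for (pr in prox_levels) for (d in ladder[ladder >= 21L])
      add(idx(pr, d, TRUE, FALSE), idx(pr, d, TRUE, TRUE), rates$k_release)
  }
  # keep only states reachable from the intact duplex under nonzero rates
  reach <- rep(FALSE, n)
  reach[1] <- TRUE
  repeat {
    new <- reach | colSums(Q[reach, , drop = FALSE] > 0) > 0
    if (identical(new, reach)) break
    reach <- new
  }
  states <- states[reach, , drop = FALSE]
  Q <- Q[reach, reach, drop = FALSE]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(states = states, Q = Q, rates = rates, mg_mM = mg_mM,
                 theta = theta, lna_region = lna_region),
            class = "cleavage_scheme")
}

state_name <- function(st) {
  ifelse(is.na(st$proximal), "intact",
         paste0("p", st$proximal, ".d", st$distal,
                ifelse(st$released, ".rel", ifelse(st$ts_cut, ".ts", ""))))
}

#' @export
print.cleavage_scheme <- function(x, ...) {
  cat(sprintf("<cleavage_scheme> %d lesion states, Mg = %g mM (theta = %.3f)\n",
              nrow(x$states), x$mg_mM, x$theta))
  if (!is.null(x$lna_region))
    cat(sprintf("  LNA-truncated at +%d\n", x$lna_region[1]))
  invisible(x)
}

#' Solve the master equation of a kinetic scheme
#'
#' Propagates the state occupancy distribution from a pure initial state
#' (the intact duplex by default) through the generator of the scheme,
#' p(t) = p(0) expm(Q t), using the matrix exponential.
#'
#' @param scheme a [cleavage_scheme()] (or any object with elements `Q` and
#'   `states`).
#' @param times non-negative, non-decreasing vector of times (s).
#' @param p0 optional initial occupancy vector (defaults to all mass on the
#'   first state).
#' @return matrix (time x state) of occupancies; rows sum to 1.  Attribute
#'   `"times"` carries the time grid.
#' @export
propagate <- function(scheme, times, p0 = NULL) {
  Q <- scheme$Q
  if (any(!is.finite(Q))) stop("non-finite rates in the scheme generator")
  if (any(times < 0) || is.unsorted(times)) stop("times must be non-negative and increasing")
  n <- nrow(Q)
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1L))
  occ <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, colnames(Q)))
  for (i in seq_along(times)) {
    P <- as.matrix(Matrix::expm(Q * times[i]))
    occ[i, ] <- as.numeric(p0 %*% P)
  }
  occ[occ < 0 & occ > -1e-12] <- 0
  attr(occ, "times") <- times
  occ
}

#' Band timecourse container
#'
#' @param times time points (s).
#' @param fragment_lengths labelled fragment lengths (nt), one per column of
#'   `fractions`.
#' @param fractions matrix (time x fragment) of band fractions in \[0, 1\].
#' @param intact vector of intact-substrate fractions (remainder).
#' @return object of class `"band_timecourse"`.
#' @export
band_timecourse <- function(times, fragment_lengths, fractions, intact) {
  fractions <- as.matrix(fractions)
  stopifnot(length(times) == nrow(fractions),
            length(fragment_lengths) == ncol(fractions),
            length(intact) == length(times))
  if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9))
    stop("band fractions must lie in [0, 1]")
  colnames(fractions) <- as.character(fragment_lengths)
  structure(list(times = times,
                 fragment_lengths = as.integer(fragment_lengths),
                 fractions = fractions, intact = intact),
            class = "band_timecourse")
}

#' @export
print.band_timecourse <- function(x, ...) {
  cat(sprintf("<band_timecourse> %d time points, bands: %s nt\n",
              length(x$times), paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Project state occupancies onto observable gel bands
#'
#' Sums the occupancy of all lesion states that yield the same labelled
#' fragment length for the given substrate map.  States in which the
#' labelled strand is still intact contribute to the intact fraction;
#' "total cleaved" is one minus intact.
#'
#' @param occupancy matrix from [propagate()].
#' @param map a [substrate_map()].
#' @param scheme the [cleavage_scheme()] that generated the occupancy.
#' @return a [band_timecourse()].
#' @export
project_bands <- function(occupancy, map, scheme) {
  st <- scheme$states
  frag <- rep(NA_integer_, nrow(st))   # NA = labelled strand intact
  for (i in seq_len(nrow(st))) {
    if (map$label$strand == "NTS") {
      p <- if (map$label$end == "5p") st$proximal[i] else st$distal[i]
      if (!is.na(p)) frag[i] <- fragment_length(map, cut_site("NTS", p))
    } else {
      if (st$ts_cut[i])
        frag[i] <- fragment_length(map, cut_site("TS", st$ts_position[i]))
    }
  }
  lens <- sort(unique(frag[!is.na(frag)]))
  fractions <- sapply(lens, function(L)
    rowSums(occupancy[, which(frag == L), drop = FALSE]))
  fractions <- matrix(fractions, nrow = nrow(occupancy))
  intact <- rowSums(occupancy[, which(is.na(frag)), drop = FALSE])
  band_timecourse(attr(occupancy, "times"), lens, fractions, intact)
}
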