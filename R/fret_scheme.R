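#' Mechanistic FRET states of the cleavage reaction
#'
#' The five mechanistic classes resolved in the single-molecule FRET assay,
#' plus the released (acceptor-dark) end state:
#' * `S1` - unbound DNA, baseline E near 0;
#' * `pS2` - premature, partially hybridised R-loop (E 0.2-0.4);
#' * `S2` - full R-loop with ongoing protospacer NTS trimming (E
#'   fluctuating 0.4-0.7; modelled as slow intra-state wander, see
#'   [photophysics()]);
#' * `S2prime` - stable R-loop without further cleavage (E around 0.6, low
#'   variance; reached with catalytically dead protein or LNA-blocked
#'   substrates);
#' * `S3` - out-of-protospacer unwinding/processing (E around 0.9);
#' * `RELEASED` - PAM-distal DNA released, acceptor lost (dark).
#'
#' @return data frame with columns `label`, `mean_E`, `sd_E`,
#'   `acceptor_dark`, `wander` (logical: slow intra-state mean wander).
#' @export
fret_states <- function() {
  data.frame(
    label = c("S1", "pS2", "S2", "S2prime", "S3", "RELEASED"),
    mean_E = c(0.00, 0.30, 0.55, 0.60, 0.90, 0.00),
    sd_E = c(0.04, 0.06, 0.04, 0.035, 0.05, 0.04),
    acceptor_dark = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    wander = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Rate specification for the mechanistic FRET scheme
#'
#' First-order rates (s^-1) at saturating Mg2+ for the state graph used by
#' the trace simulator.  Binding is pseudo-first-order with a configurable
#' apparent rate (the absolute binding rate is a free parameter of the
#' simulator); the pS2:S2 branch ratio at binding and the maturation,
#' processing and release edges follow the fixture Hill scaling, while
#' rewinding (S3 -> S2) is Mg-independent, so that low Mg favours both the
#' premature pS2 state and out-of-protospacer rewinding.
#'
#' @param k_bind apparent binding rate S1 -> (pS2 or S2).
#' @param k_mature pS2 -> S2 completion of the R-loop.
#' @param k_s23 S2 -> S3 entry into out-of-protospacer processing; this is
#'   the protospacer-processing bottleneck (1/k_s23 sets the mean t2).
#' @param k_rel S3 -> RELEASED (TS cut and PAM-distal release).
#' @param k_rewind S3 -> S2 duplex rewinding (not Mg-scaled).
#' @param k_stab S2 -> S2prime stabilisation (only used by the `lna` and
#'   `dead` scheme variants).
#' @return named list of class `"fret_rates"`.
#' @export
fret_rates <- function(k_bind = 0.05, k_mature = 0.2, k_s23 = 0.08,
                       k_rel = 0.5, k_rewind = 0.04, k_stab = 0.05) {
  r <- list(k_bind = k_bind, k_mature = k_mature, k_s23 = k_s23,
            k_rel = k_rel, k_rewind = k_rewind, k_stab = k_stab)
  if (any(unlist(r) < 0)) stop("negative rate constant")
  structure(r, class = "fret_rates")
}

#' Build the mechanistic FRET kinetic scheme
#'
#' Continuous-time Markov chain over the [fret_states()] used by the trace
#' simulator.  Three variants mirror the experimental conditions:
#' * `"wt"` - full pathway S1 -> (pS2 <-> ) S2 -> S3 -> RELEASED with an
#'   S3 -> S2 rewinding edge;
#' * `"lna"` - out-of-protospacer unwinding blocked: no S3 and no release;
#'   the fluctuating S2 stabilises into S2prime;
#' * `"dead"` - catalytically dead protein: binding leads directly to the
#'   stable S2prime R-loop (via pS2 at low Mg).
#'
#' The protein argument applies the engineered-variant kinetics: the v5.1
#' variant accelerates only the protospacer-processing step (S2 -> S3),
#' leaving binding and out-of-protospacer processing unchanged.
#'
#' @param variant scheme variant, one of `"wt"`, `"lna"`, `"dead"`.
#' @param mg_mM magnesium concentration (mM).
#' @param rates a [fret_rates()] specification.
#' @param protein `"WT"` or `"v5.1"`.
#' @param s2_accel fold-acceleration of k_s23 for the v5.1 protein
#'   (default 3).
#' @param hill Hill parameters for [mg_hill()].
#' @return object of class `"fret_scheme"` with `states` (see
#'   [fret_states()]), generator `Q`, `mg_mM`, `theta`, `variant`,
#'   `protein`, `rates`.
#' @examples
#' fret_scheme()                      # optimal condition, wild type
#' fret_scheme(mg_mM = 1)             # low-Mg condition
#' fret_scheme(protein = "v5.1")      # accelerated protospacer processing
#' @export
fret_scheme <- function(variant = c("wt", "lna", "dead"), mg_mM = 10,
                        rates = fret_rates(), protein = c("WT", "v5.1"),
                        s2_accel = 3, hill = list(h = 2, K = 4)) {
  variant <- match.arg(variant)
  protein <- match.arg(protein)
  stopifnot(inherits(rates, "fret_rates"))
  theta <- mg_hill(mg_mM, hill$h, hill$K)
  st <- fret_states()
  rownames(st) <- st$label
  n <- nrow(st)
  Q <- matrix(0, n, n, dimnames = list(st$label, st$label))
  i <- function(lab) match(lab, st$label)
  f_ps2 <- 1 - theta   # premature-branch fraction at binding
  k_s23 <- rates$k_s23 * if (protein == "v5.1") s2_accel else 1

  Q[i("S1"), i("pS2")] <- rates$k_bind * f_ps2
  Q[i("pS2"), i("S2")] <- rates$k_mature * theta
  if (variant == "dead") {
    Q[i("S1"), i("S2prime")] <- rates$k_bind * (1 - f_ps2)
    Q[i("pS2"), i("S2")] <- 0
    Q[i("pS2"), i("S2prime")] <- rates$k_mature * theta
  } else {
    Q[i("S1"), i("S2")] <- rates$k_bind * (1 - f_ps2)
  }
  if (variant == "wt") {
    Q[i("S2"), i("S3")] <- k_s23 * theta
    Q[i("S3"), i("S2")] <- rates$k_rewind
    Q[i("S3"), i("RELEASED")] <- rates$k_rel * theta
  } else if (variant == "lna") {
    Q[i("S2"), i("S2prime")] <- rates$k_stab
  }
  diag(Q) <- -rowSums(Q)
  structure(list(states = st, Q = Q, mg_mM = mg_mM, theta = theta,
                 variant = variant, protein = protein, rates = rates),
            class = "fret_scheme")
}

#' @export
print.fret_scheme <- function(x, ...) {
  cat(sprintf("<fret_scheme> variant %s, protein %s, Mg = %g mM (theta = %.3f)\n",
              x$variant, x$protein, x$mg_mM, x$theta))
  invisible(x)
}
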