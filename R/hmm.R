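#' Fit a shared Gaussian-emission hidden Markov model to E series
#'
#' Baum-Welch EM with a single (global) model across all traces of a
#' condition: pooling traces stabilises the estimates for short dwells and
#' matches the pooled transition-density analysis downstream.  Emissions
#' are Gaussian per state; missing frames contribute a flat emission
#' likelihood.  EM is restarted from several jittered initialisations and
#' the best log-likelihood is kept; states are returned in canonical order
#' (means ascending) so that well-separated fits are seed-stable.
#'
#' @param traces list of [fret_trace()] objects or numeric E vectors.
#' @param K number of states (>= 1).
#' @param init optional list with starting `mu`, `sigma`, `A`, `pi`
#'   (overrides the built-in initialisation; restarts then jitter it).
#' @param seed seed for the restarts.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap per restart (default 500).
#' @param n_restarts number of jittered restarts (default 10).
#' @param sigma_floor variance floor on the emission s.d. (E units,
#'   default 0.01); floored states are flagged.
#' @return object of class `"hmm_model"`: list with `K`, `mu`, `sigma`,
#'   `A`, `pi`, `loglik`, `ll_trace` (per-iteration log-likelihoods of the
#'   winning restart), `converged`, `sigma_floored`, `n_frames`.
#' @export
fit_hmm <- function(traces, K, init = NULL, seed = 1, tol = 1e-6,
                    max_iter = 500L, n_restarts = 10L, sigma_floor = 0.01) {
  stopifnot(K >= 1, length(traces) >= 1)
  xs <- lapply(traces, trace_obs)
  xs <- xs[vapply(xs, function(x) sum(!is.na(x)) > 0, logical(1))]
  if (!length(xs)) stop("no observed frames in any trace")
  pooled <- unlist(xs)
  pooled <- pooled[!is.na(pooled)]

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    par <- if (is.null(init)) hmm_init(pooled, K, jitter = (r > 1))
           else hmm_jitter(init, r > 1)
    fit <- hmm_em(xs, par, tol, max_iter, sigma_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  model <- structure(
    list(K = K, mu = best$mu[ord], sigma = best$sigma[ord],
         A = best$A[ord, ord, drop = FALSE], pi = best$pi[ord],
         loglik = best$loglik, ll_trace = best$ll_trace,
         converged = best$converged, sigma_floored = best$sigma_floored,
         n_frames = length(pooled)),
    class = "hmm_model")
  if (model$sigma_floored)
    warning("degenerate emission: sigma floored at ", sigma_floor,
            call. = FALSE)
  model
}

trace_obs <- function(tr) {
  if (inherits(tr, "fret_trace")) tr$E[seq_len(tr$valid_window)]
  else as.numeric(tr)
}

hmm_init <- function(pooled, K, jitter = FALSE) {
  qs <- stats::quantile(pooled, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (jitter) qs <- qs + stats::rnorm(K, 0, max(0.02, stats::sd(pooled) / 4))
  sig <- rep(max(stats::sd(pooled) / max(K, 2), 0.02), K)
  A <- matrix(0.05 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.95 else 1
  list(mu = qs, sigma = sig, A = A, pi = rep(1 / K, K))
}

hmm_jitter <- function(par, jitter) {
  if (jitter) par$mu <- par$mu + stats::rnorm(length(par$mu), 0, 0.02)
  par
}

hmm_em <- function(xs, par, tol, max_iter, sigma_floor) {
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  floored <- FALSE
  K <- length(par$mu)
  for (it in seq_len(max_iter)) {
    es <- hmm_estep(xs, par$mu, par$sigma, par$A, par$pi)
    ll <- es$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    mu <- ifelse(es$g_obs > 0, es$gx / es$g_obs, par$mu)
    v <- ifelse(es$g_obs > 0, es$gx2 / es$g_obs - mu^2, par$sigma^2)
    v[v < 0] <- 0
    sig <- sqrt(v)
    if (any(sig < sigma_floor)) {
      sig <- pmax(sig, sigma_floor)
      floored <- TRUE
    }
    A <- es$xi
    rs <- rowSums(A)
    for (k in seq_len(K))
      A[k, ] <- if (rs[k] > 0) A[k, ] / rs[k] else par$A[k, ]
    if (K == 1) A <- matrix(1, 1, 1)
    p1 <- es$g1 / sum(es$g1)
    par <- list(mu = mu, sigma = sig, A = A, pi = p1)
  }
  c(par, list(loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
              converged = converged, sigma_floored = floored))
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> K = %d, loglik = %.2f (%s)\n", x$K, x$loglik,
              if (x$converged) "converged" else "max_iter"))
  print(round(data.frame(mu = x$mu, sigma = x$sigma, pi = x$pi), 4))
  invisible(x)
}

#' Choose the number of HMM states by BIC
#'
#' Fits models for K = 1..`K_max` and minimises the Bayesian information
#' criterion, with the parameter count K - 1 (initial distribution) +
#' K(K - 1) (transitions) + 2K (emissions) and the total number of observed
#' frames as the sample size.  With heavily overlapping states at very low
#' signal-to-noise, BIC deliberately prefers fewer states (documented
#' behaviour), so the returned K can undershoot the generative one.
#'
#' @param traces as in [fit_hmm()].
#' @param K_max largest state count to consider.
#' @param ... passed to [fit_hmm()].
#' @return selected K (integer) with attribute `"bic"` (vector over K).
#' @export
select_model <- function(traces, K_max = 5L, ...) {
  bics <- vapply(seq_len(K_max), function(K) {
    m <- fit_hmm(traces, K, ...)
    p <- (K - 1) + K * (K - 1) + 2 * K
    -2 * m$loglik + p * log(m$n_frames)
  }, numeric(1))
  structure(which.min(bics), bic = bics)
}

#' Viterbi idealization of a trace
#'
#' Decodes the globally most probable state path under a fitted model
#' (deterministic given the model; likelihood ties resolve to the lowest
#' state index) and segments it into dwells.  Segments touching the trace
#' boundaries are flagged censored.
#'
#' @param model an [fit_hmm()] model.
#' @param trace a [fret_trace()] or numeric E vector.
#' @return object of class `"idealized_trace"`: list with `states`
#'   (per-frame state index over the valid window), `segments` (data frame
#'   `state`, `start`, `end`, `censored_left`, `censored_right`), `mu`
#'   (state means), `frame_s`, `id`.
#' @export
viterbi_path <- function(model, trace) {
  x <- trace_obs(trace)
  if (!length(x)) stop("empty trace")
  st <- hmm_viterbi(x, model$mu, model$sigma, model$A, model$pi)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- data.frame(state = r$values, start = starts, end = ends,
                         censored_left = starts == 1L,
                         censored_right = ends == length(st))
  structure(list(states = st, segments = segments, mu = model$mu,
                 frame_s = if (inherits(trace, "fret_trace"))
                   trace$frame_s else 0.1,
                 id = if (inherits(trace, "fret_trace")) trace$id else "trace"),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("<idealized_trace> %s: %d frames, %d dwell segment(s)\n",
              x$id, length(x$states), nrow(x$segments)))
  invisible(x)
}

#' Map fitted HMM states onto mechanistic classes
#'
#' Assigns each HMM state to one mechanistic class by its mean E against
#' ordered boundaries: S1 below the first, pS2 below the second, the
#' S2 band (S2/S2prime) below the third, S3 above.  A mean falling exactly
#' on a boundary goes to the lower class, with a warning.  S2 versus
#' S2prime cannot be told apart by level alone (same E band); the
#' distinction is contextual and made per trace by [event_sequence()].
#'
#' @param model an [fit_hmm()] model.
#' @param thresholds ordered E boundaries, default `c(0.15, 0.40, 0.75)`.
#' @return character vector, one class per HMM state (`"S1"`, `"pS2"`,
#'   `"S2"`, `"S3"`).
#' @export
classify_states <- function(model, thresholds = c(0.15, 0.40, 0.75)) {
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds))
  if (any(model$mu %in% thresholds))
    warning("state mean on a class boundary; assigned to the lower class",
            call. = FALSE)
  classes <- c("S1", "pS2", "S2", "S3")
  classes[findInterval(model$mu, thresholds, left.open = TRUE) + 1L]
}

#' Per-trace mechanistic event sequence
#'
#' Collapses an idealized trace into its sequence of mechanistic classes,
#' applying the contextual S2prime rule: a dwell in the S2 band that
#' persists to the end of the valid window without any later S3 visit, has
#' a low fitted emission s.d., and lasts long enough is relabelled
#' S2prime (the stable R-loop seen with LNA-blocked substrates and dead
#' protein).
#'
#' @param idealized an [viterbi_path()] result.
#' @param classes class per HMM state from [classify_states()].
#' @param model the fitted model (for the S2prime variance rule).
#' @param s2prime_sd maximum emission s.d. for the S2prime call
#'   (default 0.06).
#' @param s2prime_min_frames minimum terminal dwell length (default 50).
#' @return character vector of consecutive distinct classes, e.g.
#'   `c("S1", "S2", "S3")`.
#' @export
event_sequence <- function(idealized, classes, model = NULL,
                           s2prime_sd = 0.06, s2prime_min_frames = 50L) {
  seg <- idealized$segments
  cls <- classes[seg$state]
  r <- rle(cls)
  # terminal S2-band dwell with no later S3 and low variance -> S2prime
  n <- length(r$values)
  if (n >= 1 && r$values[n] == "S2") {
    last_states <- seg$state[(nrow(seg) - r$lengths[n] + 1L):nrow(seg)]
    len <- sum(seg$end[(nrow(seg) - r$lengths[n] + 1L):nrow(seg)] -
                 seg$start[(nrow(seg) - r$lengths[n] + 1L):nrow(seg)] + 1L)
    sd_ok <- is.null(model) ||
      all(model$sigma[unique(last_states)] <= s2prime_sd)
    if (seg$censored_right[nrow(seg)] && len >= s2prime_min_frames && sd_ok)
      r$values[n] <- "S2prime"
  }
  r$values
}

#' Write / read an HMM model as JSON
#'
#' @param model an [fit_hmm()] model.
#' @param path file path.
#' @return `read_hmm` returns an `"hmm_model"`.
#' @export
write_hmm <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, mu = model$mu, sigma = model$sigma,
         A = model$A, pi = model$pi, loglik = model$loglik),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(K = as.integer(j$K), mu = j$mu, sigma = j$sigma,
                 A = matrix(unlist(j$A), j$K, j$K), pi = j$pi,
                 loglik = j$loglik, ll_trace = NULL, converged = NA,
                 sigma_floored = FALSE, n_frames = NA_integer_),
            class = "hmm_model")
}
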