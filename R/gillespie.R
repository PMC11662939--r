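#' Exact stochastic simulation of a kinetic scheme
#'
#' Vectorised Gillespie sampler over the generator of a scheme: all paths
#' advance one jump per sweep, with exponential waiting times drawn from the
#' current exit rates and destinations drawn from the embedded jump chain.
#' Fully reproducible under a seed.
#'
#' @param scheme a [cleavage_scheme()] or [fret_scheme()] (any object with a
#'   generator `Q` and a `states` table).
#' @param duration_s simulated time horizon (s).
#' @param seed RNG seed (optional; the sampler also respects the caller's
#'   RNG state when `seed` is NULL).
#' @param n number of independent paths.
#' @param init index of the initial state (default 1: unbound / intact).
#' @return an object of class `"state_paths"`: list with `jumps` (data frame
#'   `path`, `time`, `state` index), `n`, `init`, `duration_s` and
#'   `state_names`.  Use [path_segments()] or [states_at()] to consume it.
#' @examples
#' g <- simulate_state_path(fret_scheme(), duration_s = 100, seed = 1, n = 5)
#' head(path_segments(g, 1))
#' @export
simulate_state_path <- function(scheme, duration_s, seed = NULL, n = 1L,
                                init = 1L) {
  Q <- scheme$Q
  stopifnot(duration_s > 0, all(is.finite(Q)))
  if (!is.null(seed)) set.seed(seed)
  nS <- nrow(Q)
  exit <- -diag(Q)
  exit[exit < 0] <- 0
  P <- Q; diag(P) <- 0

  state <- rep(as.integer(init), n)
  t_now <- numeric(n)
  done <- exit[state] <= 0
  rid <- vector("list", 64L); rt <- vector("list", 64L); rs <- vector("list", 64L)
  it <- 0L
  while (any(!done)) {
    it <- it + 1L
    if (it > 100000L) stop("gillespie: jump budget exceeded")
    act <- which(!done)
    dt <- stats::rexp(length(act), exit[state[act]])
    t_new <- t_now[act] + dt
    over <- t_new > duration_s
    done[act[over]] <- TRUE
    act <- act[!over]; t_new <- t_new[!over]
    if (!length(act)) next
    cur <- state[act]
    nxt <- integer(length(act))
    for (s in sort(unique(cur))) {
      i <- which(cur == s)
      nxt[i] <- sample.int(nS, length(i), replace = TRUE,
                           prob = P[s, ] / exit[s])
    }
    state[act] <- nxt; t_now[act] <- t_new
    rid[[it]] <- act; rt[[it]] <- t_new; rs[[it]] <- nxt
    done[act] <- exit[nxt] <= 0
  }
  jumps <- data.frame(path = unlist(rid), time = unlist(rt),
                      state = unlist(rs))
  if (nrow(jumps)) jumps <- jumps[order(jumps$path, jumps$time), ]
  structure(list(jumps = jumps, n = n, init = as.integer(init),
                 duration_s = duration_s,
                 state_names = rownames(scheme$states)),
            class = "state_paths")
}

#' @export
print.state_paths <- function(x, ...) {
  cat(sprintf("<state_paths> %d path(s), %d jumps, horizon %g s\n",
              x$n, nrow(x$jumps), x$duration_s))
  invisible(x)
}

#' Dwell segments of one simulated path
#'
#' @param paths a `"state_paths"` object.
#' @param path path index.
#' @return data frame `state` (name), `t_start`, `t_end` partitioning
#'   `[0, duration_s]`.
#' @export
path_segments <- function(paths, path = 1L) {
  j <- paths$jumps[paths$jumps$path == path, ]
  st <- c(paths$init, j$state)
  t0 <- c(0, j$time)
  t1 <- c(j$time, paths$duration_s)
  data.frame(state = paths$state_names[st], t_start = t0, t_end = t1,
             stringsAsFactors = FALSE)
}

#' State occupied by every path at given times
#'
#' @param paths a `"state_paths"` object.
#' @param times vector of query times within the horizon.
#' @return integer matrix (time x path) of state indices.
#' @export
states_at <- function(paths, times) {
  out <- matrix(paths$init, length(times), paths$n)
  j <- paths$jumps
  for (i in seq_along(times)) {
    jj <- j[j$time <= times[i], ]
    if (nrow(jj)) {
      jj <- jj[order(jj$time), ]   # last assignment per path wins
      st <- out[i, ]
      st[jj$path] <- jj$state
      out[i, ] <- st
    }
  }
  out
}

#' Empirical state occupancy of a Gillespie ensemble
#'
#' @param paths a `"state_paths"` object.
#' @param times query times.
#' @return matrix (time x state) of occupancy fractions, comparable to
#'   [propagate()] output.
#' @export
gillespie_occupancy <- function(paths, times) {
  st <- states_at(paths, times)
  nS <- length(paths$state_names)
  occ <- t(apply(st, 1, function(r) tabulate(r, nS) / length(r)))
  colnames(occ) <- paths$state_names
  attr(occ, "times") <- times
  occ
}
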