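#' Extract mechanistic dwell times from idealized traces
#'
#' Computes the three kinetic readouts per trace:
#' * `t1` (class `"S1"`) - time in S1 before the first entry into any
#'   S2-band class (pS2/S2/S2prime);
#' * `t2` (class `"S2"`) - cumulative occupancy of the S2 band between the
#'   first binding and the first S3 entry (pS2 <-> S2 excursions included:
#'   t2 reads as the total protospacer-processing time);
#' * `t3` (class `"S3"`) - cumulative S3 occupancy between the first S3
#'   entry and release (the first return from S3 to the S1 level, i.e. the
#'   acceptor-loss drop).
#'
#' A dwell whose closing event never occurs within the valid window
#' (end of trace or photobleach) is reported censored at the observed
#' duration.
#'
#' @param idealized_list list of [viterbi_path()] results.
#' @param classes_list class vector per HMM state (shared, from
#'   [classify_states()]), or a list of such vectors (one per trace).
#' @param frame_s frame interval (s).
#' @return data frame of class `"dwell_table"`: `trace`, `class`,
#'   `dwell_s`, `censored`.
#' @export
extract_dwells <- function(idealized_list, classes_list, frame_s = 0.1) {
  shared <- !is.list(classes_list)
  rows <- lapply(seq_along(idealized_list), function(i) {
    ide <- idealized_list[[i]]
    cls <- if (shared) classes_list else classes_list[[i]]
    trace_dwells(ide, cls, frame_s, ide$id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dwell_table", "data.frame")
  out
}

trace_dwells <- function(ide, classes, frame_s, id) {
  cl <- classes[ide$states]
  T <- length(cl)
  s2band <- cl %in% c("pS2", "S2", "S2prime")
  res <- NULL
  add <- function(class, frames, censored)
    res <<- rbind(res, data.frame(trace = id, class = class,
                                  dwell_s = frames * frame_s,
                                  censored = censored,
                                  stringsAsFactors = FALSE))
  bind <- which(s2band | cl == "S3")[1]
  if (is.na(bind)) {
    add("S1", T, TRUE)
    return(res)
  }
  if (bind > 1) add("S1", bind - 1L, FALSE)
  s3_first <- which(cl == "S3")
  s3_first <- s3_first[s3_first >= bind][1]
  if (is.na(s3_first)) {
    add("S2", sum(s2band[bind:T]), TRUE)
    return(res)
  }
  add("S2", sum(s2band[bind:s3_first]), FALSE)
  # release: first S3 -> S1-level transition after the first S3 entry
  rel <- which(cl == "S1" & seq_len(T) > s3_first)
  rel <- rel[rel > s3_first][1]
  if (is.na(rel)) {
    add("S3", sum(cl[s3_first:T] == "S3"), TRUE)
  } else {
    add("S3", sum(cl[s3_first:rel] == "S3"), FALSE)
  }
  res
}

#' Transition density plot from idealized traces
#'
#' One count per Viterbi transition at the (mean E before, mean E after)
#' coordinates of the fitted states, normalised to unit total mass
#' (self-transitions cannot occur in a segmented path, so the diagonal is
#' empty by construction; an ensemble without transitions yields an
#' all-zero density).
#'
#' @param idealized_list list of [viterbi_path()] results.
#' @param bins bin edges on both E axes (default `seq(0, 1, by = 0.02)`).
#' @return object of class `"tdp"`: list with `density` (before x after
#'   matrix), `bins`, `n_transitions`.
#' @export
build_tdp <- function(idealized_list, bins = seq(0, 1, by = 0.02)) {
  nb <- length(bins) - 1L
  counts <- matrix(0, nb, nb)
  n_tr <- 0L
  for (ide in idealized_list) {
    seg <- ide$segments
    if (nrow(seg) < 2L) next
    e_before <- ide$mu[seg$state[-nrow(seg)]]
    e_after <- ide$mu[seg$state[-1L]]
    ib <- findInterval(e_before, bins, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ia <- findInterval(e_after, bins, rightmost.closed = TRUE,
                       all.inside = TRUE)
    for (j in seq_along(ib)) counts[ib[j], ia[j]] <- counts[ib[j], ia[j]] + 1
    n_tr <- n_tr + length(ib)
  }
  dens <- if (n_tr > 0) counts / n_tr else counts
  structure(list(density = dens, bins = bins, n_transitions = n_tr),
            class = "tdp")
}

#' @export
print.tdp <- function(x, ...) {
  cat(sprintf("<tdp> %d transitions over %d x %d bins\n",
              x$n_transitions, nrow(x$density), ncol(x$density)))
  invisible(x)
}

#' Kaplan-Meier survival curve of dwell times
#'
#' Right-censoring-aware survival estimate (via the survival package);
#' with no censored dwells this reduces to the empirical survival
#' function.
#'
#' @param dwells a `"dwell_table"` (or data frame with `dwell_s`,
#'   `censored`), typically filtered to one class.
#' @return data frame `time`, `surv`, `n_risk`, starting at
#'   `S(0) = 1`.
#' @export
survival_curve <- function(dwells) {
  stopifnot(nrow(dwells) > 0)
  fit <- survival::survfit(
    survival::Surv(dwells$dwell_s, !dwells$censored) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(nrow(dwells), fit$n.risk))
}

#' Censoring-aware exponential fit of dwell times
#'
#' Maximum-likelihood estimate for exponentially distributed dwells with
#' right censoring: `tau_hat = sum(t_i) / #uncensored`, with an exact
#' chi-squared confidence interval on the mean.
#'
#' @param dwells as in [survival_curve()].
#' @param conf confidence level (default 0.95).
#' @return list with `tau` (mean dwell, s), `ci` (length 2), `n_events`,
#'   `n`.
#' @export
fit_exponential <- function(dwells, conf = 0.95) {
  d <- sum(!dwells$censored)
  if (d == 0) stop("no events: all dwells are censored")
  total <- sum(dwells$dwell_s)
  tau <- total / d
  a <- (1 - conf) / 2
  ci <- c(2 * total / stats::qchisq(1 - a, 2 * d),
          2 * total / stats::qchisq(a, 2 * d))
  list(tau = tau, ci = ci, n_events = d, n = nrow(dwells))
}

#' State-fraction summaries across an idealized ensemble
#'
#' Per-condition population statistics: the class of the initial E state
#' after binding, per-class occupancy fractions within the observation
#' window, and the fraction of trajectories showing PAM-distal release
#' within the window, each with a seeded bootstrap standard deviation
#' (resampling traces).
#'
#' @param idealized_list list of [viterbi_path()] results.
#' @param classes class per HMM state (see [classify_states()]).
#' @param window_s observation window (s), default 170.
#' @param frame_s frame interval (s).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed bootstrap seed.
#' @return list with `initial` (named fractions over first post-binding
#'   class), `occupancy` (named mean occupancy fractions), `release`
#'   (fraction released within the window), and `sd` (bootstrap standard
#'   deviations for each of the above).
#' @export
state_fractions <- function(idealized_list, classes, window_s = 170,
                            frame_s = 0.1, n_boot = 200, seed = 1) {
  lv <- c("S1", "pS2", "S2", "S3")
  per_trace <- lapply(idealized_list, function(ide) {
    cl <- classes[ide$states]
    w <- min(length(cl), ceiling(window_s / frame_s))
    cl <- cl[seq_len(w)]
    first_bound <- cl[cl != "S1"][1]
    occ <- vapply(lv, function(s) mean(cl == s), numeric(1))
    s3 <- which(cl == "S3")[1]
    released <- !is.na(s3) && any(cl[seq_along(cl) > s3] == "S1")
    list(initial = first_bound, occ = occ, released = released)
  })
  summarise <- function(idx) {
    pt <- per_trace[idx]
    ini <- factor(vapply(pt, function(p)
      if (is.na(p$initial)) "none" else p$initial, character(1)),
      levels = c(lv[-1], "none"))
    occ <- colMeans(do.call(rbind, lapply(pt, `[[`, "occ")))
    rel <- mean(vapply(pt, `[[`, logical(1), "released"))
    list(initial = prop.table(table(ini)), occupancy = occ, release = rel)
  }
  n <- length(idealized_list)
  est <- summarise(seq_len(n))
  set.seed(seed)
  boots <- replicate(n_boot, {
    s <- summarise(sample.int(n, n, replace = TRUE))
    c(as.numeric(s$initial), s$occupancy, s$release)
  })
  sds <- apply(boots, 1, stats::sd)
  k <- length(est$initial)
  est$sd <- list(initial = stats::setNames(sds[seq_len(k)],
                                           names(est$initial)),
                 occupancy = stats::setNames(sds[k + seq_along(est$occupancy)],
                                             names(est$occupancy)),
                 release = sds[length(sds)])
  est
}

#' Two-group comparison of dwell times
#'
#' Unpaired two-tailed t test between two dwell samples.  The Welch
#' variant is the default (unequal group sizes and variances are the rule
#' for single-molecule dwell samples); set `var_equal = TRUE` for the
#' pooled-variance test.  Censored dwells are excluded.  Significance
#' stars follow the conventional thresholds: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise.
#'
#' @param a,b dwell tables (or numeric vectors of dwell times).
#' @return list with `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  va <- dwell_values(a)
  vb <- dwell_values(b)
  if (identical(va, vb) || (stats::sd(va) == 0 && stats::sd(vb) == 0 &&
                            mean(va) == mean(vb))) {
    # degenerate identical samples: no evidence of a difference
    return(list(t = 0, df = NA_real_, p = 1, stars = "ns",
                mean_a = mean(va), mean_b = mean(vb),
                n_a = length(va), n_b = length(vb)))
  }
  tt <- stats::t.test(va, vb, var.equal = var_equal)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = stars, mean_a = mean(va), mean_b = mean(vb),
       n_a = length(va), n_b = length(vb))
}

dwell_values <- function(x) {
  if (is.data.frame(x)) x$dwell_s[!x$censored] else as.numeric(x)
}
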