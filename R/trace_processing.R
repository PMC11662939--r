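#' Background and leakage correction of a raw two-colour trace
#'
#' Applies the standard two-step correction: `I_D' = I_D - bkg_D`, then
#' `I_A' = I_A - bkg_A - leakage * I_D'`.  If more than half of the frames
#' have a corrected total below `floor` (the spot never rose above the
#' noise floor), the trace is flagged unusable.
#'
#' @param raw a `"trace_raw"` (or any data frame with `I_D`, `I_A`).
#' @param bkg_D,bkg_A per-frame channel backgrounds (a.u.).
#' @param leakage donor-into-acceptor leakage fraction, in \[0, 1).
#' @param floor noise floor on the corrected total intensity (a.u.).
#' @return data frame `frame`, `time_s` (if present), `I_D`, `I_A` of
#'   corrected intensities; attribute `usable` is FALSE (with attribute
#'   `reason`) for an all-background trace.  Other attributes of `raw`
#'   (truth, id) are carried along.
#' @export
correct_trace <- function(raw, bkg_D = 0, bkg_A = 0, leakage = 0,
                          floor = 100) {
  if (leakage < 0 || leakage >= 1) stop("leakage must lie in [0, 1)")
  id <- raw$I_D - bkg_D
  ia <- raw$I_A - bkg_A - leakage * id
  out <- raw
  out$I_D <- id
  out$I_A <- ia
  total <- id + ia
  usable <- mean(total < floor) <= 0.5
  attr(out, "usable") <- usable
  if (!usable) attr(out, "reason") <- "below_noise_floor"
  class(out) <- c("trace_corrected", "data.frame")
  out
}

#' FRET efficiency series from corrected intensities
#'
#' `E = I_A' / (I_D' + I_A')`, clipped to \[0, 1\]; frames whose corrected
#' total falls below `min_total` carry no usable signal (bleached or dark)
#' and are set to missing.
#'
#' @param corrected output of [correct_trace()].
#' @param min_total minimum corrected total intensity (a.u.) for a frame to
#'   be scored.
#' @return numeric vector of E values (NA where missing).
#' @export
fret_efficiency <- function(corrected, min_total = 100) {
  total <- corrected$I_D + corrected$I_A
  e <- corrected$I_A / total
  e[total < min_total] <- NA_real_
  pmin(pmax(e, 0), 1)
}

#' Adjacent-averaging smoothing
#'
#' Centred moving mean with an odd window of `n` points, truncated at the
#' trace edges (the first frame averages over frames 1..(n+1)/2, and so
#' on).  Missing frames are excluded from each window mean and remain
#' missing in the output.
#'
#' @param e numeric E series.
#' @param n odd window size (default 5).
#' @return smoothed series of the same length.
#' @examples
#' smooth_adjacent_average(c(0, 0, 1, 0, 0), n = 5)
#' @export
smooth_adjacent_average <- function(e, n = 5L) {
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("n must be odd and >= 1")
  if (n == 1L) return(e)
  half <- (n - 1L) %/% 2L
  T <- length(e)
  out <- rep(NA_real_, T)
  for (i in seq_len(T)) {
    if (is.na(e[i])) next
    w <- e[max(1L, i - half):min(T, i + half)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Construct a FRET trace from a raw trace
#'
#' Convenience wrapper chaining [correct_trace()], [fret_efficiency()] and
#' optionally [smooth_adjacent_average()], and locating the valid window:
#' frames before the first sustained collapse of the corrected total
#' intensity (donor bleach), during which E is defined.
#'
#' @param raw a `"trace_raw"`.
#' @param bkg_D,bkg_A,leakage correction parameters (see [correct_trace()]).
#' @param min_total frame-level signal threshold (see [fret_efficiency()]).
#' @param smooth_n optional odd window for smoothing (NULL = none).
#' @param sustain number of consecutive sub-threshold frames that mark a
#'   bleach (default 3; guards against single-frame blinks).
#' @param frame_s frame interval (s).
#' @return object of class `"fret_trace"`: list with `E` (full-length,
#'   NA outside the valid window or at dark frames), `valid_window` (last
#'   pre-bleach frame), `frame_s`, `smoothed`, `usable`, `id`, `truth`.
#' @export
fret_trace <- function(raw, bkg_D = 0, bkg_A = 0, leakage = 0,
                       min_total = 100, smooth_n = NULL, sustain = 3L,
                       frame_s = 0.1) {
  corr <- correct_trace(raw, bkg_D, bkg_A, leakage, floor = min_total)
  e <- fret_efficiency(corr, min_total)
  total_low <- is.na(e)
  # first run of >= sustain consecutive dark frames = donor bleach
  valid_window <- length(e)
  r <- rle(total_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain)
  if (length(hit)) valid_window <- starts[hit[1]] - 1L
  if (valid_window < length(e)) e[(valid_window + 1L):length(e)] <- NA_real_
  smoothed <- FALSE
  if (!is.null(smooth_n)) {
    e <- smooth_adjacent_average(e, smooth_n)
    smoothed <- TRUE
  }
  structure(list(E = e, valid_window = valid_window, frame_s = frame_s,
                 smoothed = smoothed,
                 usable = isTRUE(attr(corr, "usable")),
                 id = attr(raw, "id") %||% "trace",
                 truth = attr(raw, "truth")),
            class = "fret_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %s: %d frames, valid window %d, %s\n",
              x$id, length(x$E), x$valid_window,
              if (x$smoothed) "smoothed" else "raw"))
  invisible(x)
}

#' Select analyzable trajectories
#'
#' Deterministic pass/fail filtering with reason codes, mirroring the
#' selection applied to real data: the acceptor must be active at the start
#' of the trace (traces whose acceptor bleaches before the donor report a
#' dead acceptor), interior dark gaps (blinking/quenching) must not exceed
#' a tolerance, and the valid window must be long enough.
#'
#' @param traces list of [fret_trace()] objects.
#' @param rules list with `min_valid_frames` (default 50), `max_dark_gap`
#'   (frames, default 2) and `require_acceptor` (default TRUE; uses the
#'   simulation truth when present, otherwise requires E signal in the
#'   first frames).
#' @return list with `kept` (the passing traces), and `log`, a data frame
#'   (`id`, `pass`, `reason`) with one row per input trace.
#' @export
select_trajectories <- function(traces,
                                rules = list(min_valid_frames = 50L,
                                             max_dark_gap = 2L,
                                             require_acceptor = TRUE)) {
  rules$min_valid_frames <- rules$min_valid_frames %||% 50L
  rules$max_dark_gap <- rules$max_dark_gap %||% 2L
  rules$require_acceptor <- rules$require_acceptor %||% TRUE
  judge <- function(tr) {
    if (!tr$usable) return("below_noise_floor")
    if (isTRUE(rules$require_acceptor)) {
      tru <- tr$truth
      if (!is.null(tru) && !is.na(tru$bleach_A) &&
          (is.na(tru$bleach_D) || tru$bleach_A < tru$bleach_D))
        return("acceptor_dead")
    }
    if (tr$valid_window < rules$min_valid_frames) return("short_window")
    dark <- is.na(tr$E[seq_len(tr$valid_window)])
    if (any(dark)) {
      r <- rle(dark)
      interior <- r$values & seq_along(r$values) > 1 &
        seq_along(r$values) < length(r$values)
      if (any(r$lengths[interior] > rules$max_dark_gap))
        return("quenching")
    }
    NA_character_
  }
  reasons <- vapply(traces, judge, character(1))
  pass <- is.na(reasons)
  log <- data.frame(id = vapply(traces, function(t) t$id, character(1)),
                    pass = pass, reason = reasons,
                    stringsAsFactors = FALSE)
  list(kept = traces[pass], log = log)
}

#' Post-synchronised population FRET contour
#'
#' Aligns each trace at its first binding event (E rising above a threshold
#' and staying there for a few frames) and histograms E across traces in
#' each post-synchronisation time bin.  Each time-bin column is normalised
#' to unit mass (all-zero where no trace contributes), giving the familiar
#' population contour plot.
#'
#' @param traces list of [fret_trace()] objects.
#' @param e_bins E bin edges (default `seq(0, 1, by = 0.05)`).
#' @param time_bins post-synchronisation time bin edges in seconds
#'   (default `seq(0, 60, by = 1)`).
#' @param sync `"binding"` (default) aligns at the detected binding event;
#'   `"start"` aligns at frame 1.
#' @param threshold,sustain binding detector: first frame with
#'   `E > threshold` sustained for `sustain` frames (defaults 0.15 and 3).
#' @return object of class `"fret_contour"`: list with `density` (matrix,
#'   E bins x time bins, columns summing to 1 or all zero), `e_bins`,
#'   `time_bins`, `n_traces`.
#' @export
build_contour <- function(traces, e_bins = seq(0, 1, by = 0.05),
                          time_bins = seq(0, 60, by = 1),
                          sync = c("binding", "start"),
                          threshold = 0.15, sustain = 3L) {
  sync <- match.arg(sync)
  if (!length(traces)) stop("no traces")
  counts <- matrix(0, length(e_bins) - 1L, length(time_bins) - 1L)
  used <- 0L
  for (tr in traces) {
    t0 <- if (sync == "binding")
      detect_binding(tr$E, threshold, sustain) else 1L
    if (is.na(t0)) next
    used <- used + 1L
    idx <- t0:tr$valid_window
    if (!length(idx)) next
    tt <- (idx - t0) * tr$frame_s
    ee <- tr$E[idx]
    ok <- !is.na(ee) & tt >= time_bins[1] & tt < time_bins[length(time_bins)]
    if (!any(ok)) next
    ib <- findInterval(ee[ok], e_bins, rightmost.closed = TRUE,
                       all.inside = TRUE)
    it <- findInterval(tt[ok], time_bins, rightmost.closed = TRUE,
                       all.inside = TRUE)
    for (j in seq_along(ib)) counts[ib[j], it[j]] <- counts[ib[j], it[j]] + 1
  }
  if (used == 0L) stop("no trace contains the synchronisation event")
  cs <- colSums(counts)
  dens <- sweep(counts, 2, ifelse(cs > 0, cs, 1), "/")
  structure(list(density = dens, e_bins = e_bins, time_bins = time_bins,
                 n_traces = used),
            class = "fret_contour")
}

#' First binding event in an E series
#'
#' @param e E series.
#' @param threshold E threshold (default 0.15).
#' @param sustain consecutive frames required above threshold (default 3).
#' @return frame index of the event, or NA if absent.
#' @export
detect_binding <- function(e, threshold = 0.15, sustain = 3L) {
  above <- !is.na(e) & e > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]]
}

#' @export
print.fret_contour <- function(x, ...) {
  cat(sprintf("<fret_contour> %d x %d bins from %d trace(s)\n",
              nrow(x$density), ncol(x$density), x$n_traces))
  invisible(x)
}
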