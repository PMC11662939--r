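#' Write / read a raw trace as a tabular file with a truth sidecar
#'
#' Traces are stored as tab-separated `frame`, `I_D`, `I_A`; when the trace
#' carries a simulation truth (hidden path, bleach frames), it is written to
#' a JSON sidecar `<path>.json` so that synthetic fixtures remain
#' self-describing.
#'
#' @param trace a `"trace_raw"`.
#' @param path output file path.
#' @return `read_trace` returns a `"trace_raw"` data frame.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace[, c("frame", "I_D", "I_A")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- attr(trace, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(id = attr(trace, "id"),
           state = truth$state, E = truth$E,
           bleach_D = truth$bleach_D, bleach_A = truth$bleach_A,
           path = truth$path),
      paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace
#' @param frame_s frame interval (s) used to reconstruct the time axis.
#' @export
read_trace <- function(path, frame_s = 0.1) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  d$time_s <- (d$frame - 1) * frame_s
  d <- d[, c("frame", "time_s", "I_D", "I_A")]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(d, "id") <- j$id
    attr(d, "truth") <- list(E = j$E, state = j$state,
                             bleach_D = j$bleach_D, bleach_A = j$bleach_A,
                             path = j$path)
  }
  class(d) <- c("trace_raw", "data.frame")
  d
}

#' Write / read a band timecourse as CSV
#'
#' Long format `time_s`, `fragment_nt`, `fraction`, with the intact
#' substrate stored as `fragment_nt = "intact"`.
#'
#' @param bt a [band_timecourse()].
#' @param path CSV path.
#' @return `read_band_timecourse` returns a [band_timecourse()].
#' @export
write_band_timecourse <- function(bt, path) {
  long <- data.frame(
    time_s = rep(bt$times, ncol(bt$fractions) + 1L),
    fragment_nt = rep(c(as.character(bt$fragment_lengths), "intact"),
                      each = length(bt$times)),
    fraction = c(bt$fractions, bt$intact))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_timecourse
#' @export
read_band_timecourse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  times <- sort(unique(d$time_s))
  frags <- sort(as.integer(unique(d$fragment_nt[d$fragment_nt != "intact"])))
  fr <- sapply(frags, function(L)
    d$fraction[d$fragment_nt == as.character(L)][order(d$time_s[d$fragment_nt == as.character(L)])])
  intact <- d$fraction[d$fragment_nt == "intact"][
    order(d$time_s[d$fragment_nt == "intact"])]
  band_timecourse(times, frags, matrix(fr, ncol = length(frags)), intact)
}

#' Read a single DNA sequence from a FASTA file
#'
#' Uses Biostrings when available.
#'
#' @param path FASTA file.
#' @return character string (first record).
#' @export
read_fasta_sequence <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readDNAStringSet(path)
    return(as.character(s[[1]]))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ">")]
  toupper(paste(lines, collapse = ""))
}

#' Write a population contour as CSV with bin-edge headers
#'
#' @param contour a [build_contour()] result.
#' @param path CSV path.
#' @export
write_contour <- function(contour, path) {
  m <- contour$density
  rownames(m) <- sprintf("E_%g_%g", contour$e_bins[-length(contour$e_bins)],
                         contour$e_bins[-1])
  colnames(m) <- sprintf("t_%g_%g",
                         contour$time_bins[-length(contour$time_bins)],
                         contour$time_bins[-1])
  utils::write.csv(m, path)
  invisible(path)
}

#' Write an idealization as CSV
#'
#' One row per frame: `frame`, `state` (HMM state index) and `class`
#' (mechanistic label).
#'
#' @param idealized a [viterbi_path()] result.
#' @param classes class per HMM state (see [classify_states()]).
#' @param path CSV path.
#' @export
write_idealization <- function(idealized, classes, path) {
  utils::write.csv(
    data.frame(frame = seq_along(idealized$states),
               state = idealized$states,
               class = classes[idealized$states]),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a transition density plot as a CSV matrix
#'
#' Rows are E-before bins, columns E-after bins, with bin-edge labels.
#'
#' @param tdp a [build_tdp()] result.
#' @param path CSV path.
#' @export
write_tdp <- function(tdp, path) {
  m <- tdp$density
  lab <- sprintf("E_%g_%g", tdp$bins[-length(tdp$bins)], tdp$bins[-1])
  rownames(m) <- lab
  colnames(m) <- lab
  utils::write.csv(m, path)
  invisible(path)
}

#' Write a simulation manifest
#'
#' Records the scheme variant, Mg concentration, rates, photophysics and
#' seeds of a synthetic ensemble as JSON, so a fixture set remains
#' self-describing and regenerable.
#'
#' @param scheme the [fret_scheme()] (or [cleavage_scheme()]) used.
#' @param phys the [photophysics()] model (optional).
#' @param n number of traces/paths.
#' @param seed ensemble seed.
#' @param path JSON path.
#' @export
write_manifest <- function(scheme, phys = NULL, n, seed, path) {
  jsonlite::write_json(
    list(class = class(scheme)[1],
         variant = scheme$variant, protein = scheme$protein,
         mg_mM = scheme$mg_mM, rates = unclass(scheme$rates),
         photophysics = if (!is.null(phys)) unclass(phys),
         n = n, seed = seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
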