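#' Substrate coordinate map for a labelled duplex cleavage substrate
#'
#' Describes an end-labelled double-stranded DNA substrate in protospacer
#' coordinates.  Position +1 is the first protospacer nucleotide adjacent to
#' the PAM; the protospacer runs +1 (PAM-proximal) to +20 (PAM-distal).
#' The PAM-proximal flank (`pam_proximal_flank`, inclusive of the PAM) sits
#' upstream of +1 on the non-target strand (NTS); everything beyond +20 up
#' to the duplex end is the out-of-protospacer (PAM-distal) region.
#'
#' A cut at protospacer position `p` severs the backbone bond on the 3' side
#' of nucleotide `p` on that strand's own coordinate axis, so the fragment
#' carrying the PAM-proximal duplex end has length `pam_proximal_flank + p`
#' and the complementary fragment `total_length - pam_proximal_flank - p`.
#' With the default 80-bp substrate and a 26-nt flank this reproduces the
#' full set of denaturing-gel product lengths (e.g. the +16 nick yields a
#' 42-nt 5'-labelled NTS fragment).
#'
#' @param total_length duplex length in bp (default 80).
#' @param pam_proximal_flank nt upstream of protospacer position +1 on the
#'   NTS, inclusive of the PAM (default 26, anchored so that the +16 cut
#'   gives a 42-nt 5'-labelled NTS product).
#' @param protospacer_length protospacer length in nt; must be 20.
#' @param pam PAM sequence code, 4 characters (default `"NTTR"`).
#' @param lna_region optional length-2 integer vector, closed interval of
#'   protospacer coordinates carrying locked-nucleic-acid modifications
#'   (e.g. `c(21, 27)`); cuts inside the interval are blocked.
#' @param label list with elements `strand` (`"NTS"` or `"TS"`), `end`
#'   (`"5p"`, `"3p"` or `"internal"`) and, for internal labels, `position`
#'   (protospacer coordinate of the labelled nucleotide).
#'
#' @return an object of class `"substrate_map"`.
#' @examples
#' m <- substrate_map(label = list(strand = "NTS", end = "5p"))
#' fragment_length(m, cut_site("NTS", 16))  # 42
#' @export
substrate_map <- function(total_length = 80L,
                          pam_proximal_flank = 26L,
                          protospacer_length = 20L,
                          pam = "NTTR",
                          lna_region = NULL,
                          label = list(strand = "NTS", end = "5p")) {
  total_length <- as.integer(total_length)
  pam_proximal_flank <- as.integer(pam_proximal_flank)
  protospacer_length <- as.integer(protospacer_length)
  if (protospacer_length != 20L)
    stop("protospacer_length must be 20")
  if (pam_proximal_flank < 0L || total_length <= 0L)
    stop("lengths must be positive")
  if (pam_proximal_flank + protospacer_length > total_length)
    stop("pam_proximal_flank + protospacer_length exceeds total_length")
  if (nchar(pam) != 4L)
    stop("pam must be a 4-character code")
  if (!is.null(lna_region)) {
    lna_region <- as.integer(lna_region)
    if (length(lna_region) != 2L || lna_region[1] > lna_region[2])
      stop("lna_region must be a closed interval c(lo, hi)")
    if (lna_region[1] < 1L ||
        lna_region[2] > total_length - pam_proximal_flank)
      stop("lna_region outside the substrate's protospacer coordinate range")
  }
  label$strand <- match.arg(label$strand, c("NTS", "TS"))
  label$end <- match.arg(label$end, c("5p", "3p", "internal"))
  if (label$end == "internal" && is.null(label$position))
    stop("internal label requires a position")
  structure(
    list(total_length = total_length,
         pam_proximal_flank = pam_proximal_flank,
         protospacer_length = protospacer_length,
         pam = pam,
         lna_region = lna_region,
         label = label),
    class = "substrate_map")
}

#' @export
print.substrate_map <- function(x, ...) {
  cat(sprintf("<substrate_map> %d bp, flank %d nt (PAM %s), protospacer +1..+%d\n",
              x$total_length, x$pam_proximal_flank, x$pam,
              x$protospacer_length))
  cat(sprintf("  label: %s %s%s\n", x$label$strand, x$label$end,
              if (!is.null(x$label$position))
                sprintf(" @ +%d", x$label$position) else ""))
  if (!is.null(x$lna_region))
    cat(sprintf("  LNA region: +%d..+%d\n", x$lna_region[1], x$lna_region[2]))
  invisible(x)
}

#' A single strand cleavage site in protospacer coordinates
#'
#' @param strand `"NTS"` or `"TS"`.
#' @param position protospacer coordinate `p >= 1`; the cut severs the bond
#'   3' of nucleotide `p` on that strand's coordinate axis.  Positions
#'   beyond +20 denote out-of-protospacer cuts.
#' @return an object of class `"cut_site"`.
#' @export
cut_site <- function(strand = c("NTS", "TS"), position) {
  strand <- match.arg(strand)
  position <- as.integer(position)
  if (position < 1L) stop("cut position must be >= 1")
  structure(list(strand = strand, position = position), class = "cut_site")
}

#' @export
print.cut_site <- function(x, ...) {
  cat(sprintf("<cut_site> %s +%d\n", x$strand, x$position))
  invisible(x)
}

# distance (nt) from the PAM-proximal duplex end to the cut bond on the cut
# strand; the complementary fragment is total_length minus this
proximal_cut_distance <- function(map, position) {
  map$pam_proximal_flank + position
}

#' Length of the labelled fragment produced by a single cut
#'
#' Both strand coordinate axes are anchored at protospacer position +1 with
#' the flank lengths taken from the map.  The NTS 5' terminus and the TS 3'
#' terminus sit at the PAM-proximal duplex end, so a cut at +p leaves a
#' `flank + p` nt fragment on that side and `total - flank - p` nt on the
#' PAM-distal side; which of the two is reported depends on where the label
#' sits.
#'
#' @param map a [substrate_map()]; its label must be set.
#' @param cut a [cut_site()] on the same substrate.
#' @return labelled fragment length in nt (integer).  For an internal label,
#'   the length of the fragment that retains the labelled nucleotide; if the
#'   label falls on a fragment too short to resolve the function signals a
#'   condition of class `"smcleave_short_product"`.
#' @examples
#' m5 <- substrate_map(label = list(strand = "NTS", end = "5p"))
#' m3 <- substrate_map(label = list(strand = "NTS", end = "3p"))
#' fragment_length(m5, cut_site("NTS", 14))  # 40
#' fragment_length(m3, cut_site("NTS", 25))  # 29
#' @export
fragment_length <- function(map, cut) {
  stopifnot(inherits(map, "substrate_map"), inherits(cut, "cut_site"))
  if (cut$position > map$total_length - map$pam_proximal_flank)
    stop("cut position beyond the substrate end")
  prox <- proximal_cut_distance(map, cut$position)
  dist <- map$total_length - prox
  if (cut$strand != map$label$strand)
    stop("label and cut are on different strands; the labelled strand is uncut")
  lab <- map$label
  if (lab$end == "internal") {
    # labelled nucleotide at protospacer coordinate lab$position on the
    # labelled strand: it stays with the proximal piece iff position <= p
    len <- if (lab$position <= cut$position) prox else dist
    if (len < 8L)
      stop(structure(
        class = c("smcleave_short_product", "error", "condition"),
        list(message = sprintf(
          "labelled product (%d nt) shorter than the resolvable window", len),
          call = sys.call(-1))))
    return(as.integer(len))
  }
  # end labels: NTS 5' and TS 3' are PAM-proximal termini
  proximal_label <- (lab$strand == "NTS" && lab$end == "5p") ||
    (lab$strand == "TS" && lab$end == "3p")
  as.integer(if (proximal_label) prox else dist)
}

#' Is a cut position blocked by the map's LNA region?
#'
#' Locked nucleotides resist duplex unwinding; because unwinding is a
#' prerequisite for cleavage, all cuts that require opening the duplex past
#' the first locked base pair are blocked.  A cut at `p` severs the bond
#' between nucleotides `p` and `p + 1`, so the cut at the LNA boundary
#' itself (e.g. +21 for an LNA region starting at +21) is still permitted
#' while deeper cuts (+23, +25 and the TS cut at +23) are not.
#'
#' @param map a [substrate_map()].
#' @param position protospacer coordinate of the cut.
#' @return logical.
#' @export
lna_blocked <- function(map, position) {
  !is.null(map$lna_region) && position > map$lna_region[1]
}

#' Enumerate observable labelled fragment lengths under a cleavage scheme
#'
#' Walks every lesion state reachable in the scheme and collects the
#' distinct fragment lengths visible to the map's label: a 5'-end NTS label
#' (PAM-proximal terminus) sees only the proximal 3'->5' trimming front, a
#' 3'-end NTS label only the distal 5'->3' front, and a TS label only the
#' endonucleolytic TS cut.  Cut positions blocked by the map's LNA region
#' (see [lna_blocked()]) are excluded.
#'
#' @param map a [substrate_map()].
#' @param scheme a [cleavage_scheme()].
#' @return sorted integer vector of distinct observable fragment lengths.
#' @examples
#' m3 <- substrate_map(label = list(strand = "NTS", end = "3p"))
#' enumerate_products(m3, cleavage_scheme())  # 29 31 33 36 38
#' @export
enumerate_products <- function(map, scheme) {
  stopifnot(inherits(map, "substrate_map"), inherits(scheme, "cleavage_scheme"))
  st <- scheme$states
  lens <- integer(0)
  if (map$label$strand == "NTS") {
    pos <- if (map$label$end == "5p") st$proximal else st$distal
    pos <- sort(unique(pos[!is.na(pos)]))
    for (p in pos) {
      if (lna_blocked(map, p)) next
      lens <- c(lens, fragment_length(map, cut_site("NTS", p)))
    }
  } else {
    ts_pos <- unique(st$ts_position[st$ts_cut])
    ts_pos <- ts_pos[!is.na(ts_pos)]
    for (p in ts_pos) {
      if (lna_blocked(map, p)) next
      lens <- c(lens, fragment_length(map, cut_site("TS", p)))
    }
  }
  sort(unique(lens))
}
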