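#' Insertion-site specification
#'
#' An insertion site is given either as a 1-based coordinate or as an anchor
#' subsequence whose occurrence on the vector is looked up at resolution time
#' (e.g. a start codon or an affinity-tag coding sequence).
#'
#' @param coordinate 1-based position on the vector (coordinate mode).
#' @param anchor Anchor subsequence, at least 3 nt (anchor mode).
#' @param required_unique In anchor mode, fail if the anchor occurs more than
#'   once rather than picking one occurrence.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(coordinate = NULL, anchor = NULL, required_unique = TRUE) {
  if (is.null(coordinate) == is.null(anchor))
    stop_mrf("argument", "give exactly one of `coordinate` or `anchor`")
  if (!is.null(coordinate)) {
    coordinate <- as.integer(coordinate)
    if (is.na(coordinate) || coordinate < 1L)
      stop_mrf("argument", "coordinate must be a 1-based position (>= 1)")
    mode <- "coordinate"
  } else {
    anchor <- assert_dna(anchor, "anchor")
    if (nchar(anchor) < 3L)
      stop_mrf("argument", "anchor must be at least 3 nt")
    mode <- "anchor"
  }
  structure(list(mode = mode, coordinate = coordinate, anchor = anchor,
                 required_unique = isTRUE(required_unique)),
            class = "site_spec")
}

as_site_spec <- function(x) {
  if (inherits(x, "site_spec")) return(x)
  if (is.numeric(x)) return(site_spec(coordinate = x))
  if (is.character(x)) return(site_spec(anchor = x))
  stop_mrf("argument", "site must be a coordinate, an anchor string, or a site_spec")
}

#' Resolve an insertion site to a vector coordinate
#'
#' Coordinate mode bounds-checks the position. Anchor mode returns the 1-based
#' start of the unique top-strand occurrence; on circular vectors the search
#' wraps across the origin. With `both_strands = TRUE` the reverse complement
#' is searched too and the strand of the hit is attached as an attribute.
#'
#' @param vector A [nuc_seq()].
#' @param site A [site_spec()], a coordinate, or an anchor string.
#' @param both_strands Also search the bottom strand.
#' @return The 1-based coordinate (integer); anchor hits carry a `"strand"`
#'   attribute (`"top"` or `"bottom"`).
#' @examples
#' v <- nuc_seq("AAACCCGGG", id = "v")
#' resolve_site(v, "CCC")  # 4
#' @export
resolve_site <- function(vector, site, both_strands = FALSE) {
  vector <- as_nuc_seq(vector)
  site <- as_site_spec(site)
  L <- seq_length(vector)
  if (site$mode == "coordinate") {
    if (site$coordinate > L)
      stop_mrf("bounds", sprintf("coordinate %d beyond sequence '%s' (%d bp)",
                                 site$coordinate, vector$id, L))
    return(site$coordinate)
  }
  hits <- locate_matches(vector, site$anchor)
  strands <- rep("top", length(hits))
  if (both_strands) {
    rc_hits <- locate_matches(vector, revcomp(site$anchor))
    hits <- c(hits, rc_hits)
    strands <- c(strands, rep("bottom", length(rc_hits)))
  }
  if (length(hits) == 0L)
    stop_mrf("anchor_not_found",
             sprintf("anchor '%s' not found on vector '%s'", site$anchor, vector$id),
             anchor = site$anchor)
  if (length(hits) > 1L && site$required_unique)
    stop_mrf("anchor_ambiguous",
             sprintf("anchor '%s' occurs %d times on '%s' (positions %s)",
                     site$anchor, length(hits), vector$id,
                     paste(sort(hits), collapse = ", ")),
             anchor = site$anchor, positions = sort(hits))
  ord <- order(hits)
  structure(hits[ord][1], strand = strands[ord][1])
}
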