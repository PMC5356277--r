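# Simulation of the two PCR rounds: regular double-primer PCR produces blunt
# duplexes ("fragment 1" from the vector, "fragment 2" from the insert); two
# single-primer linear PCRs per fragment then produce tailed single strands
# ("3-1"/"3-2", "4-1"/"4-2") which anneal into cohesive-ended duplexes
# ("3", "4"). Priming is exact-match only: the simulation models the intended
# reaction, not PCR artifacts.

#' Blunt PCR amplicon
#'
#' @param top Top strand, 5' to 3'.
#' @param id Label.
#' @return An object of class `amplicon_duplex` with `top`, `bottom`
#'   (`revcomp(top)`) and `blunt = TRUE`.
#' @export
amplicon_duplex <- function(top, id = "amplicon") {
  top <- assert_dna(top, "amplicon top strand")
  structure(list(top = top, bottom = revcomp(top), blunt = TRUE, id = id),
            class = "amplicon_duplex")
}

#' @export
print.amplicon_duplex <- function(x, ...) {
  cat(sprintf("<amplicon_duplex> %s: %d bp, blunt\n", x$id, nchar(x$top)))
  invisible(x)
}

#' Single-strand product of a linear PCR
#'
#' @param bases The strand, 5' to 3' (primer tail + body + template copy).
#' @param origin Name of the primer that produced it.
#' @param label Fragment label (the workflow uses "3-1", "3-2", "4-1", "4-2").
#' @return An object of class `strand_product`.
#' @export
strand_product <- function(bases, origin = "", label = "") {
  structure(list(bases = assert_dna(bases, "strand"), origin = origin,
                 label = label),
            class = "strand_product")
}

#' @export
print.strand_product <- function(x, ...) {
  cat(sprintf("<strand_product> %s (from %s): %d nt\n",
              x$label, x$origin, nchar(x$bases)))
  invisible(x)
}

# An end record annotates one terminus of a duplex: which strand protrudes,
# the protruding sequence 5'->3', whether it is a 5' or 3' protrusion, and
# which side of the duplex it sits on. Zero length <=> blunt.
end_record <- function(seq, strand, end = "5p", side = "left") {
  list(seq = seq, length = nchar(seq), strand = strand, end = end, side = side)
}

#' Double-stranded fragment with annotated cohesive ends
#'
#' @param top,bottom The two strands, each 5' to 3'. Drawn conventionally,
#'   `top` runs left to right and `bottom` right to left, so the left end of
#'   the duplex holds top's 5' terminus and bottom's 3' terminus.
#' @param left_overhang,right_overhang End records as produced by [anneal()]:
#'   lists with `seq`, `length`, `strand` (`"top"`/`"bottom"`), `end`
#'   (`"5p"`/`"3p"`), `side`.
#' @param id Label.
#' @return An object of class `sticky_duplex`.
#' @export
sticky_duplex <- function(top, bottom, left_overhang, right_overhang,
                          id = "duplex") {
  structure(list(top = assert_dna(top, "top strand"),
                 bottom = assert_dna(bottom, "bottom strand"),
                 left_overhang = left_overhang,
                 right_overhang = right_overhang, id = id),
            class = "sticky_duplex")
}

#' @export
print.sticky_duplex <- function(x, ...) {
  fmt <- function(e) if (e$length == 0L) "blunt"
    else sprintf("%s %s-%s protrusion %s", e$strand, substr(e$end, 1, 1), "'", e$seq)
  cat(sprintf("<sticky_duplex> %s: top %d nt / bottom %d nt\n  left: %s\n  right: %s\n",
              x$id, nchar(x$top), nchar(x$bottom),
              fmt(x$left_overhang), fmt(x$right_overhang)))
  invisible(x)
}

#' @rdname sticky_duplex
#' @param x A `sticky_duplex`.
#' @export
duplex_span <- function(x) {
  # total extent in bp including both protrusions
  nchar(x$top) +
    (if (x$left_overhang$strand == "bottom") x$left_overhang$length else 0L) +
    (if (x$right_overhang$strand == "bottom") x$right_overhang$length else 0L)
}

# --- priming ---------------------------------------------------------------

find_binding <- function(seq_obj, body, primer_name, strand_label) {
  hits <- locate_matches(seq_obj, body)
  list(hits = hits, strand = strand_label, primer = primer_name)
}

#' Simulate regular double-primer PCR
#'
#' The forward primer body must match the template top strand exactly and
#' uniquely; the reverse primer body must match the bottom strand likewise.
#' On circular templates the amplicon runs from the forward site forward to
#' the reverse site, wrapping the origin if needed. Primer tails are appended
#' untemplated: the product top strand is
#' `fwd tail + template segment + revcomp(rev tail)`, and the product is
#' blunt.
#'
#' @param template A [nuc_seq()] (circular or linear).
#' @param fwd,rev Forward and reverse [oligo()]s.
#' @param id Product label.
#' @return An [amplicon_duplex()].
#' @export
pcr_amplify <- function(template, fwd, rev, id = NULL) {
  template <- as_nuc_seq(template)
  L <- seq_length(template)
  fb <- fwd$body
  rb <- rev$body
  f_hits <- locate_matches(template, fb)
  r_hits <- locate_matches(template, revcomp(rb))  # rev binds the bottom strand
  for (h in list(list(f_hits, fwd), list(r_hits, rev))) {
    if (length(h[[1]]) == 0L)
      stop_mrf("no_binding",
               sprintf("primer %s has no exact binding site on template '%s'",
                       h[[2]]$name, template$id), primer = h[[2]]$name)
    if (length(h[[1]]) > 1L)
      stop_mrf("ambiguous_priming",
               sprintf("primer %s binds template '%s' at %d sites (positions %s)",
                       h[[2]]$name, template$id, length(h[[1]]),
                       paste(h[[1]], collapse = ", ")),
               primer = h[[2]]$name, positions = h[[1]])
  }
  f_start <- f_hits[1]
  r_end <- r_hits[1] + nchar(rb) - 1L
  if (is_circular(template)) {
    seg_len <- ((r_end - f_start) %% L) + 1L
    seg <- circ_sub(template$bases, f_start, seg_len)
  } else {
    if (r_end < f_start)
      stop_mrf("geometry",
               sprintf("primers %s/%s diverge on linear template '%s': no product",
                       fwd$name, rev$name, template$id))
    seg <- substr(template$bases, f_start, r_end)
  }
  rtail <- if (nzchar(rev$tail)) revcomp(rev$tail) else ""
  amplicon_duplex(paste0(fwd$tail, seg, rtail),
                  id = id %||% paste0(template$id, "-amplicon"))
}

#' Simulate single-primer linear PCR
#'
#' The primer body must match exactly one site on exactly one strand of the
#' template duplex. The product is the full-length copy of that strand from
#' the binding site to its 3'-proximal template end, with the primer tail
#' appended at the 5' end -- the end product of a linear amplification, with
#' no intermediate species or stoichiometry tracked.
#'
#' @param template An [amplicon_duplex()] (or `sticky_duplex`).
#' @param primer An [oligo()].
#' @param label Fragment label for the product.
#' @return A [strand_product()].
#' @export
linear_amplify <- function(template, primer, label = "") {
  b <- primer$body
  top_hits <- locate_fixed(template$top, b)
  bot_hits <- locate_fixed(template$bottom, b)
  total <- length(top_hits) + length(bot_hits)
  if (total == 0L)
    stop_mrf("no_binding",
             sprintf("primer %s has no exact binding site on duplex '%s'",
                     primer$name, template$id), primer = primer$name)
  if (total > 1L)
    stop_mrf("ambiguous_priming",
             sprintf("primer %s binds duplex '%s' at %d sites", primer$name,
                     template$id, total), primer = primer$name)
  strand <- if (length(top_hits)) template$top else template$bottom
  start <- if (length(top_hits)) top_hits[1] else bot_hits[1]
  strand_product(paste0(primer$tail, substr(strand, start, nchar(strand))),
                 origin = primer$name,
                 label = if (nzchar(label)) label else primer$name)
}

# --- annealing -------------------------------------------------------------

# Overlap of s1 (top) with r2 = revcomp(s2) at offset d: s1[j] pairs r2[j-d].
overlap_bounds <- function(d, n1, n2) {
  a <- max(1L, d + 1L)
  b <- min(n1, d + n2)
  c(a, b)
}

perfect_at <- function(raw1, raw2, d, n1, n2) {
  ab <- overlap_bounds(d, n1, n2)
  if (ab[2] < ab[1]) return(FALSE)
  identical(raw1[ab[1]:ab[2]], raw2[(ab[1] - d):(ab[2] - d)])
}

# Candidate offsets from probe seeding: any perfect overlap of length >= w
# whose right edge is min(n1, d + n2) must contain either s1's 3'-terminal
# w-mer (when the edge is n1) or r2's 3'-terminal w-mer (when it is d + n2).
candidate_offsets <- function(s1, r2, w = 12L) {
  n1 <- nchar(s1); n2 <- nchar(r2)
  d1 <- integer(); d2 <- integer()
  if (n1 >= w) {
    probe <- substr(s1, n1 - w + 1L, n1)
    d1 <- (n1 - w + 1L) - locate_fixed(r2, probe)
  }
  if (n2 >= w) {
    probe <- substr(r2, n2 - w + 1L, n2)
    d2 <- locate_fixed(s1, probe) - (n2 - w + 1L)
  }
  unique(c(d1, d2))
}

#' Anneal two single strands into a cohesive-ended duplex
#'
#' Slides the second strand against the first over all relative offsets and
#' pairs them at the maximal perfectly complementary core, which must be at
#' least `min_core` nt; unpaired extensions at either end are annotated as
#' overhangs (in this workflow both are 5' protrusions: the primer tails).
#' Partial complementarity within the core is an error, not a partial
#' duplex -- the simulation is deterministic.
#'
#' @param s1,s2 [strand_product()]s or plain strings, 5' to 3'. `s1` becomes
#'   the top strand of the duplex, `s2` the bottom strand.
#' @param min_core Minimum core length, nt.
#' @param id Label for the duplex.
#' @return A [sticky_duplex()].
#' @examples
#' d <- anneal("TTTTTAACGT", "CCCCCACGTT", min_core = 5)
#' d$left_overhang$seq   # "TTTTT"
#' d$right_overhang$seq  # "CCCCC"
#' @export
anneal <- function(s1, s2, min_core = 15L, id = "annealed") {
  b1 <- if (inherits(s1, "strand_product")) s1$bases else assert_dna(s1, "strand 1")
  b2 <- if (inherits(s2, "strand_product")) s2$bases else assert_dna(s2, "strand 2")
  r2 <- revcomp(b2)
  n1 <- nchar(b1); n2 <- nchar(r2)
  raw1 <- charToRaw(b1); raw2 <- charToRaw(r2)

  ds <- if (min_core >= 12L && min(n1, n2) > 64L) candidate_offsets(b1, r2)
        else seq.int(-(n2 - 1L), n1 - 1L)
  best_d <- NA_integer_; best_len <- -1L
  for (d in ds) {
    ab <- overlap_bounds(d, n1, n2)
    len <- ab[2] - ab[1] + 1L
    if (len < min_core || len <= best_len) next
    if (perfect_at(raw1, raw2, d, n1, n2)) { best_d <- d; best_len <- len }
  }
  if (is.na(best_d)) {
    # diagnose near-misses on small inputs: report mismatch positions of the
    # best imperfect alignment rather than a bare failure
    if (max(n1, n2) <= 2000L) {
      best_score <- -1L; mm <- integer(); at <- NA_integer_
      for (d in seq.int(-(n2 - 1L), n1 - 1L)) {
        ab <- overlap_bounds(d, n1, n2)
        len <- ab[2] - ab[1] + 1L
        if (len < min_core) next
        idx <- ab[1]:ab[2]
        ok <- raw1[idx] == raw2[idx - d]
        if (sum(ok) > best_score) { best_score <- sum(ok); mm <- idx[!ok]; at <- d }
      }
      if (!is.na(at) && length(mm) && best_score >= min_core * 0.8)
        stop_mrf("mismatch",
                 sprintf("strands share a near-complementary core but mismatch at top-strand positions %s",
                         paste(mm, collapse = ", ")), positions = mm)
    }
    stop_mrf("annealing_failure",
             sprintf("no perfectly complementary core of >= %d nt between the strands",
                     min_core))
  }
  d <- best_d
  e <- (d + n2) - n1
  left <- if (d > 0L) end_record(substr(b1, 1L, d), "top", "5p", "left")
          else if (d < 0L) end_record(substr(b2, n2 + d + 1L, n2), "bottom", "3p", "left")
          else end_record("", "top", "5p", "left")
  right <- if (e > 0L) end_record(substr(b2, 1L, e), "bottom", "5p", "right")
           else if (e < 0L) end_record(substr(b1, n1 + e + 1L, n1), "top", "3p", "right")
           else end_record("", "bottom", "5p", "right")
  sticky_duplex(b1, b2, left, right, id = id)
}
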