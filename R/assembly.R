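# Cohesive-end compatibility and ligation into the final circular construct,
# plus the in-silico analogues of the bench verification steps: sequence
# identity against the reference splice (the stand-in for junction
# sequencing) and predicted fragment sizes (the stand-in for gel bands).

#' Are two cohesive ends compatible for ligation?
#'
#' Two ends ligate when both are 5' protrusions of equal, nonzero length
#' whose sequences are reverse complements and which sit on opposite strands
#' once the fragments are juxtaposed (upstream fragment's right end against
#' downstream fragment's left end; a fragment contributing the "wrong" side
#' is flipped, which swaps its strand annotation).
#'
#' @param e1,e2 End records (`left_overhang`/`right_overhang` of a
#'   [sticky_duplex()]): `e1` the right end of the upstream fragment, `e2`
#'   the left end of the downstream fragment.
#' @return `TRUE` or `FALSE`.
#' @export
ends_compatible <- function(e1, e2) {
  flip_strand <- function(s) if (s == "top") "bottom" else "top"
  s1 <- e1$strand; s2 <- e2$strand
  if (!is.null(e1$side) && identical(e1$side, "left")) s1 <- flip_strand(s1)
  if (!is.null(e2$side) && identical(e2$side, "right")) s2 <- flip_strand(s2)
  e1$length > 0L && e2$length > 0L &&
    identical(e1$end, "5p") && identical(e2$end, "5p") &&
    e1$length == e2$length &&
    s1 != s2 &&
    identical(e1$seq, revcomp(e2$seq))
}

new_construct <- function(seq, junctions, provenance, self_circle = FALSE) {
  structure(list(seq = seq, junctions = junctions, provenance = provenance,
                 self_circle = self_circle),
            class = "construct")
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("<construct> %s: %d bp circular (ligated from %s)%s\n",
              x$seq$id, seq_length(x$seq),
              paste(x$provenance, collapse = " + "),
              if (x$self_circle) "  [WARNING: self-circularization]" else ""))
  for (j in x$junctions)
    cat(sprintf("  junction at %d: overhang %s\n", j$position, j$overhang))
  invisible(x)
}

#' Ligate cohesive-ended fragments
#'
#' Joins `frag1`'s right end to `frag2`'s left end; with
#' `circularize = TRUE` also seals `frag2`'s right end to `frag1`'s left
#' end, producing the final circular construct (nick-sealing is implicit).
#' Any incompatible junction -- including blunt ends, which the cohesive-only
#' policy refuses -- raises a ligation error naming both overhangs. Called
#' with a single self-compatible fragment, the self-circularization product
#' is returned flagged with `self_circle = TRUE`.
#'
#' @param frag1,frag2 [sticky_duplex()] fragments; `frag2` may be omitted to
#'   test self-circularization of `frag1`.
#' @param circularize Close the product into a circle.
#' @param id Label for the product.
#' @return A `construct` (circular) or, with `circularize = FALSE`, the
#'   joined [sticky_duplex()].
#' @export
ligate <- function(frag1, frag2 = NULL, circularize = TRUE, id = "construct") {
  lig_err <- function(junction, ea, eb)
    stop_mrf("ligation",
             sprintf("incompatible ends at %s: %s vs %s", junction,
                     if (ea$length) ea$seq else "(blunt)",
                     if (eb$length) eb$seq else "(blunt)"))
  if (is.null(frag2)) {
    if (!circularize)
      stop_mrf("argument", "a single fragment can only be self-circularized")
    if (!ends_compatible(frag1$right_overhang, frag1$left_overhang))
      lig_err("self-circularization", frag1$right_overhang, frag1$left_overhang)
    seq <- nuc_seq(frag1$top, id = id, topology = "circular")
    return(new_construct(seq,
                         list(list(position = 1L,
                                   overhang = frag1$left_overhang$seq)),
                         frag1$id, self_circle = TRUE))
  }
  if (!ends_compatible(frag1$right_overhang, frag2$left_overhang))
    lig_err(sprintf("%s/%s", frag1$id, frag2$id),
            frag1$right_overhang, frag2$left_overhang)
  if (circularize) {
    if (!ends_compatible(frag2$right_overhang, frag1$left_overhang))
      lig_err(sprintf("%s/%s (closing)", frag2$id, frag1$id),
              frag2$right_overhang, frag1$left_overhang)
    top <- paste0(frag1$top, frag2$top)
    seq <- nuc_seq(top, id = id, topology = "circular")
    junctions <- list(
      list(position = nchar(frag1$top) + 1L,
           overhang = frag2$left_overhang$seq),
      list(position = 1L, overhang = frag1$left_overhang$seq))
    return(new_construct(seq, junctions, c(frag1$id, frag2$id)))
  }
  sticky_duplex(paste0(frag1$top, frag2$top),
                paste0(frag2$bottom, frag1$bottom),
                frag1$left_overhang, frag2$right_overhang,
                id = id)
}

#' Verify a construct against its cloning job
#'
#' The in-silico analogue of the bench verification: (1) identity of the
#' construct versus the reference splice, compared rotation- and
#' strand-flip-invariantly (a ligated circle has no origin or top strand);
#' (2) a match/mismatch call per junction with a +/-30 bp sequence excerpt
#' around it, the stand-in for junction sequencing traces; (3) the expected
#' colony-PCR product size for a forward primer annealing to the retained
#' vector backbone and a reverse primer annealing inside the insert, with
#' the parental empty vector as negative control (no product expected).
#'
#' @param construct A `construct`, or a circular [nuc_seq()].
#' @param job The [cloning_job()] the construct should realize.
#' @param colony_upstream How far upstream of junction A (bp) the colony-PCR
#'   forward primer anneals on the backbone.
#' @param colony_insert_at Insert coordinate (bp) at which the colony-PCR
#'   reverse primer ends.
#' @return A report of class `mrf_verification`: fields `identical`,
#'   `insert_found` (`"forward"`, `"reverse"`, `"absent"`), `junction_a`,
#'   `junction_b` (each `match` + `excerpt`), `colony_pcr` (`product_bp` or
#'   `NA`, primers, `negative_control_bp`), and the lengths involved.
#' @export
verify_construct <- function(construct, job,
                             colony_upstream = 100L, colony_insert_at = 200L) {
  cs <- if (inherits(construct, "construct")) construct$seq else as_nuc_seq(construct)
  if (!is_circular(cs)) cs <- nuc_seq(cs$bases, cs$id, "circular")
  ref <- reference_splice(job)
  ov <- extract_overhangs(job, relax = TRUE)
  ins <- job$insert$bases
  ins_len <- nchar(ins)
  identical_flag <- circular_equal(cs, ref, flip = TRUE)

  doubled <- paste0(cs$bases, cs$bases)
  flipped <- revcomp(cs$bases)
  probe_len <- min(25L, ins_len)
  find_either <- function(pat) {
    if (grepl(pat, doubled, fixed = TRUE)) return("forward")
    if (grepl(pat, paste0(flipped, flipped), fixed = TRUE)) return("reverse")
    "absent"
  }
  insert_found <- find_either(substr(ins, 1L, probe_len))

  junction_report <- function(pat, junction_offset) {
    # junction_offset: position of the junction's first construct base within
    # the pattern hit
    hit <- locate_fixed(doubled, pat)
    hit <- hit[hit <= seq_length(cs)]
    if (length(hit)) {
      jpos <- cidx(hit[1] + junction_offset, seq_length(cs))
      excerpt <- circ_sub(cs$bases, jpos - 30L, min(60L, seq_length(cs)))
      list(match = TRUE, position = jpos, excerpt = excerpt)
    } else {
      list(match = FALSE, position = NA_integer_, excerpt = NA_character_)
    }
  }
  pat_a <- paste0(ov$a$seq, substr(ins, 1L, probe_len))
  pat_b <- paste0(substr(ins, max(1L, ins_len - probe_len + 1L), ins_len), ov$b$seq)
  ja <- junction_report(pat_a, job$k)  # junction A sits after the overhang-A bases
  jb <- junction_report(pat_b, nchar(pat_b) - job$k)

  # colony PCR: forward primer on retained backbone upstream of junction A,
  # reverse primer inside the insert
  L <- seq_length(job$vector)
  up <- max(0L, min(colony_upstream, job$retained_len - 2L * job$k - 25L))
  fwd_body <- circ_sub(job$vector$bases, job$junction_a - job$k - up - 19L, 20L)
  rev_at <- min(colony_insert_at, ins_len)
  rev_len <- min(20L, rev_at)
  rev_body <- revcomp(substr(ins, rev_at - rev_len + 1L, rev_at))
  fwd <- oligo("colony-fwd", 1L, "forward", fwd_body)
  rev <- oligo("colony-rev", 2L, "reverse", rev_body)
  size_on <- function(template) {
    tryCatch(nchar(pcr_amplify(template, fwd, rev)$top),
             mrf_error = function(e) NA_integer_)
  }
  structure(list(
    identical = identical_flag,
    insert_found = insert_found,
    junction_a = ja, junction_b = jb,
    colony_pcr = list(product_bp = size_on(cs),
                      fwd = fwd_body, rev = rev_body,
                      negative_control_bp = size_on(job$vector)),
    construct_bp = seq_length(cs),
    expected_bp = seq_length(ref)
  ), class = "mrf_verification")
}

#' @export
print.mrf_verification <- function(x, ...) {
  cat(sprintf("<verification> identity: %s (%d bp observed / %d bp expected)\n",
              if (x$identical) "PASS" else "FAIL", x$construct_bp, x$expected_bp))
  cat(sprintf("  insert orientation: %s\n", x$insert_found))
  for (side in c("a", "b")) {
    j <- x[[paste0("junction_", side)]]
    cat(sprintf("  junction %s: %s%s\n", toupper(side),
                if (j$match) "match" else "MISMATCH",
                if (j$match) paste0("  ...", j$excerpt, "...") else ""))
  }
  cat(sprintf("  colony PCR product: %s bp (empty-vector control: %s)\n",
              ifelse(is.na(x$colony_pcr$product_bp), "absent",
                     x$colony_pcr$product_bp),
              ifelse(is.na(x$colony_pcr$negative_control_bp), "absent",
                     x$colony_pcr$negative_control_bp)))
  invisible(x)
}

#' Predicted electrophoresis band sizes
#'
#' Sequence lengths of simulated species, for comparison against expected gel
#' bands. Sticky duplexes report both strand lengths and the total duplex
#' span; circular constructs report the circle length (open/closed mobility
#' is not modelled).
#'
#' @param ... Simulated products ([amplicon_duplex()], [strand_product()],
#'   [sticky_duplex()], `construct`, [nuc_seq()]), or a single list of them.
#' @return A data frame with columns `label`, `species`, `length_bp`.
#' @export
predicted_band_sizes <- function(...) {
  prods <- list(...)
  if (length(prods) == 1L && is.list(prods[[1]]) && is.null(attr(prods[[1]], "class")))
    prods <- prods[[1]]
  rows <- lapply(prods, function(p) {
    if (inherits(p, "amplicon_duplex"))
      data.frame(label = p$id, species = "blunt duplex", length_bp = nchar(p$top))
    else if (inherits(p, "strand_product"))
      data.frame(label = p$label, species = "single strand", length_bp = nchar(p$bases))
    else if (inherits(p, "sticky_duplex"))
      data.frame(label = p$id,
                 species = c("top strand", "bottom strand", "duplex span"),
                 length_bp = c(nchar(p$top), nchar(p$bottom), duplex_span(p)))
    else if (inherits(p, "construct"))
      data.frame(label = p$seq$id, species = "circular construct",
                 length_bp = seq_length(p$seq))
    else if (inherits(p, "nuc_seq"))
      data.frame(label = p$id, species = p$topology, length_bp = seq_length(p))
    else stop_mrf("argument", "unsupported product type for band-size prediction")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
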