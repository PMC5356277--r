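# A cloning job is the design problem statement: replace the vector interval
# strictly between junction A and junction B (the "stuffer") with the insert.
# The k bases immediately before/at junction A and at/after junction B are
# retained vector sequence and become the cohesive overhangs, so junctions are
# always flanked by vector-derived sequence and the final construct is
# seamless by construction.

#' Cohesive overhang region
#'
#' A k-base vector-derived region flanking a junction, read on the construct
#' top strand: side A is the k bases immediately before junction A (ending at
#' the junction), side B the k bases starting at junction B.
#'
#' @param seq Overhang sequence (vector-derived, top strand).
#' @param side `"A"` or `"B"`.
#' @param relax Permit lengths outside the default 5-8 nt policy.
#' @return An object of class `overhang`.
#' @export
overhang <- function(seq, side = c("A", "B"), relax = FALSE) {
  side <- match.arg(side)
  seq <- assert_dna(seq, "overhang")
  k <- nchar(seq)
  if (!relax && (k < 5L || k > 8L))
    stop_mrf("argument",
             sprintf("overhang length %d outside the 5-8 nt policy (set relax to override)", k))
  if (grepl("N", seq, fixed = TRUE))
    stop_mrf("alphabet", "overhang region contains ambiguous base N")
  structure(list(seq = seq, length = k, side = side), class = "overhang")
}

#' Define a cloning job
#'
#' Resolves both insertion sites on the vector and packages the replacement
#' problem: the insert replaces the vector bases strictly between junction A
#' and junction B (walking forward from A to B, wrapping the origin on
#' circular vectors). Anchor-mode sites are converted to junctions using the
#' `anchor_junction_*` convention in `config` (default: junction A is the
#' last base of the upstream anchor, junction B the first base of the
#' downstream anchor).
#'
#' @param vector Circular [nuc_seq()] (the acceptor plasmid).
#' @param insert Linear [nuc_seq()] (the gene of interest).
#' @param site_a,site_b Insertion sites: coordinates, anchor strings, or
#'   [site_spec()] objects.
#' @param k Overhang length, nt (default from `config`).
#' @param config An [mrf_config()] list.
#' @return An object of class `cloning_job` with resolved junctions, the
#'   stuffer sequence, and k.
#' @examples
#' v <- nuc_seq("AAAAATTTTTCCCCCGGGGG", id = "toyvec", topology = "circular")
#' ins <- nuc_seq("AACGT", id = "toygene")
#' job <- cloning_job(v, ins, site_a = 10, site_b = 16, k = 5)
#' job$stuffer  # "CCCCC"
#' @export
cloning_job <- function(vector, insert, site_a, site_b,
                        k = config$k, config = mrf_config()) {
  vector <- as_nuc_seq(vector)
  insert <- as_nuc_seq(insert)
  if (!is_circular(vector))
    stop_mrf("argument", "the acceptor vector must be circular")
  if (is_circular(insert))
    stop_mrf("argument", "the insert must be linear")
  k <- as.integer(k)
  if (!config$relax_overhang_length && (k < 5L || k > 8L))
    stop_mrf("argument", sprintf("k = %d outside the 5-8 nt overhang policy", k))
  L <- seq_length(vector)

  resolve_junction <- function(site, which) {
    spec <- as_site_spec(site)
    pos <- as.integer(resolve_site(vector, spec, both_strands = config$both_strand_anchor))
    if (spec$mode == "anchor") {
      conv <- if (which == "A") config$anchor_junction_a else config$anchor_junction_b
      if (conv == "end") pos <- cidx(pos + nchar(spec$anchor) - 1L, L)
    }
    pos
  }
  jA <- resolve_junction(site_a, "A")
  jB <- resolve_junction(site_b, "B")
  if (jA == jB)
    stop_mrf("geometry", "junction A and junction B resolve to the same position")

  stuffer_len <- (jB - jA - 1L) %% L
  retained <- L - stuffer_len
  job <- structure(list(
    vector = vector, insert = insert,
    junction_a = jA, junction_b = jB,
    k = k,
    stuffer = circ_sub(vector$bases, jA + 1L, stuffer_len),
    stuffer_len = stuffer_len,
    retained_len = retained
  ), class = "cloning_job")
  # overhang geometry is validated eagerly so malformed jobs fail here
  extract_overhangs(job, relax = config$relax_overhang_length)
  job
}

#' @export
print.cloning_job <- function(x, ...) {
  cat(sprintf(paste0("<cloning_job> replace %d bp stuffer of '%s' (%d bp, circular)\n",
                     "  between junction A = %d and junction B = %d (k = %d)\n",
                     "  with insert '%s' (%d bp); construct will be %d bp\n"),
              x$stuffer_len, x$vector$id, seq_length(x$vector),
              x$junction_a, x$junction_b, x$k,
              x$insert$id, seq_length(x$insert),
              construct_length(x)))
  invisible(x)
}

#' @rdname cloning_job
#' @param job A `cloning_job`.
#' @export
construct_length <- function(job) {
  seq_length(job$vector) - job$stuffer_len + seq_length(job$insert)
}

#' Extract the two cohesive overhang regions of a job
#'
#' Side A is vector bases `[A-k+1 .. A]`, side B is `[B .. B+k-1]`, both on
#' the top strand with circular wrap. The two regions and the stuffer must be
#' pairwise disjoint; otherwise a geometry error is raised.
#'
#' @param job A [cloning_job()].
#' @param relax Permit k outside 5-8 nt.
#' @return A list with elements `a` and `b`, each an [overhang()].
#' @export
extract_overhangs <- function(job, relax = FALSE) {
  k <- job$k
  if (job$retained_len < 2L * k)
    stop_mrf("geometry",
             sprintf(paste0("overhang regions collide: retained vector is %d bp ",
                            "but 2k = %d bp is needed"), job$retained_len, 2L * k))
  a <- circ_sub(job$vector$bases, job$junction_a - k + 1L, k)
  b <- circ_sub(job$vector$bases, job$junction_b, k)
  list(a = overhang(a, "A", relax = relax),
       b = overhang(b, "B", relax = relax))
}

#' Reference splice: the ground-truth construct
#'
#' The construct obtained by directly replacing the stuffer with the insert
#' in the vector sequence. The MRF simulation must reproduce this circle
#' (up to rotation) -- it is the in-silico analogue of a verified clone.
#'
#' @param job A [cloning_job()].
#' @return A circular [nuc_seq()], linearized starting at junction B.
#' @export
reference_splice <- function(job) {
  retained <- circ_sub(job$vector$bases, job$junction_b, job$retained_len)
  nuc_seq(paste0(retained, job$insert$bases),
          id = paste0(job$vector$id, "-", job$insert$id),
          topology = "circular")
}
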