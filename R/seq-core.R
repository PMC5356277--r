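#' @keywords internal
"_PACKAGE"

# Structured conditions: every error raised by the package carries class
# c("mrf_<kind>_error", "mrf_error") so callers (and the CLI) can dispatch.
stop_mrf <- function(kind, msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c(paste0("mrf_", kind, "_error"), "mrf_error")))
}

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_mrf("alphabet", sprintf("%s must be a single character string", what))
  x <- toupper(x)
  if (nchar(x) == 0L)
    stop_mrf("alphabet", sprintf("%s is empty", what))
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L)
    stop_mrf("alphabet",
             sprintf("%s contains non-DNA characters: %s", what,
                     paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  x
}

#' Reverse complement of a DNA string
#'
#' @param seq A DNA string over the alphabet A, C, G, T, N (case-insensitive).
#' @return The reverse complement, uppercase, as a character string.
#' @examples
#' revcomp("GATTACA")  # "TGTAATC"
#' @export
revcomp <- function(seq) {
  seq <- assert_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' DNA sequence with topology
#'
#' The universal sequence currency of the package: an uppercase DNA string
#' together with a short identifier and a topology flag. Circular sequences
#' support index arithmetic modulo their length (slices wrap across the
#' origin); linear sequences reject out-of-range access.
#'
#' @param bases DNA string over A, C, G, T, N; case-normalized on construction.
#' @param id Short text label.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `nuc_seq`.
#' @examples
#' v <- nuc_seq("AAAAATTTTTCCCCCGGGGG", id = "toyvec", topology = "circular")
#' seq_length(v)
#' @export
nuc_seq <- function(bases, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  bases <- assert_dna(bases, sprintf("sequence '%s'", id))
  structure(list(id = as.character(id), bases = bases, topology = topology),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$bases)
  shown <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<nuc_seq> %s: %d bp, %s\n  %s\n", x$id, n, x$topology, shown))
  invisible(x)
}

#' @rdname nuc_seq
#' @param x A `nuc_seq`.
#' @export
seq_length <- function(x) nchar(x$bases)

#' @rdname nuc_seq
#' @export
is_circular <- function(x) identical(x$topology, "circular")

as_nuc_seq <- function(x, id = "seq", topology = "linear") {
  if (inherits(x, "nuc_seq")) x else nuc_seq(x, id = id, topology = topology)
}

# 1-based index modulo length
cidx <- function(i, L) ((as.integer(i) - 1L) %% L) + 1L

# Circular substring: always defined for 0 <= len <= L, wrapping the origin.
circ_sub <- function(bases, start, len) {
  L <- nchar(bases)
  if (len == 0L) return("")
  if (len > L) stop_mrf("bounds", "requested slice longer than the sequence")
  start <- cidx(start, L)
  end <- start + len - 1L
  if (end <= L) substr(bases, start, end)
  else paste0(substr(bases, start, L), substr(bases, 1, end - L))
}

#' Extract a subsequence honoring topology
#'
#' Circular sequences wrap across the origin; linear sequences raise a bounds
#' error for out-of-range access.
#'
#' @param x A [nuc_seq()].
#' @param start 1-based start.
#' @param len Slice length in bases.
#' @return A character string of length `len`.
#' @export
seq_sub <- function(x, start, len) {
  x <- as_nuc_seq(x)
  L <- seq_length(x)
  len <- as.integer(len)
  if (len < 0L) stop_mrf("bounds", "negative slice length")
  if (is_circular(x)) return(circ_sub(x$bases, start, len))
  start <- as.integer(start)
  if (start < 1L || len > 0L && start + len - 1L > L)
    stop_mrf("bounds",
             sprintf("slice [%d..%d] out of range for linear sequence '%s' (%d bp)",
                     start, start + len - 1L, x$id, L))
  substr(x$bases, start, start + len - 1L)
}

# All 1-based start positions of `pattern` in `subject` (plain string),
# overlapping occurrences included.
locate_fixed <- function(subject, pattern) {
  out <- integer()
  from <- 1L
  n <- nchar(subject)
  np <- nchar(pattern)
  if (np == 0L || np > n) return(out)
  while (from <= n - np + 1L) {
    hit <- regexpr(pattern, substr(subject, from, n), fixed = TRUE)
    if (hit < 0L) break
    pos <- from + as.integer(hit) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

# Occurrences of `pattern` on the top strand of a nuc_seq; circular search
# wraps across the origin (starts reported in 1..L).
locate_matches <- function(x, pattern, circular = is_circular(x)) {
  x <- as_nuc_seq(x)
  L <- seq_length(x)
  np <- nchar(pattern)
  subject <- if (circular && np > 1L)
    paste0(x$bases, substr(x$bases, 1, min(np - 1L, L))) else x$bases
  hits <- locate_fixed(subject, pattern)
  hits[hits <= L]
}

#' Rotation-invariant (and optionally strand-flip-invariant) circle identity
#'
#' Two circular sequences are the same molecule if one is a rotation of the
#' other; a ligated circle has no defined origin. With `flip = TRUE` the
#' reverse complement is also accepted, since a double-stranded circle has no
#' defined top strand either.
#'
#' @param a,b `nuc_seq` objects or plain strings, interpreted as circles.
#' @param flip Also accept the reverse complement of `b`.
#' @return `TRUE` or `FALSE`.
#' @export
circular_equal <- function(a, b, flip = FALSE) {
  sa <- if (inherits(a, "nuc_seq")) a$bases else assert_dna(a)
  sb <- if (inherits(b, "nuc_seq")) b$bases else assert_dna(b)
  if (nchar(sa) != nchar(sb)) return(FALSE)
  doubled <- paste0(sa, sa)
  grepl(sb, doubled, fixed = TRUE) ||
    (flip && grepl(revcomp(sb), doubled, fixed = TRUE))
}
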