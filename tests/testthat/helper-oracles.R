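# Independent oracles, deliberately sharing no code with the package:
# complementation is done with a lookup table, reverse complement by
# character reversal, searches by exhaustive scanning.

COMP <- c(A = "T", T = "A", G = "C", C = "G", N = "N")

oracle_revcomp <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(COMP[chars])), collapse = "")
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Exhaustive scan of all substring start positions (circular via doubling).
oracle_find_all <- function(subject, pattern, circular = FALSE) {
  L <- nchar(subject)
  s <- if (circular) paste0(subject, subject) else subject
  np <- nchar(pattern)
  lim <- if (circular) L else L - np + 1L
  hits <- integer()
  for (i in seq_len(max(0L, lim)))
    if (substr(s, i, i + np - 1L) == pattern) hits <- c(hits, i)
  hits
}

# Brute-force annealing: slide s2 against s1 over every offset, demanding a
# perfect Watson-Crick paired overlap; report the maximal one with its
# unpaired 5' extensions. s1 position j pairs s2 position n2 + 1 - (j - d).
oracle_anneal <- function(s1, s2, min_core = 15L) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  n1 <- length(c1); n2 <- length(c2)
  best <- NULL
  for (d in seq.int(-(n2 - 1L), n1 - 1L)) {
    a <- max(1L, d + 1L); b <- min(n1, d + n2)
    len <- b - a + 1L
    if (len < min_core) next
    ok <- TRUE
    for (j in a:b) {
      if (COMP[[c1[j]]] != c2[n2 + 1L - (j - d)]) { ok <- FALSE; break }
    }
    if (ok && (is.null(best) || len > best$core)) {
      e <- (d + n2) - n1
      best <- list(
        d = d, core = len,
        left_seq = if (d > 0L) substr(s1, 1L, d) else "",
        left_strand = "top",
        right_seq = if (e > 0L) substr(s2, 1L, e) else "",
        right_strand = "bottom")
    }
  }
  best
}

# Doubled-string PCR oracle for circular templates.
oracle_pcr_circular <- function(template, fwd_body, rev_body,
                                fwd_tail = "", rev_tail = "") {
  L <- nchar(template)
  f <- oracle_find_all(template, fwd_body, circular = TRUE)
  r <- oracle_find_all(template, oracle_revcomp(rev_body), circular = TRUE)
  if (length(f) != 1L || length(r) != 1L) return(NULL)
  r_end <- r[1] + nchar(rev_body) - 1L
  span <- ((r_end - f[1]) %% L) + 1L
  seg <- substr(paste0(template, template), f[1], f[1] + span - 1L)
  paste0(fwd_tail, seg, if (nzchar(rev_tail)) oracle_revcomp(rev_tail) else "")
}

# Ground-truth splice: replace the vector interval strictly between A and B
# with the insert (stuffer may wrap the origin).
oracle_splice <- function(vector_str, A, B, insert_str) {
  L <- nchar(vector_str)
  retained <- if (B <= A) substr(vector_str, B, A)
              else paste0(substr(vector_str, B, L), substr(vector_str, 1, A))
  paste0(retained, insert_str)
}

# Rotation equality of two circles, by doubling.
oracle_rot_equal <- function(a, b) {
  nchar(a) == nchar(b) && grepl(b, paste0(a, a), fixed = TRUE)
}

# Shared toy fixture: 20 bp circular vector, 5 bp insert, k = 5, junctions
# 10/16 so the stuffer is CCCCC and the overhangs TTTTT / GGGGG.
toy_config <- function() {
  mrf_config(k = 5, body_target = 5, body_window = c(5, 5), min_core = 5)
}

toy_job <- function() {
  v <- nuc_seq("AAAAATTTTTCCCCCGGGGG", id = "toyvec", topology = "circular")
  ins <- nuc_seq("AACGT", id = "toygene")
  cloning_job(v, ins, 10, 16, k = 5, config = toy_config())
}
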