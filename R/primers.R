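# The eight-primer set. Per fragment (insert and vector) there are a plain
# forward/reverse pair for the regular double-primer PCR and a tailed pair,
# identical except for a 5' tail, for the two single-primer linear PCRs. Tail
# assignment is fixed by the seamless-junction requirement: each junction
# overhang must end up as complementary 5' protrusions on the two fragments,
# which forces
#   insert fwd tail = overhang A        insert rev tail = revcomp(overhang B)
#   vector fwd tail = overhang B        vector rev tail = revcomp(overhang A)
# (the unique assignment, up to a global fragment swap, for which ligation
# reconstitutes the reference splice exactly).

#' A PCR oligo with body/tail decomposition
#'
#' @param name Oligo name.
#' @param role Integer 1-8 (1-4 insert primers, 5-8 vector primers; odd =
#'   forward, even = reverse; 3,4,7,8 carry tails).
#' @param direction `"forward"` or `"reverse"`.
#' @param body Template-homologous part, 5' to 3'.
#' @param tail 5' tail (possibly empty); the full sequence is `tail + body`.
#' @param tm_body Melting temperature of the body, Celsius.
#' @param warnings Character vector of design-rule warnings.
#' @return An object of class `oligo`.
#' @export
oligo <- function(name, role, direction = c("forward", "reverse"),
                  body, tail = "", tm_body = NA_real_, warnings = character()) {
  direction <- match.arg(direction)
  body <- assert_dna(body, sprintf("body of %s", name))
  if (grepl("N", body, fixed = TRUE))
    stop_mrf("alphabet", sprintf("primer body of %s contains ambiguous base N", name))
  if (nzchar(tail)) tail <- assert_dna(tail, sprintf("tail of %s", name))
  structure(list(name = as.character(name), role = as.integer(role),
                 direction = direction, body = body, tail = tail,
                 tm_body = tm_body, warnings = warnings),
            class = "oligo")
}

#' @rdname oligo
#' @param x An `oligo`.
#' @export
oligo_seq <- function(x) paste0(x$tail, x$body)

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s (role %d, %s): 5'-%s%s-3'  Tm(body) %.1f C%s\n",
              x$name, x$role, x$direction,
              if (nzchar(x$tail)) paste0("[", x$tail, "]") else "", x$body,
              x$tm_body,
              if (length(x$warnings)) paste0("  [", paste(x$warnings, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Select a primer homology body
#'
#' The body starts at the junction and is extended or trimmed within the
#' length window so that the 3'-terminal base is G or C (the only terminus a
#' length change can move); among qualifying lengths the one closest to
#' `target_len` wins, ties going to the shorter. If no length in the window
#' qualifies, the best-effort body at the target length is returned with a
#' rule-violation warning attached (attribute `"warnings"`), never silently.
#'
#' @param template A [nuc_seq()].
#' @param junction 1-based coordinate: for `"forward"`, the first template
#'   base of the body; for `"reverse"`, the last template base covered (the
#'   body is the reverse complement ending 3' at the complement of
#'   `template[junction - len + 1]`).
#' @param direction `"forward"` or `"reverse"`.
#' @param target_len,window Target body length and allowed `c(min, max)`.
#' @return The body as a character string, with a `"warnings"` attribute.
#' @export
select_body <- function(template, junction, direction = c("forward", "reverse"),
                        target_len = 25L, window = c(20L, 32L)) {
  direction <- match.arg(direction)
  template <- as_nuc_seq(template)
  lens <- seq.int(window[1], window[2])
  grab <- function(len) {
    out <- tryCatch({
      if (direction == "forward") seq_sub(template, junction, len)
      else revcomp(seq_sub(template, junction - len + 1L, len))
    }, mrf_bounds_error = function(e) NULL)
    if (!is.null(out) && grepl("N", out, fixed = TRUE)) out <- NULL
    out
  }
  bodies <- lapply(lens, grab)
  avail <- !vapply(bodies, is.null, logical(1))
  if (!any(avail))
    stop_mrf("length",
             sprintf("template '%s' cannot supply a %d-%d nt body at position %d",
                     template$id, window[1], window[2], junction))
  # preference order: |len - target| ascending, shorter first on ties
  ord <- order(abs(lens - target_len), lens)
  gc_ok <- function(b) substr(b, nchar(b), nchar(b)) %in% c("G", "C")
  for (i in ord) {
    if (avail[i] && gc_ok(bodies[[i]]))
      return(structure(bodies[[i]], warnings = character()))
  }
  best <- ord[avail[ord]][1]
  structure(bodies[[best]],
            warnings = sprintf("gc_3prime: no body length in %d-%d ends in G/C",
                               window[1], window[2]))
}

#' Advisory checks on a pair of cohesive overhangs
#'
#' Flags design risks that undermine cohesive-end specificity: identical A/B
#' overhangs (the insert could go in reversed), self-complementary
#' (palindromic) overhangs (fragment self-ligation), and homopolymer
#' overhangs (annealing slippage; annotation only). Advisory -- never an
#' error.
#'
#' @param ov_a,ov_b [overhang()] objects (or plain strings).
#' @return A data frame with columns `code`, `side`, `message`; zero rows
#'   when nothing is flagged.
#' @export
validate_overhangs <- function(ov_a, ov_b) {
  sa <- if (inherits(ov_a, "overhang")) ov_a$seq else assert_dna(ov_a)
  sb <- if (inherits(ov_b, "overhang")) ov_b$seq else assert_dna(ov_b)
  out <- list()
  add <- function(code, side, message)
    out[[length(out) + 1L]] <<- data.frame(code = code, side = side,
                                           message = message)
  if (identical(sa, sb))
    add("identical_overhangs", "AB",
        sprintf("overhangs A and B are identical (%s): reversed-insert ligation possible", sa))
  for (side in c("A", "B")) {
    s <- if (side == "A") sa else sb
    if (identical(s, revcomp(s)))
      add("palindromic_overhang", side,
          sprintf("overhang %s (%s) is self-complementary: self-ligation risk", side, s))
    if (length(unique(strsplit(s, "")[[1]])) == 1L)
      add("homopolymer_overhang", side,
          sprintf("overhang %s (%s) is a homopolymer: annealing slippage possible", side, s))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(code = character(), side = character(), message = character())
}

#' Design the full eight-primer set for a cloning job
#'
#' Builds the plain and tailed forward/reverse primers for both the insert
#' and the vector fragment. Plain bodies anchor exactly at the fragment
#' boundaries (insert ends; vector backbone core, which starts k bases after
#' junction B and ends k bases before junction A), so the simulated amplicons
#' are seamless by construction. Tails are the junction overhangs as
#' described above. Every oligo carries a body Tm; G/C-terminal-rule
#' violations and overhang advisories are aggregated on the returned set,
#' never dropped.
#'
#' @param job A [cloning_job()].
#' @param config An [mrf_config()]; controls body window/target and Tm model.
#' @return An object of class `primer_set`: named oligos
#'   `insert_fwd_plain` (1), `insert_rev_plain` (2), `insert_fwd_tailed` (3),
#'   `insert_rev_tailed` (4), `vector_fwd_plain` (5), `vector_rev_plain` (6),
#'   `vector_fwd_tailed` (7), `vector_rev_tailed` (8), plus `$overhangs` and
#'   a `$warnings` data frame.
#' @export
design_primer_set <- function(job, config = mrf_config()) {
  ov <- extract_overhangs(job, relax = config$relax_overhang_length)
  k <- job$k
  L <- seq_length(job$vector)
  ins_len <- seq_length(job$insert)

  body_ins_f <- select_body(job$insert, 1L, "forward",
                            config$body_target, config$body_window)
  body_ins_r <- select_body(job$insert, ins_len, "reverse",
                            config$body_target, config$body_window)
  body_vec_f <- select_body(job$vector, cidx(job$junction_b + k, L), "forward",
                            config$body_target, config$body_window)
  body_vec_r <- select_body(job$vector, cidx(job$junction_a - k, L), "reverse",
                            config$body_target, config$body_window)

  mk <- function(stem, idx, role, direction, body, tail = "") {
    warn <- attr(body, "warnings") %||% character()
    full_first <- substr(if (nzchar(tail)) tail else body, 1L, 1L)
    if (!full_first %in% c("G", "C"))
      warn <- c(warn, "gc_5prime: 5'-terminal base is not G/C")
    o <- oligo(name = paste0(stem, idx), role = role, direction = direction,
               body = as.character(body), tail = tail,
               tm_body = tryCatch(
                 melting_temp(as.character(body), method = config$tm_method),
                 mrf_error = function(e) NA_real_),
               warnings = warn)
    o
  }
  tails <- list(p3 = ov$a$seq, p4 = revcomp(ov$b$seq),
                p7 = ov$b$seq, p8 = revcomp(ov$a$seq))
  ins_id <- job$insert$id
  vec_id <- job$vector$id
  set <- list(
    insert_fwd_plain  = mk(ins_id, 1, 1L, "forward", body_ins_f),
    insert_rev_plain  = mk(ins_id, 2, 2L, "reverse", body_ins_r),
    insert_fwd_tailed = mk(ins_id, 3, 3L, "forward", body_ins_f, tails$p3),
    insert_rev_tailed = mk(ins_id, 4, 4L, "reverse", body_ins_r, tails$p4),
    vector_fwd_plain  = mk(vec_id, 1, 5L, "forward", body_vec_f),
    vector_rev_plain  = mk(vec_id, 2, 6L, "reverse", body_vec_r),
    vector_fwd_tailed = mk(vec_id, 3, 7L, "forward", body_vec_f, tails$p7),
    vector_rev_tailed = mk(vec_id, 4, 8L, "reverse", body_vec_r, tails$p8)
  )
  ov_warn <- validate_overhangs(ov$a, ov$b)
  oligo_warn <- do.call(rbind, lapply(set, function(o) {
    if (!length(o$warnings)) return(NULL)
    data.frame(code = sub(":.*$", "", o$warnings), side = o$name,
               message = o$warnings)
  }))
  structure(list(oligos = set, overhangs = ov,
                 warnings = rbind(ov_warn, oligo_warn)),
            class = "primer_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.primer_set <- function(x, ...) {
  cat("<primer_set> 8 oligos (roles 1-8)\n")
  for (o in x$oligos) print(o)
  if (nrow(x$warnings))
    cat(sprintf("warnings: %s\n", paste(unique(x$warnings$code), collapse = ", ")))
  invisible(x)
}

#' Tabulate a primer set
#'
#' @param ps A `primer_set` from [design_primer_set()].
#' @return A data frame with columns `name`, `role`, `direction`,
#'   `sequence` (5' to 3'), `body_len`, `tail`, `tm_body`, `warnings`.
#' @export
primer_table <- function(ps) {
  do.call(rbind, lapply(ps$oligos, function(o) {
    data.frame(name = o$name, role = o$role, direction = o$direction,
               sequence = oligo_seq(o), body_len = nchar(o$body),
               tail = o$tail, tm_body = round(o$tm_body, 1),
               warnings = paste(o$warnings, collapse = "; "),
               row.names = NULL)
  }))
}

#' @rdname primer_table
#' @param path Output file path.
#' @export
write_primer_tsv <- function(ps, path) {
  utils::write.table(primer_table(ps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname primer_table
#' @export
write_oligo_fasta <- function(ps, path) {
  lines <- unlist(lapply(ps$oligos, function(o)
    c(sprintf(">%s role=%d %s", o$name, o$role, o$direction), oligo_seq(o))))
  writeLines(lines, path)
  invisible(path)
}
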