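# Sequence file I/O. FASTA goes through Biostrings; topology is encoded with
# the conventional "circular" keyword in the header. GenBank flat files are
# read minimally (LOCUS topology flag + ORIGIN block) and written with a
# small feature table -- enough to round-trip constructs and open them in
# standard plasmid viewers.

#' Read DNA sequences from FASTA
#'
#' Topology is taken from the header: a record whose description contains the
#' word `circular` is loaded as a circular sequence.
#'
#' @param path FASTA file path.
#' @return A list of [nuc_seq()] objects (one per record).
#' @export
read_dna_fasta <- function(path) {
  if (!file.exists(path)) stop_mrf("io", sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    topo <- if (grepl("\\bcircular\\b", header, ignore.case = TRUE))
      "circular" else "linear"
    nuc_seq(as.character(set[[i]]), id = id, topology = topo)
  })
}

#' @rdname read_dna_fasta
#' @param seqs A [nuc_seq()] or list of them.
#' @export
write_dna_fasta <- function(seqs, path) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    header <- paste0(">", s$id, if (is_circular(s)) " circular" else "")
    body <- substring(s$bases,
                      seq(1, nchar(s$bases), 70),
                      pmin(seq(1, nchar(s$bases), 70) + 69, nchar(s$bases)))
    c(header, body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Honors the LOCUS circular flag and the ORIGIN sequence block; features are
#' not parsed.
#'
#' @param path GenBank file path.
#' @return A [nuc_seq()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop_mrf("io", sprintf("file not found: %s", path))
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop_mrf("io", sprintf("%s: no LOCUS line", path))
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else "seq"
  topo <- if (any(grepl("circular", toks, ignore.case = TRUE)))
    "circular" else "linear"
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop_mrf("io", sprintf("%s: no ORIGIN block", path))
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > o[1]][1] else length(lines) + 1L
  seq_lines <- lines[seq.int(o[1] + 1L, end - 1L)]
  bases <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  nuc_seq(bases, id = id, topology = topo)
}

format_genbank_location <- function(start, end, L) {
  # circular features crossing the origin use the join() notation
  if (end <= L) sprintf("%d..%d", start, end)
  else sprintf("join(%d..%d,1..%d)", start, L, end - L)
}

#' Write a GenBank flat file
#'
#' @param x A [nuc_seq()] or `construct`.
#' @param path Output path.
#' @param features Optional list of features, each
#'   `list(type =, start =, end =, label =)` with 1-based inclusive
#'   coordinates (end may exceed the length for origin-crossing features).
#' @param definition DEFINITION line text.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path, features = list(), definition = "") {
  s <- if (inherits(x, "construct")) x$seq else as_nuc_seq(x)
  L <- seq_length(s)
  lines <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN",
            substr(s$id, 1, 17), L, s$topology),
    sprintf("DEFINITION  %s", if (nzchar(definition)) definition else s$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L))
  for (f in features) {
    lines <- c(lines,
               sprintf("     %-15s %s", f$type,
                       format_genbank_location(f$start, f$end, L)),
               sprintf("                     /label=\"%s\"", f$label))
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, L, 60)) {
    chunk <- substr(s$bases, i, min(i + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", i, tolower(paste(groups, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ligated construct as annotated GenBank
#'
#' Annotates the insert span, the two junction overhang regions, and the
#' retained backbone, located by exact search of the job's sequences in the
#' construct.
#'
#' @param construct A `construct` from [ligate()].
#' @param job The [cloning_job()] it realizes.
#' @param path Output path.
#' @export
write_construct_genbank <- function(construct, job, path) {
  s <- construct$seq
  L <- seq_length(s)
  doubled <- paste0(s$bases, s$bases)
  ov <- extract_overhangs(job, relax = TRUE)
  k <- job$k
  ins <- job$insert$bases
  features <- list()
  hit <- locate_fixed(doubled, paste0(ov$a$seq, ins, ov$b$seq))
  hit <- hit[hit <= L]
  if (length(hit)) {
    a0 <- hit[1]
    features <- list(
      list(type = "misc_feature", start = a0, end = a0 + k - 1L,
           label = "overhang A"),
      list(type = "CDS", start = a0 + k, end = a0 + k + nchar(ins) - 1L,
           label = job$insert$id),
      list(type = "misc_feature", start = a0 + k + nchar(ins),
           end = a0 + 2L * k + nchar(ins) - 1L, label = "overhang B"))
  }
  write_genbank(s, path, features = features,
                definition = sprintf("%s ligated into %s (MRF simulation)",
                                     job$insert$id, job$vector$id))
}

#' Serialize a verification report to JSON
#'
#' @param report An `mrf_verification` from [verify_construct()].
#' @param path Output path.
#' @export
write_verification_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
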