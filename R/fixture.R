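# Seeded synthetic vector/insert pairs. These stand in for the real inputs
# of the workflow (a plasmid plus a gene amplified from genomic DNA or cDNA)
# and carry their own ground truth, so every simulation on a fixture can be
# checked against the reference splice exactly.

random_dna <- function(n, gc_fraction = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc_fraction) / 2, (1 - gc_fraction) / 2,
                        gc_fraction / 2, gc_fraction / 2)),
        collapse = "")
}

#' Generate a seeded synthetic cloning fixture
#'
#' Draws a random circular vector with a designated stuffer, a random linear
#' insert, resolves the junctions, and precomputes the reference splice. The
#' overhang regions are redrawn (by regenerating the vector) until
#' [validate_overhangs()] reports no identical-overhang or palindromic
#' warnings, within a bounded retry budget. Identical seeds give identical
#' fixtures; the caller's RNG state is restored on exit.
#'
#' @param seed Integer seed.
#' @param vector_len,insert_len Lengths, bp (each at least `4 * k + 20`).
#' @param k Overhang length, nt.
#' @param gc_fraction GC content of the random sequences (0-1, exclusive).
#' @param max_tries Retry budget for the overhang redraw.
#' @return An object of class `fixture_job`: `seed`, `vector`, `insert`,
#'   `job`, `expected` (the reference splice), `k`, `gc_fraction`.
#' @examples
#' fx <- generate_fixture(seed = 42, vector_len = 3000, insert_len = 500)
#' fx$job
#' @export
generate_fixture <- function(seed, vector_len = 5000L, insert_len = 1000L,
                             k = 6L, gc_fraction = 0.5, max_tries = 100L) {
  vector_len <- as.integer(vector_len)
  insert_len <- as.integer(insert_len)
  k <- as.integer(k)
  if (vector_len < 4L * k + 20L || insert_len < 4L * k + 20L)
    stop_mrf("argument", sprintf("lengths must be at least 4k + 20 = %d bp",
                                 4L * k + 20L))
  if (!is.finite(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop_mrf("argument", "gc_fraction must be strictly between 0 and 1")

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  cfg <- mrf_config(k = k, relax_overhang_length = k < 5L || k > 8L)
  insert <- nuc_seq(random_dna(insert_len, gc_fraction),
                    id = sprintf("gene_s%d", as.integer(seed)))
  # the stuffer scales with the vector but always leaves room for the two
  # overhang regions and full-length primer bodies on the backbone core
  stuffer_len <- max(1L, min(vector_len %/% 4L,
                             vector_len - (2L * k + 2L * 33L + 10L)))
  for (try in seq_len(max_tries)) {
    vec <- nuc_seq(random_dna(vector_len, gc_fraction),
                   id = sprintf("plasmid_s%d", as.integer(seed)),
                   topology = "circular")
    jA <- sample.int(vector_len, 1L)
    jB <- cidx(jA + stuffer_len + 1L, vector_len)
    job <- tryCatch(cloning_job(vec, insert, jA, jB, k = k, config = cfg),
                    mrf_error = function(e) NULL)
    if (is.null(job)) next
    ov <- extract_overhangs(job, relax = cfg$relax_overhang_length)
    warn <- validate_overhangs(ov$a, ov$b)
    if (!any(warn$code %in% c("identical_overhangs", "palindromic_overhang"))) {
      return(structure(list(seed = as.integer(seed), vector = vec,
                            insert = insert, job = job,
                            expected = reference_splice(job),
                            k = k, gc_fraction = gc_fraction),
                       class = "fixture_job"))
    }
  }
  stop_mrf("generation",
           sprintf("could not draw ligation-safe overhangs in %d tries", max_tries))
}

#' @export
print.fixture_job <- function(x, ...) {
  cat(sprintf("<fixture_job> seed %d: vector %d bp, insert %d bp, k = %d, GC %.2f\n",
              x$seed, seq_length(x$vector), seq_length(x$insert), x$k,
              x$gc_fraction))
  print(x$job)
  invisible(x)
}

#' Write a fixture job to a directory
#'
#' Emits `vector.fasta`, `insert.fasta`, `expected.fasta` and a `job.yaml`
#' describing junctions, k, and the seed -- the file set the CLI `simulate`
#' and `verify` subcommands consume.
#'
#' @param fx A `fixture_job`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dna_fasta(fx$vector, file.path(dir, "vector.fasta"))
  write_dna_fasta(fx$insert, file.path(dir, "insert.fasta"))
  write_dna_fasta(fx$expected, file.path(dir, "expected.fasta"))
  yaml::write_yaml(list(seed = fx$seed, junction_a = fx$job$junction_a,
                        junction_b = fx$job$junction_b, k = fx$k,
                        gc_fraction = fx$gc_fraction),
                   file.path(dir, "job.yaml"))
  invisible(dir)
}

#' Reload a fixture directory as a cloning job
#'
#' @param dir Directory written by [write_fixture()].
#' @param config An [mrf_config()].
#' @return A [cloning_job()].
#' @export
read_fixture_job <- function(dir, config = mrf_config()) {
  meta <- yaml::read_yaml(file.path(dir, "job.yaml"))
  vec <- read_dna_fasta(file.path(dir, "vector.fasta"))[[1]]
  ins <- read_dna_fasta(file.path(dir, "insert.fasta"))[[1]]
  cloning_job(vec, ins, meta$junction_a, meta$junction_b, k = meta$k,
              config = config)
}
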