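#' Run the full MRF cloning simulation for a job
#'
#' Executes the whole workflow at sequence level: designs the eight-primer
#' set; amplifies the vector backbone ("fragment 1") and the insert
#' ("fragment 2") by double-primer PCR; runs the four single-primer linear
#' amplifications ("3-1"/"3-2" on the vector product, "4-1"/"4-2" on the
#' insert product); anneals each pair into a cohesive-ended duplex
#' ("fragment 3", "fragment 4"); ligates the two into the circular
#' construct; and verifies it against the reference splice.
#'
#' @param job A [cloning_job()].
#' @param config An [mrf_config()].
#' @param verbose Narrate the stages with fragment labels.
#' @return A list of class `mrf_simulation`: `primers`, `fragment1`,
#'   `fragment2`, `strands` (the four single-strand products), `fragment3`,
#'   `fragment4`, `construct`, `verification`, `bands`, and the
#'   thermocycler `programs` for both PCR rounds.
#' @export
simulate_cloning <- function(job, config = mrf_config(), verbose = FALSE) {
  say <- if (verbose) function(...) message(sprintf(...)) else function(...) NULL
  ps <- design_primer_set(job, config)
  o <- ps$oligos
  min_core <- min(config$min_core,
                  nchar(o$vector_fwd_plain$body), nchar(o$insert_fwd_plain$body))

  say("round 1: double-primer PCR of vector backbone -> fragment 1")
  frag1 <- pcr_amplify(job$vector, o$vector_fwd_plain, o$vector_rev_plain,
                       id = "1")
  say("round 1: double-primer PCR of insert -> fragment 2")
  frag2 <- pcr_amplify(job$insert, o$insert_fwd_plain, o$insert_rev_plain,
                       id = "2")

  say("round 2: single-primer linear PCRs -> strands 3-1, 3-2, 4-1, 4-2")
  s31 <- linear_amplify(frag1, o$vector_fwd_tailed, label = "3-1")
  s32 <- linear_amplify(frag1, o$vector_rev_tailed, label = "3-2")
  s41 <- linear_amplify(frag2, o$insert_fwd_tailed, label = "4-1")
  s42 <- linear_amplify(frag2, o$insert_rev_tailed, label = "4-2")

  say("annealing -> cohesive-ended fragments 3 (vector) and 4 (insert)")
  frag3 <- anneal(s31, s32, min_core = min_core, id = "3")
  frag4 <- anneal(s41, s42, min_core = min_core, id = "4")

  say("ligation -> circular construct")
  construct <- ligate(frag4, frag3, circularize = TRUE,
                      id = paste0(job$vector$id, "-", job$insert$id))
  verification <- verify_construct(construct, job)
  say("verification: identity %s", if (verification$identical) "PASS" else "FAIL")

  structure(list(
    primers = ps,
    fragment1 = frag1, fragment2 = frag2,
    strands = list(`3-1` = s31, `3-2` = s32, `4-1` = s41, `4-2` = s42),
    fragment3 = frag3, fragment4 = frag4,
    construct = construct,
    verification = verification,
    bands = predicted_band_sizes(frag1, frag2, frag3, frag4, construct),
    programs = list(
      vector_pcr = touchdown_program(nchar(frag1$top)),
      insert_pcr = touchdown_program(nchar(frag2$top)))
  ), class = "mrf_simulation")
}

#' @export
print.mrf_simulation <- function(x, ...) {
  cat(sprintf("<mrf_simulation> %s\n", x$construct$seq$id))
  print(x$bands)
  print(x$verification)
  invisible(x)
}
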