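toy_fragments <- function() {
  job <- toy_job()
  ps <- design_primer_set(job, toy_config())
  frag1 <- pcr_amplify(job$vector, ps$oligos$vector_fwd_plain,
                       ps$oligos$vector_rev_plain, id = "1")
  frag2 <- pcr_amplify(job$insert, ps$oligos$insert_fwd_plain,
                       ps$oligos$insert_rev_plain, id = "2")
  frag3 <- anneal(linear_amplify(frag1, ps$oligos$vector_fwd_tailed),
                  linear_amplify(frag1, ps$oligos$vector_rev_tailed),
                  min_core = 5, id = "3")
  frag4 <- anneal(linear_amplify(frag2, ps$oligos$insert_fwd_tailed),
                  linear_amplify(frag2, ps$oligos$insert_rev_tailed),
                  min_core = 5, id = "4")
  list(job = job, vector_frag = frag3, insert_frag = frag4)
}

test_that("cohesive-end compatibility requires 5' reverse-complement protrusions
           on opposite strands", {
  e_top <- list(seq = "TTTTT", length = 5L, strand = "top", end = "5p", side = "left")
  e_bot <- list(seq = "AAAAA", length = 5L, strand = "bottom", end = "5p", side = "right")
  expect_true(ends_compatible(e_bot, e_top))
  e_same <- list(seq = "TTTTT", length = 5L, strand = "bottom", end = "5p", side = "right")
  expect_false(ends_compatible(e_same, e_top))
  blunt <- list(seq = "", length = 0L, strand = "top", end = "5p", side = "left")
  expect_false(ends_compatible(e_bot, blunt))
  three_p <- list(seq = "TTTTT", length = 5L, strand = "top", end = "3p", side = "left")
  expect_false(ends_compatible(e_bot, three_p))
})

test_that("compatibility over all pairs of 3-nt overhangs matches a
           base-pairing oracle", {
  bases <- c("A", "C", "G", "T")
  mers <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  expect_length(mers, 64)
  for (x in mers) for (y in mers) {
    e1 <- list(seq = x, length = 3L, strand = "bottom", end = "5p", side = "right")
    e2 <- list(seq = y, length = 3L, strand = "top", end = "5p", side = "left")
    # oracle: juxtapose and check Watson-Crick pairing position by position
    # (top base j sits opposite bottom base 4 - j)
    paired <- all(vapply(1:3, function(j)
      COMP[[substr(y, j, j)]] == substr(x, 4 - j, 4 - j), logical(1)))
    expect_equal(ends_compatible(e1, e2), paired)
  }
})

test_that("two-fragment circular ligation reproduces the hand-spliced construct", {
  fr <- toy_fragments()
  built <- ligate(fr$insert_frag, fr$vector_frag, circularize = TRUE)
  expect_s3_class(built, "construct")
  expect_true(is_circular(built$seq))
  # hand-splice oracle: stuffer CCCCC replaced by AACGT in the 20 bp vector
  expect_true(oracle_rot_equal(built$seq$bases, "AAAAATTTTTAACGTGGGGG"))
  expect_equal(seq_length(built$seq), 20L)
  expect_false(built$self_circle)
})

test_that("ligation is symmetric under fragment swap and refuses bad ends", {
  fr <- toy_fragments()
  a <- ligate(fr$insert_frag, fr$vector_frag)
  b <- ligate(fr$vector_frag, fr$insert_frag)
  expect_true(circular_equal(a$seq, b$seq))

  # blunt fragments cannot ligate under the cohesive-only policy
  blunt1 <- anneal("ACGGTCAGGTCAGGACGGTT", revcomp("ACGGTCAGGTCAGGACGGTT"))
  expect_error(ligate(blunt1, fr$vector_frag), class = "mrf_ligation_error")

  # non-complementary overhangs raise a ligation error naming both
  err <- expect_error(ligate(fr$vector_frag, fr$vector_frag),
                      class = "mrf_ligation_error")
  expect_match(conditionMessage(err), "AAAAA")
  expect_match(conditionMessage(err), "GGGGG")
})

test_that("a fragment with mutually complementary ends self-circularizes
           with a warning flag", {
  # left 5' protrusion GCATG (top), right 5' protrusion CATGC (bottom):
  # revcomp(CATGC) = GCATG, so the fragment can close on itself
  s1 <- paste0("GCATG", "ACGGTCAGGTCAGGACGGTT")
  s2 <- paste0("CATGC", revcomp("ACGGTCAGGTCAGGACGGTT"))
  frag <- anneal(s1, s2, min_core = 15)
  out <- ligate(frag)
  expect_true(out$self_circle)
  expect_true(is_circular(out$seq))
})

test_that("verification passes the simulated construct and reports junctions", {
  fr <- toy_fragments()
  built <- ligate(fr$insert_frag, fr$vector_frag)
  rep <- verify_construct(built, fr$job)
  expect_true(rep$identical)
  expect_true(rep$junction_a$match)
  expect_true(rep$junction_b$match)
  expect_equal(rep$insert_found, "forward")
  expect_equal(rep$construct_bp, rep$expected_bp)
})

test_that("verification rejects the parental vector and a reversed insert", {
  set.seed(310)
  fx <- generate_fixture(seed = 31, vector_len = 3000, insert_len = 600, k = 6)
  job <- fx$job

  # parental vector: stuffer never replaced
  rep_parent <- verify_construct(job$vector, job)
  expect_false(rep_parent$identical)
  expect_equal(rep_parent$insert_found, "absent")
  expect_true(is.na(rep_parent$colony_pcr$product_bp))

  # force-build the reversed-insert splice
  L <- seq_length(job$vector)
  retained <- seq_sub(job$vector, job$junction_b, job$retained_len)
  reversed <- nuc_seq(paste0(retained, revcomp(job$insert$bases)),
                      id = "reversed", topology = "circular")
  rep_rev <- verify_construct(reversed, job)
  expect_false(rep_rev$identical)
  expect_equal(rep_rev$insert_found, "reverse")

  # and the correct construct passes with a colony-PCR product
  sim <- simulate_cloning(job)
  rep_ok <- sim$verification
  expect_true(rep_ok$identical)
  expect_false(is.na(rep_ok$colony_pcr$product_bp))
  expect_true(is.na(rep_ok$colony_pcr$negative_control_bp))
})

test_that("band-size prediction reports strand lengths and duplex spans", {
  fr <- toy_fragments()
  bands <- predicted_band_sizes(fr$insert_frag)
  expect_equal(bands$length_bp[bands$species == "top strand"], 10)
  expect_equal(bands$length_bp[bands$species == "bottom strand"], 10)
  expect_equal(bands$length_bp[bands$species == "duplex span"], 15)

  blunt <- amplicon_duplex(strrep("ACGT", 25), id = "blunt100")
  expect_equal(predicted_band_sizes(blunt)$length_bp, 100)

  built <- ligate(fr$insert_frag, fr$vector_frag)
  mix <- predicted_band_sizes(fr$insert_frag, fr$vector_frag, built)
  expect_equal(nrow(mix), 7)  # 3 rows per sticky duplex + 1 circle
  expect_equal(mix$length_bp[mix$species == "circular construct"], 20)
})

test_that("construct length is conserved across random simulations", {
  set.seed(320)
  for (i in 1:5) {
    fx <- generate_fixture(seed = 600 + i,
                           vector_len = sample(2000:4000, 1),
                           insert_len = sample(200:2000, 1),
                           k = sample(5:8, 1))
    sim <- simulate_cloning(fx$job)
    expect_equal(seq_length(sim$construct$seq),
                 seq_length(fx$vector) - fx$job$stuffer_len + seq_length(fx$insert))
    expect_true(sim$verification$identical)
  }
})
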