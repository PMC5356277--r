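mk_oligo <- function(body, tail = "", name = "p", direction = "forward") {
  oligo(name, 1L, direction, body = body, tail = tail)
}

test_that("double-primer PCR with end-anchored primers is the identity", {
  set.seed(210)
  tpl_str <- rand_dna(300)
  tpl <- nuc_seq(tpl_str, id = "t")
  fwd <- mk_oligo(substr(tpl_str, 1, 20))
  rev <- mk_oligo(oracle_revcomp(substr(tpl_str, 281, 300)), direction = "reverse")
  prod <- pcr_amplify(tpl, fwd, rev)
  expect_equal(prod$top, tpl_str)
  expect_true(prod$blunt)
  expect_equal(prod$bottom, oracle_revcomp(tpl_str))

  # tails are appended untemplated on both ends
  fwd_t <- mk_oligo(substr(tpl_str, 1, 20), tail = "GGCCAA")
  rev_t <- mk_oligo(oracle_revcomp(substr(tpl_str, 281, 300)),
                    tail = "TTGGCC", direction = "reverse")
  prod_t <- pcr_amplify(tpl, fwd_t, rev_t)
  expect_equal(nchar(prod_t$top), 300 + 6 + 6)
  expect_equal(prod_t$top, paste0("GGCCAA", tpl_str, oracle_revcomp("TTGGCC")))
})

test_that("PCR errors name the failing primer and list ambiguous sites", {
  set.seed(215)
  tpl <- nuc_seq(paste0(rand_dna(100), "ACGTACGTACGTACG"), id = "t")
  good <- mk_oligo(seq_sub(tpl, 1, 18))
  miss <- mk_oligo("TTTTTTTTTTTTTTTTTT", name = "absent", direction = "reverse")
  err <- expect_error(pcr_amplify(tpl, good, miss), class = "mrf_no_binding_error")
  expect_equal(err$primer, "absent")
  # divergent orientation on a linear template yields no product
  set.seed(211)
  lin_str <- rand_dna(200)
  lin <- nuc_seq(lin_str, id = "lin")
  late_f <- mk_oligo(substr(lin_str, 150, 169))
  early_r <- mk_oligo(oracle_revcomp(substr(lin_str, 20, 39)), direction = "reverse")
  expect_error(pcr_amplify(lin, late_f, early_r), class = "mrf_geometry_error")
  # the same primers amplify across the origin when the template is circular
  circ <- nuc_seq(lin_str, id = "circ", topology = "circular")
  wrapped <- pcr_amplify(circ, late_f, early_r)
  expect_equal(wrapped$top,
               oracle_pcr_circular(lin_str, late_f$body, early_r$body))
})

test_that("circular amplification is rotation-invariant", {
  set.seed(212)
  base <- rand_dna(400)
  fwd <- mk_oligo(substr(base, 350, 369))
  rev <- mk_oligo(oracle_revcomp(substr(base, 80, 99)), direction = "reverse")
  ref <- pcr_amplify(nuc_seq(base, topology = "circular"), fwd, rev)$top
  for (shift in c(25, 199, 350)) {
    rotated <- paste0(substr(base, shift + 1, 400), substr(base, 1, shift))
    got <- pcr_amplify(nuc_seq(rotated, topology = "circular"), fwd, rev)$top
    expect_equal(got, ref)
  }
})

test_that("single-primer linear amplification copies one strand full-length", {
  job <- toy_job()
  ps <- design_primer_set(job, toy_config())
  frag2 <- pcr_amplify(job$insert, ps$oligos$insert_fwd_plain,
                       ps$oligos$insert_rev_plain)
  expect_equal(frag2$top, "AACGT")
  # untailed forward primer reproduces the top strand
  s <- linear_amplify(frag2, ps$oligos$insert_fwd_plain)
  expect_equal(s$bases, frag2$top)
  # tailed primers prepend their tails
  expect_equal(linear_amplify(frag2, ps$oligos$insert_fwd_tailed)$bases,
               "TTTTTAACGT")
  expect_equal(linear_amplify(frag2, ps$oligos$insert_rev_tailed)$bases,
               "CCCCCACGTT")
  expect_error(linear_amplify(frag2, mk_oligo("GGGGG", name = "nohit")),
               class = "mrf_no_binding_error")
})

test_that("annealing pairs the complementary core and annotates 5' overhangs", {
  d <- anneal("TTTTTAACGT", "CCCCCACGTT", min_core = 5)
  expect_equal(d$left_overhang$seq, "TTTTT")
  expect_equal(d$left_overhang$strand, "top")
  expect_equal(d$left_overhang$end, "5p")
  expect_equal(d$right_overhang$seq, "CCCCC")
  expect_equal(d$right_overhang$strand, "bottom")

  # a strand and its reverse complement give a blunt duplex
  set.seed(220)
  s <- rand_dna(60)
  b <- anneal(s, oracle_revcomp(s), min_core = 15)
  expect_equal(b$left_overhang$length, 0L)
  expect_equal(b$right_overhang$length, 0L)

  # no shared core at all
  expect_error(anneal(strrep("A", 30), strrep("A", 30), min_core = 15),
               class = "mrf_annealing_failure_error")
  # near-complementary core with an internal mismatch is reported as such
  s2 <- oracle_revcomp(s)
  substr(s2, 30, 30) <- chartr("ACGT", "GTAC", substr(s2, 30, 30))
  err <- expect_error(anneal(s, s2, min_core = 15), class = "mrf_mismatch_error")
  expect_true(length(err$positions) >= 1)
})

test_that("annealing agrees with the brute-force offset-scan oracle", {
  set.seed(221)
  for (i in 1:120) {
    core <- rand_dna(sample(15:40, 1))
    t1 <- rand_dna(sample(0:8, 1))
    t2 <- rand_dna(sample(0:8, 1))
    s1 <- paste0(t1, core)
    s2 <- paste0(t2, oracle_revcomp(core))
    want <- oracle_anneal(s1, s2, min_core = 15)
    got <- anneal(s1, s2, min_core = 15)
    expect_equal(got$left_overhang$seq, want$left_seq)
    expect_equal(got$right_overhang$seq, want$right_seq)
    expect_equal(nchar(got$top) - got$left_overhang$length -
                   (if (got$right_overhang$strand == "top") got$right_overhang$length else 0L),
                 want$core)
  }
})

test_that("probe-seeded annealing of long strands matches the oracle route", {
  set.seed(222)
  core <- rand_dna(3000)
  s1 <- paste0("GCGCGT", core)
  s2 <- paste0("TTAACC", oracle_revcomp(core))
  d <- anneal(s1, s2, min_core = 15)
  expect_equal(d$left_overhang$seq, "GCGCGT")
  expect_equal(d$right_overhang$seq, "TTAACC")
})

test_that("linear amplification plus annealing round-trips a blunt duplex", {
  set.seed(230)
  for (i in 1:10) {
    top <- rand_dna(sample(60:200, 1))
    dup <- amplicon_duplex(top)
    fwd <- mk_oligo(substr(top, 1, 20))
    rev <- mk_oligo(substr(oracle_revcomp(top), 1, 20), direction = "reverse")
    back <- anneal(linear_amplify(dup, fwd), linear_amplify(dup, rev))
    expect_equal(back$top, dup$top)
    expect_equal(back$bottom, dup$bottom)
    expect_equal(back$left_overhang$length, 0L)
    expect_equal(back$right_overhang$length, 0L)
  }
})

test_that("tailed single-primer products anneal into fragments whose
           overhangs are the job's junction overhangs", {
  set.seed(231)
  for (i in 1:8) {
    fx <- generate_fixture(seed = 400 + i, vector_len = 3000, insert_len = 800,
                           k = sample(5:8, 1))
    ps <- design_primer_set(fx$job)
    ov <- ps$overhangs
    frag2 <- pcr_amplify(fx$job$insert, ps$oligos$insert_fwd_plain,
                         ps$oligos$insert_rev_plain)
    frag4 <- anneal(linear_amplify(frag2, ps$oligos$insert_fwd_tailed),
                    linear_amplify(frag2, ps$oligos$insert_rev_tailed))
    expect_equal(frag4$left_overhang$seq, ov$a$seq)
    expect_equal(frag4$right_overhang$seq, revcomp(ov$b$seq))
    frag1 <- pcr_amplify(fx$job$vector, ps$oligos$vector_fwd_plain,
                         ps$oligos$vector_rev_plain)
    frag3 <- anneal(linear_amplify(frag1, ps$oligos$vector_fwd_tailed),
                    linear_amplify(frag1, ps$oligos$vector_rev_tailed))
    expect_equal(frag3$left_overhang$seq, ov$b$seq)
    expect_equal(frag3$right_overhang$seq, revcomp(ov$a$seq))
  }
})
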