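test_that("select_body extends or trims to satisfy the 3' G/C rule", {
  # bases 1..25 end in T but 1..26 end in G: the 26-mer must win
  tpl <- nuc_seq(paste0(strrep("A", 24), "TG", strrep("A", 20)), id = "t")
  body <- select_body(tpl, 1, "forward", target_len = 25, window = c(20, 32))
  expect_equal(nchar(body), 26L)
  expect_equal(as.character(substr(body, 26, 26)), "G")
  expect_length(attr(body, "warnings"), 0)

  # every length qualifies on an all-G template: the target length wins
  allg <- nuc_seq(strrep("G", 50), id = "g")
  expect_equal(nchar(select_body(allg, 1, "forward")), 25L)

  # nothing qualifies: best effort at the target with an explicit warning
  allt <- nuc_seq(strrep("T", 50), id = "t")
  b <- select_body(allt, 1, "forward")
  expect_equal(nchar(b), 25L)
  expect_match(attr(b, "warnings"), "gc_3prime")
})

test_that("select_body matches an exhaustive window-scoring oracle", {
  set.seed(110)
  for (i in 1:40) {
    tpl_str <- rand_dna(80)
    tpl <- nuc_seq(tpl_str, id = "t")
    dir <- sample(c("forward", "reverse"), 1)
    junction <- if (dir == "forward") sample(1:40, 1) else sample(40:80, 1)
    got <- select_body(tpl, junction, dir, target_len = 25, window = c(20, 32))
    # oracle: score every window length, keep G/C-terminal candidates,
    # minimize |len - 25| with ties to the shorter
    cands <- list()
    for (len in 20:32) {
      b <- if (dir == "forward") {
        if (junction + len - 1 > 80) next
        substr(tpl_str, junction, junction + len - 1)
      } else {
        if (junction - len + 1 < 1) next
        oracle_revcomp(substr(tpl_str, junction - len + 1, junction))
      }
      cands[[as.character(len)]] <- b
    }
    lens <- as.integer(names(cands))
    ok <- vapply(cands, function(b) substr(b, nchar(b), nchar(b)) %in% c("G", "C"),
                 logical(1))
    if (any(ok)) {
      keep <- lens[ok]
      pick <- keep[order(abs(keep - 25), keep)][1]
      expect_equal(as.character(got), cands[[as.character(pick)]])
      expect_length(attr(got, "warnings"), 0)
    } else {
      expect_match(attr(got, "warnings"), "gc_3prime")
    }
  }
})

test_that("melting temperature is deterministic, GC-monotone, and matches an
           independent nearest-neighbor reimplementation", {
  s <- "ACGTACGTACGTACGTACGT"
  expect_identical(melting_temp(s), melting_temp(s))
  expect_error(melting_temp("ACGTACG"), class = "mrf_length_error")
  expect_error(melting_temp("ACGTNACGT"), class = "mrf_alphabet_error")

  # fallback formula strictly increases when an A becomes a G at fixed length
  a <- "ATATATATATATATATATAT"
  b <- sub("A", "G", a)
  expect_gt(melting_temp(b, method = "gc_fallback"),
            melting_temp(a, method = "gc_fallback"))

  # independent reimplementation of the unified NN table as oracle
  nn <- function(x) {
    dh_tab <- list(AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), AC = c(-8.4, -22.4),
                   AG = c(-7.8, -21.0), TA = c(-7.2, -21.3), TT = c(-7.9, -22.2),
                   TC = c(-8.2, -22.2), TG = c(-8.5, -22.7), CA = c(-8.5, -22.7),
                   CT = c(-7.8, -21.0), CC = c(-8.0, -19.9), CG = c(-10.6, -27.2),
                   GA = c(-8.2, -22.2), GT = c(-8.4, -22.4), GC = c(-9.8, -24.4),
                   GG = c(-8.0, -19.9))
    n <- nchar(x)
    dh <- 0; ds <- 0
    for (i in 1:(n - 1)) {
      v <- dh_tab[[substr(x, i, i + 1)]]
      dh <- dh + v[1]; ds <- ds + v[2]
    }
    for (t in c(substr(x, 1, 1), substr(x, n, n))) {
      if (t %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1) * log(0.05)
    dh * 1000 / (ds + 1.987 * log(500e-9 / 4)) - 273.15
  }
  expect_equal(melting_temp(s), nn(s), tolerance = 0.5 / abs(nn(s)))
  expect_equal(melting_temp(s), 56.146, tolerance = 1e-4)
  set.seed(120)
  for (i in 1:20) {
    x <- rand_dna(sample(12:35, 1))
    expect_lt(abs(melting_temp(x) - nn(x)), 0.5)
  }
})

test_that("the designed set carries the junction overhangs as tails", {
  job <- toy_job()
  ps <- design_primer_set(job, toy_config())
  o <- ps$oligos
  expect_length(o, 8)
  expect_equal(vapply(o, function(x) x$role, integer(1), USE.NAMES = FALSE), 1:8)
  expect_equal(sum(vapply(o, function(x) nzchar(x$tail), logical(1))), 4L)
  expect_equal(o$insert_fwd_tailed$tail, "TTTTT")             # overhang A
  expect_equal(o$insert_rev_tailed$tail, "CCCCC")             # revcomp(B)
  expect_equal(o$vector_fwd_tailed$tail, "GGGGG")             # overhang B
  expect_equal(o$vector_rev_tailed$tail, "AAAAA")             # revcomp(A)
  expect_equal(oligo_seq(o$insert_fwd_tailed), "TTTTTAACGT")
})

test_that("tailed primers share bodies with their plain counterparts and
           tails always have length k", {
  set.seed(130)
  for (i in 1:10) {
    k <- sample(5:8, 1)
    fx <- generate_fixture(seed = 1000 + i, vector_len = 2000,
                           insert_len = 400, k = k)
    ps <- design_primer_set(fx$job)
    o <- ps$oligos
    expect_equal(o$insert_fwd_plain$body, o$insert_fwd_tailed$body)
    expect_equal(o$insert_rev_plain$body, o$insert_rev_tailed$body)
    expect_equal(o$vector_fwd_plain$body, o$vector_fwd_tailed$body)
    expect_equal(o$vector_rev_plain$body, o$vector_rev_tailed$body)
    for (nm in c("insert_fwd_plain", "insert_rev_plain",
                 "vector_fwd_plain", "vector_rev_plain"))
      expect_equal(o[[nm]]$tail, "")
    for (nm in c("insert_fwd_tailed", "insert_rev_tailed",
                 "vector_fwd_tailed", "vector_rev_tailed"))
      expect_equal(nchar(o[[nm]]$tail), k)
    # G/C rule holds or is explicitly flagged, per oligo
    for (x in o) {
      s <- oligo_seq(x)
      ends_gc <- substr(s, 1, 1) %in% c("G", "C") &&
        substr(s, nchar(s), nchar(s)) %in% c("G", "C")
      expect_true(ends_gc || length(x$warnings) > 0)
    }
  }
})

test_that("validate_overhangs flags palindromes, homopolymers, and identity", {
  w <- validate_overhangs("GATC", "AATT")
  expect_setequal(w$side[w$code == "palindromic_overhang"], c("A", "B"))

  w <- validate_overhangs("TTTTT", "GGGGG")
  expect_setequal(w$code, "homopolymer_overhang")

  w <- validate_overhangs("CATGC", "CATGC")
  expect_true("identical_overhangs" %in% w$code)

  expect_equal(nrow(validate_overhangs("GATCC", "TTGCA")), 0L)
})
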