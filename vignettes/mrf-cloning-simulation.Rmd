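---
title: "Simulating modified restriction-free cloning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating modified restriction-free cloning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfclone)
```

## The method being modelled

Modified restriction-free (MRF) cloning inserts a DNA fragment between two
arbitrary positions of a circular vector without restriction enzymes. The
wet-lab workflow has four stages, and `mrfclone` models each of them at
single-base resolution:

1. **Double-primer PCR.** The vector backbone (minus the "stuffer" segment
   to be replaced) and the insert are amplified with ordinary primer pairs,
   giving two blunt double-stranded fragments.
2. **Single-primer linear PCR.** Each blunt fragment serves as template for
   two separate reactions, each containing a *single* 5'-tailed primer.
   With one primer, product accumulates linearly, and every product strand
   begins with the untemplated tail.
3. **Annealing.** The two tailed strands from each fragment are combined.
   Their templated cores are exact reverse complements, so they hybridize
   into a duplex whose two tails remain single-stranded — 5' cohesive
   protrusions of the tail length.
4. **Ligation.** The tails are chosen so that the insert fragment's
   protrusions are reverse complements of the vector fragment's. T4 ligase
   joins the two fragments into the final circular construct with seamless
   junctions.

## Geometry and tail assignment

A cloning job is defined by a circular vector, an insert, two junction
positions $A$ and $B$ on the vector (with the stuffer strictly between
them, possibly wrapping the origin), and the overhang length $k$ (5–8 nt
by default). The two overhang regions are vector sequence:

* overhang A = vector$[A-k+1 .. A]$ (the $k$ bases ending at $A$),
* overhang B = vector$[B .. B+k-1]$ (the $k$ bases starting at $B$).

The vector backbone is amplified from $B+k$ to $A-k$, so each overhang
region appears exactly once in the ligated circle — as a protrusion, not as
backbone — which is what makes the junctions seamless. The tail assignment
follows from requiring each junction overhang to appear as complementary 5'
protrusions on the two fragments: the tailed insert primers carry overhang
A (forward) and the reverse complement of overhang B (reverse); the tailed
vector primers carry overhang B (forward) and the reverse complement of
overhang A (reverse). Up to swapping the two fragments this is the unique
assignment for which ligation reconstitutes the intended construct, which
the test suite verifies against the *reference splice* — the ground truth
obtained by directly replacing the stuffer with the insert.

```{r toy}
vec <- nuc_seq("AAAAATTTTTCCCCCGGGGG", id = "toyvec", topology = "circular")
ins <- nuc_seq("AACGT", id = "toygene")
cfg <- mrf_config(k = 5, body_target = 5, body_window = c(5, 5), min_core = 5)
job <- cloning_job(vec, ins, 10, 16, k = 5, config = cfg)
job
design_primer_set(job, cfg)$oligos$insert_fwd_tailed
simulate_cloning(job, cfg)$verification$identical
```

## Model components and simplifications

**Priming** is modelled as exact, unique, full-length binding: a primer
body must occur exactly once on its target strand (ambiguous or absent
binding is a structured error naming the primer and the sites). Partial
hybridization, mispriming, and polymerase errors are out of scope — the
simulator answers "what does this design produce if the chemistry works",
not "how likely is the chemistry to work".

**Annealing** finds the maximal perfectly complementary overlap between the
two strands over all alignments, requiring at least `min_core` paired
bases (default 15). For strands in the kilobase range an $O(n^2)$ scan is
too slow, so candidate alignments are seeded from the 3'-terminal 12-mers
of each strand and verified by direct comparison; a full scan remains the
fallback for short strands. Near-complementary pairs (a long overlap
spoiled by point mismatches) produce a mismatch error that reports the
offending positions.

**Melting temperatures** use the unified nearest-neighbor thermodynamic
parameter set with a monovalent-salt entropy correction
($0.368\,(N-1)\ln[\mathrm{Na^+}]$, 50 mM Na$^+$, 500 nM oligo). The
implementation was cross-checked against an independent reimplementation
and a reference value for a fixed 20-mer (56.146 °C). A length-and-GC
fallback formula is available via `mrf_config(tm_method = "gc_fallback")`.

**Primer bodies** are selected from the template in a 20–32 nt window
around a 25 nt target, preferring candidates whose 3'-terminal base is G or
C (ties resolved toward the target length, then toward the shorter
candidate). When no candidate satisfies the rule, the target-length body is
used and the violation is surfaced as an explicit per-oligo warning rather
than an error, matching how a bench scientist would treat the guideline.

**Verification** is rotation- and flip-invariant (a plasmid has no
canonical origin or strand), reports insert orientation, matches both
junctions with ±30 bp excerpts, and simulates a colony PCR: a backbone
forward primer upstream of junction A paired with an insert-internal
reverse primer, with the parental vector as the negative-control template.

## Protocol artifacts

The protocol module renders the bench-side parameters of the workflow:
touchdown PCR (98 °C initial denaturation; 20 cycles with annealing
stepping 60 → 50.5 °C at −0.5 °C/cycle and 72 °C extension at 30 s/kb,
rounded up; then 10 cycles at a fixed 52 °C), colony PCR (25 cycles,
50 °C annealing, 60 s/kb extension at 68 °C), reaction recipes (50 ng
template for double-primer reactions, 500 ng for single-primer reactions —
linear amplification needs the extra template), and ligation mixes. Molar
amounts use the 650 g·mol⁻¹·bp⁻¹ average; the vector:insert ratio defaults
to 1:3 and switches to 6:1 for inserts of 10 kb and above, with overrides
accepted inside the 6:1 … 1:10 policy bounds.

```{r protocol}
annealing_temperatures(touchdown_program(1000))
ligation_mix(5500, 20000)$ratio
```

The packaged screening table (46 constructs, 8 colonies checked each)
summarizes to an overall efficiency of 86.9 %. One numerical convention is
worth noting: the overall percentage is *truncated* (not rounded) to one
decimal — 320/368 = 86.9565 % reports as 86.9 — while per-row percentages
use ordinary rounding.

```{r table}
tab <- read_efficiency_table(
  system.file("extdata", "cloning_efficiency.tsv", package = "mrfclone"))
efficiency_summary(tab)
```

## Synthetic fixtures

`generate_fixture(seed, ...)` draws a random circular vector and insert at
a requested GC content, places the junctions so the stuffer leaves room for
full-length primer bodies on the backbone, and redraws the vector until the
two overhangs are neither identical nor palindromic (either would permit
unintended ligation products). Fixtures carry their own expected construct,
so any simulation on a fixture can be checked exactly. Identical seeds give
identical fixtures, and the caller's RNG state is restored. The test suite
exercises vectors of 3–10 kb, inserts of 0.1–20 kb, and $k \in \{5..8\}$;
these sizes are this package's own choices of a realistic working range
(typical plasmids and gene-cluster-sized inserts), not an external
constraint.

```{r fixture}
fx <- generate_fixture(seed = 42, vector_len = 3000, insert_len = 500)
sim <- simulate_cloning(fx$job)
sim$verification$identical
sim$bands
```

## Limitations

* Hybridization is all-or-nothing at exact-match resolution; no
  thermodynamic ensemble, secondary structure, or off-target model.
* Ligation efficiency, transformation, and colony statistics are not
  simulated — the packaged efficiency table is empirical input, and the
  simulator cannot predict such rates.
* GenBank support is deliberately minimal (LOCUS topology, ORIGIN block,
  and a small feature table), enough for round-tripping constructs and
  opening them in plasmid viewers, not a general flat-file parser.
* Primer concentration effects, polymerase choice, and buffer chemistry
  appear only as fixed recipe entries.
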