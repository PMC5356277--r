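# Oligo melting temperature. The default model is the unified
# nearest-neighbor parameter set (dH in kcal/mol, dS in cal/mol/K) with a
# sodium entropy correction and a 500 nM non-self-complementary oligo
# assumption; a length-and-GC formula is available as a cheap fallback.

.NN_DH <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
            TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
            CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
            GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
            TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
            CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
            GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor estimate under fixed default conditions (50 mM monovalent
#' salt, 500 nM total oligo, non-self-complementary assumption), or a simple
#' length-and-GC formula (`method = "gc_fallback"`:
#' `64.9 + 41 * (nGC - 16.4) / N`). The nearest-neighbor route sums unified
#' dinucleotide stacking enthalpies/entropies plus terminal initiation terms
#' and applies the entropic salt correction `0.368 * (N - 1) * ln[Na+]`.
#'
#' @param seq DNA string, at least 8 nt, no N.
#' @param method `"nn"` or `"gc_fallback"`.
#' @param na_mM Monovalent cation concentration, mM.
#' @param oligo_nM Total oligo concentration, nM.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temp("ACGTACGTACGTACGTACGT")
#' @export
melting_temp <- function(seq, method = c("nn", "gc_fallback"),
                         na_mM = 50, oligo_nM = 500) {
  method <- match.arg(method)
  seq <- assert_dna(seq, "oligo")
  n <- nchar(seq)
  if (n < 8L)
    stop_mrf("length", sprintf("oligo too short for a Tm estimate (%d nt, need >= 8)", n))
  if (grepl("N", seq, fixed = TRUE))
    stop_mrf("alphabet", "Tm is undefined for ambiguous base N")
  chars <- strsplit(seq, "")[[1]]
  n_gc <- sum(chars %in% c("G", "C"))
  if (method == "gc_fallback")
    return(64.9 + 41 * (n_gc - 16.4) / n)

  dinucs <- paste0(chars[-n], chars[-1])
  dH <- sum(.NN_DH[dinucs])
  dS <- sum(.NN_DS[dinucs])
  # terminal initiation: G/C end +0.1 kcal/mol, -2.8 cal/mol/K; A/T end
  # +2.3 kcal/mol, +4.1 cal/mol/K
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                        { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  dH * 1000 / (dS + 1.987 * log(ct / 4)) - 273.15
}
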