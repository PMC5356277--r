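# Bench-protocol emitters: thermocycler programs, 50 uL PCR reaction
# recipes, the ligation molar-ratio calculator, and the cloning-efficiency
# summarizer for colony-PCR screening tables.

#' Thermocycler program building blocks
#'
#' A step is a temperature hold; a phase repeats an ordered list of steps for
#' a number of cycles; a program is an ordered list of phases. A step may
#' carry a per-cycle temperature decrement (touchdown annealing).
#'
#' @param temperature_c Temperature, Celsius (4-99).
#' @param duration_s Hold time, seconds (> 0).
#' @param decrement_c Per-cycle temperature decrement, Celsius (>= 0).
#' @param name Step name.
#' @return `thermo_step()`: a list of class `thermo_step`.
#' @export
thermo_step <- function(temperature_c, duration_s, decrement_c = 0, name = "") {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop_mrf("argument", "step duration must be positive")
  if (temperature_c < 4 || temperature_c > 99)
    stop_mrf("argument", "step temperature must be within 4-99 C")
  structure(list(name = name, temperature_c = temperature_c,
                 duration_s = as.integer(duration_s),
                 decrement_c = decrement_c),
            class = "thermo_step")
}

#' @rdname thermo_step
#' @param cycles Number of repeats (>= 1).
#' @param steps List of `thermo_step`s.
#' @export
thermo_phase <- function(cycles, steps) {
  if (cycles < 1L) stop_mrf("argument", "cycles must be >= 1")
  if (!length(steps)) stop_mrf("argument", "a phase needs at least one step")
  structure(list(cycles = as.integer(cycles), steps = steps),
            class = "thermo_phase")
}

#' @rdname thermo_step
#' @param label Program label.
#' @param phases List of `thermo_phase`s.
#' @export
thermo_program <- function(label, phases) {
  if (!length(phases)) stop_mrf("argument", "a program needs at least one phase")
  structure(list(label = label, phases = phases), class = "thermo_program")
}

#' @export
print.thermo_program <- function(x, ...) {
  cat(format_thermo_card(x), sep = "\n")
  invisible(x)
}

#' Render a program as a human-readable card
#' @param program A [thermo_program()].
#' @return Character vector of lines.
#' @export
format_thermo_card <- function(program) {
  out <- sprintf("=== %s ===", program$label)
  for (ph in program$phases) {
    out <- c(out, sprintf("%d cycle%s:", ph$cycles, if (ph$cycles > 1) "s" else ""))
    for (st in ph$steps) {
      dec <- if (st$decrement_c > 0)
        sprintf(" (-%.1f C/cycle)", st$decrement_c) else ""
      out <- c(out, sprintf("  %-22s %5.1f C for %4d s%s",
                            st$name, st$temperature_c, st$duration_s, dec))
    }
  }
  out
}

#' @rdname format_thermo_card
#' @param path Output JSON path.
#' @export
write_thermo_json <- function(program, path) {
  jsonlite::write_json(
    list(label = program$label,
         phases = lapply(program$phases, function(ph)
           list(cycles = ph$cycles,
                steps = lapply(ph$steps, unclass)))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-cycle annealing temperatures of a touchdown phase
#'
#' @param program A [thermo_program()].
#' @return Numeric vector: the annealing temperature actually used in each
#'   cycle of the first phase containing a decremented step.
#' @export
annealing_temperatures <- function(program) {
  for (ph in program$phases) {
    for (st in ph$steps) {
      if (st$decrement_c > 0)
        return(st$temperature_c - st$decrement_c * (seq_len(ph$cycles) - 1))
    }
  }
  numeric()
}

extension_seconds <- function(amplicon_len_bp, s_per_kb) {
  max(1L, as.integer(ceiling(s_per_kb * amplicon_len_bp / 1000)))
}

#' Touchdown PCR program
#'
#' Initial denaturation 98 C for 5 min; 20 touchdown cycles of 98 C 20 s,
#' annealing 20 s starting at 60 C and dropping 0.5 C per cycle (so the last
#' touchdown cycle anneals at 50.5 C -- the literal per-cycle rule), and
#' 72 C extension at 30 s/kb; then 10 cycles with annealing fixed at 52 C;
#' final extension 72 C for 10 min. Extension times are rounded up to whole
#' seconds, minimum 1 s.
#'
#' @param amplicon_len_bp Expected amplicon length, bp.
#' @return A [thermo_program()].
#' @examples
#' touchdown_program(2000)  # 60 s extension
#' @export
touchdown_program <- function(amplicon_len_bp) {
  amplicon_len_bp <- as.integer(amplicon_len_bp)
  if (is.na(amplicon_len_bp) || amplicon_len_bp < 1L)
    stop_mrf("argument", "amplicon length must be a positive number of bp")
  ext <- extension_seconds(amplicon_len_bp, 30)
  thermo_program(
    sprintf("Touchdown PCR (%d bp amplicon)", amplicon_len_bp),
    list(
      thermo_phase(1L, list(thermo_step(98, 300, name = "initial denaturation"))),
      thermo_phase(20L, list(
        thermo_step(98, 20, name = "denaturation"),
        thermo_step(60, 20, decrement_c = 0.5, name = "annealing (touchdown)"),
        thermo_step(72, ext, name = "extension"))),
      thermo_phase(10L, list(
        thermo_step(98, 20, name = "denaturation"),
        thermo_step(52, 20, name = "annealing"),
        thermo_step(72, ext, name = "extension"))),
      thermo_phase(1L, list(thermo_step(72, 600, name = "final extension")))
    ))
}

#' Colony PCR program
#'
#' 95 C for 2 min; 25 cycles of 95 C 30 s, 50 C 30 s, 68 C extension at
#' 1 min/kb; final extension 68 C for 10 min.
#'
#' @inheritParams touchdown_program
#' @return A [thermo_program()].
#' @export
colony_pcr_program <- function(amplicon_len_bp) {
  amplicon_len_bp <- as.integer(amplicon_len_bp)
  if (is.na(amplicon_len_bp) || amplicon_len_bp < 1L)
    stop_mrf("argument", "amplicon length must be a positive number of bp")
  ext <- extension_seconds(amplicon_len_bp, 60)
  thermo_program(
    sprintf("Colony PCR (%d bp amplicon)", amplicon_len_bp),
    list(
      thermo_phase(1L, list(thermo_step(95, 120, name = "initial denaturation"))),
      thermo_phase(25L, list(
        thermo_step(95, 30, name = "denaturation"),
        thermo_step(50, 30, name = "annealing"),
        thermo_step(68, ext, name = "extension"))),
      thermo_phase(1L, list(thermo_step(68, 600, name = "final extension")))
    ))
}

#' PCR reaction recipe
#'
#' The 50 uL reaction compositions: the regular double-primer reaction
#' ("Reaction 1", ~50 ng template, both primers) and the single-primer
#' linear reactions ("Reaction 2a"/"2b", ~500 ng template -- about ten times
#' more, since single-primer amplification is linear -- and exactly one
#' primer). Components otherwise identical: 10 uL 5x GC buffer, 1 uL 10 mM
#' dNTPs, 1.5 uL DMSO, 1 uL high-fidelity polymerase, water to 50 uL.
#'
#' @param kind `"double"` or `"single"`.
#' @param primer For `kind = "single"`: which primer the reaction contains.
#' @return An object of class `recipe_spec` with `$label`, `$components`
#'   (data frame `name`, `amount`, `unit`) and `$total_volume_ul = 50`.
#' @export
reaction_recipe <- function(kind = c("double", "single"),
                            primer = c("forward", "reverse")) {
  kind <- match.arg(kind)
  primer <- match.arg(primer)
  rows <- list(data.frame(name = "Template DNA",
                          amount = if (kind == "double") 50 else 500,
                          unit = "ng"))
  if (kind == "double" || primer == "forward")
    rows <- c(rows, list(data.frame(name = "Forward primer (100 uM)",
                                    amount = 0.25, unit = "uL")))
  if (kind == "double" || primer == "reverse")
    rows <- c(rows, list(data.frame(name = "Reverse primer (100 uM)",
                                    amount = 0.25, unit = "uL")))
  rows <- c(rows, list(
    data.frame(name = "Phusion GC Buffer (5x)", amount = 10, unit = "uL"),
    data.frame(name = "dNTPs (10 mM)", amount = 1, unit = "uL"),
    data.frame(name = "DMSO (100%)", amount = 1.5, unit = "uL"),
    data.frame(name = "Phusion High-Fidelity DNA Polymerase", amount = 1, unit = "uL"),
    data.frame(name = "Water", amount = NA_real_, unit = "to 50 uL")))
  label <- if (kind == "double") "Reaction 1"
           else if (primer == "forward") "Reaction 2a" else "Reaction 2b"
  structure(list(label = label, kind = kind,
                 components = do.call(rbind, rows), total_volume_ul = 50),
            class = "recipe_spec")
}

#' @export
print.recipe_spec <- function(x, ...) {
  cat(sprintf("=== %s (%s-primer PCR, %d uL) ===\n",
              x$label, x$kind, x$total_volume_ul))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %-40s %s %s\n", x$components$name[i],
                ifelse(is.na(x$components$amount[i]), "",
                       format(x$components$amount[i])),
                x$components$unit[i]))
  invisible(x)
}

#' Ligation mix calculator
#'
#' Converts fragment masses to picomoles with the linear double-stranded DNA
#' approximation (650 g/mol per bp) and applies the molar-ratio policy:
#' vector:insert 1:3 for ordinary inserts, switching to 6:1 at and above the
#' large-insert threshold (default 10 kb). The ratio, whether from policy or
#' override, must stay within the 1:10 to 6:1 vector:insert bounds. The mix
#' is a 20 uL reaction incubated at 25 C (room temperature) for 2 h and
#' heat-inactivated at 65 C for 10 min.
#'
#' @param vec_len,ins_len Fragment lengths, bp.
#' @param vec_mass_ng Vector mass put in the reaction, ng.
#' @param ratio_override Optional `c(vector, insert)` molar ratio.
#' @param config An [mrf_config()] (threshold and policy ratios).
#' @return An object of class `ligation_recipe`.
#' @examples
#' ligation_mix(5500, 1400, vec_mass_ng = 50)     # 1:3
#' ligation_mix(5500, 20000, vec_mass_ng = 50)    # 6:1
#' @export
ligation_mix <- function(vec_len, ins_len, vec_mass_ng = 50,
                         ratio_override = NULL, config = mrf_config()) {
  if (vec_len <= 0 || ins_len <= 0 || vec_mass_ng <= 0)
    stop_mrf("argument", "lengths and mass must be positive")
  ratio <- if (!is.null(ratio_override)) as.numeric(ratio_override)
           else if (ins_len >= config$large_insert_threshold) config$ratio_large
           else config$ratio_small
  if (length(ratio) != 2L || any(ratio <= 0))
    stop_mrf("argument", "ratio must be two positive numbers c(vector, insert)")
  rel <- ratio[2] / ratio[1]  # insert molecules per vector molecule
  if (rel < 1 / 6 - 1e-9 || rel > 10 + 1e-9)
    stop_mrf("argument",
             sprintf("vector:insert ratio %g:%g outside the 6:1 to 1:10 policy bounds",
                     ratio[1], ratio[2]))
  pmol_per_ng <- function(len) 1000 / (650 * len)
  vec_pmol <- vec_mass_ng * pmol_per_ng(vec_len)
  ins_pmol <- vec_pmol * rel
  structure(list(
    vector = list(length_bp = vec_len, mass_ng = vec_mass_ng, pmol = vec_pmol),
    insert = list(length_bp = ins_len, mass_ng = ins_pmol * 650 * ins_len / 1000,
                  pmol = ins_pmol),
    ratio = c(vector = ratio[1], insert = ratio[2]),
    volume_ul = 20,
    incubation = list(temperature_c = 25, time_s = 7200),
    inactivation = list(temperature_c = 65, time_s = 600)
  ), class = "ligation_recipe")
}

#' @export
print.ligation_recipe <- function(x, ...) {
  cat(sprintf(paste0("=== Ligation mix (T4 DNA ligase, %d uL) ===\n",
                     "  vector: %d bp, %.1f ng (%.4f pmol)\n",
                     "  insert: %d bp, %.1f ng (%.4f pmol)\n",
                     "  molar ratio vector:insert = %g:%g\n",
                     "  incubate %g C for %d min; inactivate %g C for %d min\n"),
              x$volume_ul,
              x$vector$length_bp, x$vector$mass_ng, x$vector$pmol,
              x$insert$length_bp, x$insert$mass_ng, x$insert$pmol,
              x$ratio["vector"], x$ratio["insert"],
              x$incubation$temperature_c, x$incubation$time_s %/% 60,
              x$inactivation$temperature_c, x$inactivation$time_s %/% 60))
  invisible(x)
}

#' Summarize a cloning-efficiency screening table
#'
#' For a table of constructs with colonies checked / colonies positive (from
#' colony-PCR screening), computes the per-row percent positive and the
#' overall efficiency `100 * sum(positive) / sum(checked)`. The overall
#' percent is reported truncated to one decimal place (the convention used
#' for such screening summaries); per-row percents are rounded.
#'
#' @param rows Data frame with at least columns `checked` and `positive`
#'   (integer counts per construct); typically also `gene`, `length_bp`,
#'   `vector`.
#' @return An object of class `efficiency_summary`: `overall_percent`,
#'   `per_row_percent`, and `totals` (`constructs`, `checked`, `positive`).
#' @examples
#' efficiency_summary(data.frame(checked = 8, positive = 7))$overall_percent
#' @export
efficiency_summary <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop_mrf("argument", "rows must be a non-empty data frame")
  if (!all(c("checked", "positive") %in% names(rows)))
    stop_mrf("argument", "rows must have `checked` and `positive` columns")
  checked <- as.integer(rows$checked)
  positive <- as.integer(rows$positive)
  if (any(is.na(checked)) || any(is.na(positive)) || any(checked <= 0L) ||
      any(positive < 0L) || any(positive > checked))
    stop_mrf("argument", "need 0 <= positive <= checked and checked > 0 in every row")
  overall <- floor(1000 * sum(positive) / sum(checked)) / 10
  structure(list(
    overall_percent = overall,
    per_row_percent = round(100 * positive / checked, 1),
    totals = list(constructs = nrow(rows),
                  checked = sum(checked), positive = sum(positive)),
    rows = rows
  ), class = "efficiency_summary")
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat(sprintf(paste0("<efficiency_summary> %d constructs, %d colonies checked, ",
                     "%d positive\n  overall efficiency: %.1f%%\n"),
              x$totals$constructs, x$totals$checked, x$totals$positive,
              x$overall_percent))
  invisible(x)
}

#' Read a cloning-efficiency TSV
#'
#' Expected columns: `gene`, `gene_id`, `length_bp`, `vector`, `checked`,
#' `positive` (plus optional `start`/`end` genome coordinates). The package
#' ships such a table of 46 constructs under
#' `system.file("extdata", "cloning_efficiency.tsv", package = "mrfclone")`.
#'
#' @param path Path to a tab-separated table.
#' @return A data frame.
#' @export
read_efficiency_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("checked", "positive")
  if (!all(need %in% names(df)))
    stop_mrf("argument",
             sprintf("table %s lacks required columns: %s", path,
                     paste(setdiff(need, names(df)), collapse = ", ")))
  df
}
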