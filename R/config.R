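#' Package configuration
#'
#' Collects every tunable of the design/simulation pipeline in one list so
#' that runs are reproducible from a single record. Values can be loaded from
#' a YAML file with [read_mrf_config()]; unnamed entries fall back to these
#' defaults.
#'
#' @param k Cohesive-overhang length in nucleotides (5-8 under the default
#'   policy; see `relax_overhang_length`).
#' @param body_target Target primer homology-body length, nt.
#' @param body_window Allowed body-length window, `c(min, max)`, nt.
#' @param tm_method Melting-temperature model: `"nn"` (nearest-neighbor) or
#'   `"gc_fallback"` (length-and-GC formula).
#' @param min_core Minimum perfectly complementary core, nt, required by
#'   [anneal()].
#' @param large_insert_threshold Insert length, bp, at and above which
#'   [ligation_mix()] switches to the large-insert vector:insert ratio.
#' @param ratio_small,ratio_large `c(vector, insert)` molar ratios for
#'   ordinary and large inserts.
#' @param anchor_junction_a,anchor_junction_b Which base of an anchor match
#'   becomes the junction: `"end"` (last base) or `"start"` (first base).
#' @param relax_overhang_length Allow k outside 5-8 (toy examples).
#' @param both_strand_anchor Search anchors on both strands.
#' @return A named list of class `mrf_config`.
#' @export
mrf_config <- function(k = 6L,
                       body_target = 25L,
                       body_window = c(20L, 32L),
                       tm_method = c("nn", "gc_fallback"),
                       min_core = 15L,
                       large_insert_threshold = 10000L,
                       ratio_small = c(1L, 3L),
                       ratio_large = c(6L, 1L),
                       anchor_junction_a = c("end", "start"),
                       anchor_junction_b = c("start", "end"),
                       relax_overhang_length = FALSE,
                       both_strand_anchor = FALSE) {
  cfg <- list(
    k = as.integer(k),
    body_target = as.integer(body_target),
    body_window = as.integer(body_window),
    tm_method = match.arg(tm_method),
    min_core = as.integer(min_core),
    large_insert_threshold = as.integer(large_insert_threshold),
    ratio_small = as.numeric(ratio_small),
    ratio_large = as.numeric(ratio_large),
    anchor_junction_a = match.arg(anchor_junction_a),
    anchor_junction_b = match.arg(anchor_junction_b),
    relax_overhang_length = isTRUE(relax_overhang_length),
    both_strand_anchor = isTRUE(both_strand_anchor)
  )
  if (length(cfg$body_window) != 2L || cfg$body_window[1] > cfg$body_window[2])
    stop_mrf("argument", "body_window must be c(min, max) with min <= max")
  structure(cfg, class = c("mrf_config", "list"))
}

#' Read configuration from a YAML file
#'
#' Keys present in the file override the defaults of [mrf_config()]; unknown
#' keys raise an error rather than being silently dropped.
#'
#' @param path Path to a YAML key/value file.
#' @return An `mrf_config` list.
#' @export
read_mrf_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mrf_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop_mrf("argument", paste("unknown config keys:", paste(extra, collapse = ", ")))
  do.call(mrf_config, vals)
}

#' @rdname read_mrf_config
#' @param config An `mrf_config` list.
#' @export
write_mrf_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
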