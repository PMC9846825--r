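# Run configuration: digestion, chemistry, tolerances and the acceptance
# thresholds, serializable to/from JSON.

#' Pipeline run configuration
#'
#' Collects every tunable of the search and validation procedure with the
#' defaults used throughout: 10 ppm precursor/parent tolerance, 0.02 Da
#' fragment tolerance, the >40% assigned-peak rule evaluated over the 50
#' most intense peaks, and at least 2 consecutive cross-link specific
#' ions in a series.
#'
#' @param digest A [digest_spec()].
#' @param adduct Adduct `modification` searched (default [mod_dep()]).
#' @param target_residues Residues on which the adduct is searched.
#' @param fixed_mods,variable_mods Lists of modifications (defaults:
#'   carbamidomethyl-C fixed; Met oxidation variable).
#' @param bridges Named list of `bridge_definition`s searched (default:
#'   the glutamate-lysine isopeptide bridge only).
#' @param tol_ppm Precursor match tolerance, ppm.
#' @param parent_tol_ppm Parent-mass re-check tolerance, ppm.
#' @param frag_tol_da Fragment tolerance, Da.
#' @param assigned_fraction_cutoff Strict lower bound on the assigned
#'   fraction, in (0, 1); default 0.40.
#' @param min_xl_series Minimum consecutive cross-link specific ions in
#'   one series (default 2).
#' @param top_n Denominator cap for [assigned_fraction()] (default 50).
#' @param fragment_charges Fragment charges considered (default 1:2).
#' @param require_signature If `TRUE`, adduct acceptance additionally
#'   requires a signature ion (off by default: Dep-E signature ions are
#'   calculated but not observed in practice).
#' @param seed Integer seed recorded with the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(digest = digest_spec(),
                       adduct = mod_dep(),
                       target_residues = c("E", "D", "K", "Y", "S", "T", "H", "R"),
                       fixed_mods = list(mod_carbamidomethyl()),
                       variable_mods = list(mod_oxidation()),
                       bridges = builtin_bridges()["EK_isopeptide"],
                       tol_ppm = 10,
                       parent_tol_ppm = 10,
                       frag_tol_da = 0.02,
                       assigned_fraction_cutoff = 0.40,
                       min_xl_series = 2L,
                       top_n = 50L,
                       fragment_charges = c(1L, 2L),
                       require_signature = FALSE,
                       seed = 1L) {
  stopifnot(inherits(digest, "digest_spec"),
            inherits(adduct, "modification"),
            assigned_fraction_cutoff > 0, assigned_fraction_cutoff < 1,
            tol_ppm > 0, frag_tol_da > 0, min_xl_series >= 1L, top_n >= 1L)
  structure(list(digest = digest, adduct = adduct,
                 target_residues = toupper(target_residues),
                 fixed_mods = fixed_mods, variable_mods = variable_mods,
                 bridges = bridges, tol_ppm = tol_ppm,
                 parent_tol_ppm = parent_tol_ppm, frag_tol_da = frag_tol_da,
                 assigned_fraction_cutoff = assigned_fraction_cutoff,
                 min_xl_series = as.integer(min_xl_series),
                 top_n = as.integer(top_n),
                 fragment_charges = as.integer(fragment_charges),
                 require_signature = isTRUE(require_signature),
                 seed = as.integer(seed)),
            class = "run_config")
}

.mod_to_list <- function(m) {
  list(name = m$name, delta = m$delta,
       formula = if (!is.null(m$formula)) m$formula, targets = m$targets)
}

.bridge_to_list <- function(b) {
  list(name = b$name, donors = b$donors, acceptors = b$acceptors,
       formula = if (!is.null(b$formula)) b$formula, delta = b$delta)
}

#' Write a run configuration to JSON
#'
#' All defaults are written out explicitly, so a saved config is a full
#' record of the run.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    digest = unclass(config$digest),
    adduct = .mod_to_list(config$adduct),
    target_residues = config$target_residues,
    fixed_mods = lapply(config$fixed_mods, .mod_to_list),
    variable_mods = lapply(config$variable_mods, .mod_to_list),
    bridges = lapply(unname(config$bridges), .bridge_to_list),
    tol_ppm = config$tol_ppm, parent_tol_ppm = config$parent_tol_ppm,
    frag_tol_da = config$frag_tol_da,
    assigned_fraction_cutoff = config$assigned_fraction_cutoff,
    min_xl_series = config$min_xl_series, top_n = config$top_n,
    fragment_charges = config$fragment_charges,
    require_signature = config$require_signature, seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Inverse of [write_config()]; the round trip is stable.
#' @param path JSON config path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mod <- function(d) {
    modification(d$name, delta = as.numeric(d$delta),
                 formula = if (!is.null(d$formula)) d$formula,
                 targets = unlist(d$targets))
  }
  as_bridge <- function(d) {
    bridge_definition(d$name, unlist(d$donors), unlist(d$acceptors),
                      formula = if (!is.null(d$formula)) d$formula,
                      delta = as.numeric(d$delta))
  }
  bridges <- lapply(x$bridges, as_bridge)
  names(bridges) <- vapply(bridges, `[[`, character(1), "name")
  run_config(
    digest = digest_spec(x$digest$specificity, x$digest$max_missed,
                         unlist(x$digest$length_range)),
    adduct = as_mod(x$adduct),
    target_residues = unlist(x$target_residues),
    fixed_mods = lapply(x$fixed_mods, as_mod),
    variable_mods = lapply(x$variable_mods, as_mod),
    bridges = bridges,
    tol_ppm = x$tol_ppm, parent_tol_ppm = x$parent_tol_ppm,
    frag_tol_da = x$frag_tol_da,
    assigned_fraction_cutoff = x$assigned_fraction_cutoff,
    min_xl_series = x$min_xl_series, top_n = x$top_n,
    fragment_charges = unlist(x$fragment_charges),
    require_signature = x$require_signature, seed = x$seed)
}
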