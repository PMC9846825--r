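# Monoisotopic mass arithmetic: elemental formulas, residues, modified
# peptides, charged-ion m/z, and immonium-derived signature ions.

# Monoisotopic atomic masses (Da). CHNOPS only; average masses unsupported.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

#' Physical constants used throughout
#'
#' Monoisotopic constants for charged-ion arithmetic: the proton mass used
#' for protonation, the neutral masses of water, ammonia, carbon monoxide
#' and ethylene (the last three appear as neutral losses of signature
#' ions), and the CHNOPS monoisotopic atomic mass table.
#'
#' @return Named list with elements `proton`, `water`, `ammonia`, `co`,
#'   `ethylene` (all Da) and `atomic` (named numeric vector of atomic
#'   masses).
#' @examples
#' physical_constants()$water   # 18.010565
#' @export
physical_constants <- function() {
  list(
    proton   = 1.0072765,
    water    = unname(2 * .ATOMIC_MASS["H"] + .ATOMIC_MASS["O"]),
    ammonia  = unname(3 * .ATOMIC_MASS["H"] + .ATOMIC_MASS["N"]),
    co       = unname(.ATOMIC_MASS["C"] + .ATOMIC_MASS["O"]),
    ethylene = unname(2 * .ATOMIC_MASS["C"] + 4 * .ATOMIC_MASS["H"]),
    atomic   = .ATOMIC_MASS
  )
}

.PROTON <- 1.0072765
.WATER  <- unname(2 * .ATOMIC_MASS["H"] + .ATOMIC_MASS["O"])

#' Parse an elemental formula string
#'
#' Formulas are sequences of element symbols each followed by an optional
#' signed integer count, e.g. `"C4H9O3P"` or `"H-2 O-1"` (spaces optional).
#' Negative counts express mass deficits such as the water loss of a
#' zero-length isopeptide bridge.
#'
#' @param formula Character scalar.
#' @return Named integer vector of element counts (repeated symbols are
#'   summed).
#' @examples
#' parse_formula("C4H9O3P")
#' parse_formula("H-2 O-1")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  if (s == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (sum(nchar(tokens)) != nchar(s)) {
    stop("malformed elemental formula: '", formula, "'", call. = FALSE)
  }
  elems <- sub("^([A-Z][a-z]?).*$", "\\1", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  if (anyNA(counts)) {
    stop("malformed elemental formula: '", formula, "'", call. = FALSE)
  }
  bad <- setdiff(unique(elems), names(.ATOMIC_MASS))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- tapply(counts, elems, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Either a formula string (see [parse_formula()]) or a
#'   named numeric vector of element counts. Counts may be negative.
#' @return Signed monoisotopic mass in Da; `0` for the empty formula.
#' @examples
#' formula_mass("C4H9O3P")  # 136.0289, the diethyl phosphate adduct
#' formula_mass("H-2 O-1")  # -18.0106, the isopeptide bridge
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  bad <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(unname(formula) * .ATOMIC_MASS[names(formula)])
}

# Residue elemental compositions (the residue, i.e. amino acid minus water).
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, formula_mass, numeric(1))

#' Monoisotopic residue masses
#'
#' @return Named numeric vector over the 20 standard residue letters
#'   (residue = amino acid minus water), in Da.
#' @export
residue_masses <- function() .RESIDUE_MASS

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide/protein sequence", call. = FALSE)
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters), names(.RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  letters
}

#' Define a mass modification
#'
#' A modification carries a name, a monoisotopic mass delta, optionally an
#' elemental formula, and the set of residue letters it may sit on. When
#' both `delta` and `formula` are supplied they must agree within 1e-4 Da.
#'
#' @param name Modification name.
#' @param delta Monoisotopic mass shift in Da (optional if `formula` given).
#' @param formula Elemental formula string or named count vector (optional).
#' @param targets Character vector of residue letters the modification may
#'   be placed on.
#' @return Object of class `modification`.
#' @seealso [mod_dep()], [mod_oxidation()], [mod_carbamidomethyl()]
#' @export
modification <- function(name, delta = NULL, formula = NULL,
                         targets = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(delta) && is.null(formula)) {
    stop("modification needs a delta or a formula", call. = FALSE)
  }
  fmass <- if (!is.null(formula)) formula_mass(formula) else NULL
  if (is.null(delta)) delta <- fmass
  if (!is.null(fmass) && abs(delta - fmass) > 1e-4) {
    stop("modification '", name, "': delta ", delta,
         " disagrees with formula mass ", fmass, call. = FALSE)
  }
  structure(
    list(name = name, delta = delta, formula = formula,
         targets = toupper(as.character(targets))),
    class = "modification"
  )
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s %+0.4f Da on {%s}\n",
              x$name, x$delta, paste(x$targets, collapse = "")))
  invisible(x)
}

#' Diethyl phosphate (Dep) adduct, +136.0289 Da
#'
#' The covalent adduct left by chlorpyrifos oxon on nucleophilic side
#' chains: diethyl phosphate minus the proton lost from the nucleophile,
#' composition C4H9O3P. Eligible residues default to the full searched set
#' E, D, K, Y, S, T, H, R.
#'
#' @param targets Residue letters the adduct may be placed on.
#' @return A `modification`.
#' @export
mod_dep <- function(targets = c("E", "D", "K", "Y", "S", "T", "H", "R")) {
  modification("Dep", formula = "C4H9O3P", targets = targets)
}

#' Methionine oxidation (+15.9949 Da)
#' @return A `modification`.
#' @export
mod_oxidation <- function() modification("Oxidation", formula = "O", targets = "M")

#' Carbamidomethyl-cysteine (+57.0215 Da)
#'
#' Fixed modification from iodoacetamide alkylation.
#' @return A `modification`.
#' @export
mod_carbamidomethyl <- function() {
  modification("Carbamidomethyl", formula = "C2H3NO", targets = "C")
}

#' Load modification definitions from a JSON config
#'
#' Each entry is an object with `name`, `targets`, and `formula` and/or
#' `delta`.
#'
#' @param path Path to a JSON file containing an array of definitions.
#' @return List of `modification` objects, named by modification name.
#' @export
read_modifications <- function(path) {
  defs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(defs, function(d) {
    modification(d$name,
                 delta = if (!is.null(d$delta)) as.numeric(d$delta),
                 formula = if (!is.null(d$formula)) d$formula,
                 targets = unlist(d$targets))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Construct a modified peptide
#'
#' The unit of all mass arithmetic: a residue sequence over the 20
#' standard letters plus zero or more positioned modifications. At most one
#' modification per position; each modification must target the residue at
#' its position.
#'
#' @param sequence Peptide sequence (character scalar).
#' @param mods List of `list(pos = <1-based index>, mod = <modification>)`.
#' @return Object of class `modified_peptide` with fields `sequence`,
#'   `residues` (letter vector) and `mods`.
#' @examples
#' modified_peptide("AFVHWYVGEGMEEGEFSEAR",
#'                  mods = list(list(pos = 9, mod = mod_dep()),
#'                              list(pos = 11, mod = mod_oxidation())))
#' @export
modified_peptide <- function(sequence, mods = list()) {
  if (inherits(sequence, "modified_peptide")) return(sequence)
  residues <- .check_sequence(sequence)
  n <- length(residues)
  if (length(mods)) {
    pos <- vapply(mods, function(m) as.integer(m$pos), integer(1))
    if (any(pos < 1L | pos > n)) {
      stop("modification position outside sequence", call. = FALSE)
    }
    if (anyDuplicated(pos)) {
      stop("more than one modification at a position", call. = FALSE)
    }
    for (m in mods) {
      res <- residues[m$pos]
      if (length(m$mod$targets) && !(res %in% m$mod$targets)) {
        stop("modification '", m$mod$name, "' does not target residue ",
             res, " at position ", m$pos, call. = FALSE)
      }
    }
    mods <- lapply(mods[order(pos)],
                   function(m) list(pos = as.integer(m$pos), mod = m$mod))
  }
  structure(list(sequence = sequence, residues = residues, mods = mods),
            class = "modified_peptide")
}

#' @export
print.modified_peptide <- function(x, ...) {
  ann <- vapply(x$mods, function(m) {
    sprintf("%s@%d", m$mod$name, m$pos)
  }, character(1))
  cat(sprintf("<modified_peptide> %s%s  M = %.4f Da\n", x$sequence,
              if (length(ann)) paste0(" [", paste(ann, collapse = ", "), "]") else "",
              peptide_mass(x)))
  invisible(x)
}

# Per-position mass vector: residue mass + modification delta at each index.
.position_masses <- function(p) {
  m <- unname(.RESIDUE_MASS[p$residues])
  for (mod in p$mods) m[mod$pos] <- m[mod$pos] + mod$mod$delta
  m
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Residue-mass sum plus one water plus all modification deltas.
#'
#' @param p A `modified_peptide` or bare sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("STKSPR")   # 674.3711
#' @export
peptide_mass <- function(p) {
  p <- modified_peptide(p)
  sum(.position_masses(p)) + .WATER
}

#' m/z of a protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge (number of protons).
#' @return `(neutral_mass + charge * proton) / charge`.
#' @examples
#' mz_from_mass(2478.1299, 3)   # 827.0506, an MH3+ ion
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  stopifnot(is.numeric(neutral_mass), is.numeric(charge))
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (neutral_mass + charge * .PROTON) / charge
}

#' Neutral mass from an observed m/z and charge
#'
#' Inverse of [mz_from_mass()].
#' @param mz Observed m/z.
#' @param charge Positive integer charge.
#' @return Neutral monoisotopic mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  stopifnot(is.numeric(mz), is.numeric(charge))
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  mz * charge - charge * .PROTON
}

# Round half up to the nearest integer ("nominal" masses; round() would
# round half to even).
.round_half_up <- function(x) floor(x + 0.5)

#' Immonium ion m/z of a residue
#'
#' Convention: residue mass minus CO plus one proton.
#' @param residue Single residue letter.
#' @return m/z of the singly charged immonium ion.
#' @export
immonium_mz <- function(residue) {
  residue <- toupper(residue)
  if (!residue %in% names(.RESIDUE_MASS)) {
    stop("unknown residue letter: ", residue, call. = FALSE)
  }
  pc <- physical_constants()
  unname(.RESIDUE_MASS[residue]) - pc$co + pc$proton
}

#' Signature (diagnostic) ions of an adduct-bearing residue
#'
#' Low-mass diagnostic ions for diethyl phosphate adducts on lysine,
#' tyrosine or glutamate: the immonium ion plus the adduct delta, followed
#' by characteristic neutral losses. Lysine loses ammonia (giving nominal
#' masses 237 and 220 for Dep-K); tyrosine and glutamate lose one or two
#' ethylenes, each optionally with water (Dep-Y: 272, 244, 226, 216, 198;
#' Dep-E: 238, 210, 192, 182, 164).
#'
#' @param residue One of `"K"`, `"Y"`, `"E"`.
#' @param adduct A `modification`; defaults to [mod_dep()].
#' @return `data.frame` with columns `label`, `mz` (exact) and `nominal`
#'   (integer, rounded half-up).
#' @examples
#' signature_ions("K")$nominal   # 237 220
#' @export
signature_ions <- function(residue, adduct = mod_dep()) {
  residue <- toupper(residue)
  if (!residue %in% c("K", "Y", "E")) {
    stop("signature ions supported for K, Y and E only", call. = FALSE)
  }
  pc <- physical_constants()
  base <- immonium_mz(residue) + adduct$delta
  tag <- paste0("imm(", residue, ")+", adduct$name)
  if (residue == "K") {
    labels <- c(tag, paste0(tag, "-NH3"))
    mz <- c(base, base - pc$ammonia)
  } else {
    losses <- c(0, pc$ethylene, pc$ethylene + pc$water,
                2 * pc$ethylene, 2 * pc$ethylene + pc$water)
    labels <- c(tag, paste0(tag, c("-C2H4", "-C2H4-H2O", "-2C2H4", "-2C2H4-H2O")))
    mz <- base - losses
  }
  data.frame(label = labels, mz = mz, nominal = .round_half_up(mz),
             stringsAsFactors = FALSE)
}
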