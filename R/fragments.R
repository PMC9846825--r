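# Theoretical b/y fragment ions for linear modified peptides and for
# zero-length cross-linked peptide pairs, including the cross-link
# specific ions that carry the intact partner peptide through the bridge.

#' Define a cross-link bridge chemistry
#'
#' A named cross-link: the residue letters eligible on either side and a
#' signed elemental mass delta. The zero-length glutamate-lysine
#' isopeptide bond is `H-2 O-1` (-18.0106 Da, loss of OH from Glu and H
#' from Lys). Orientation is chemical, not positional: a candidate is
#' valid if one linked residue is in the donor set and the other in the
#' acceptor set, in either order.
#'
#' @param name Bridge name.
#' @param donors,acceptors Nonempty character vectors of residue letters.
#' @param formula Elemental formula of the bridge delta (string or named
#'   counts); may have negative counts.
#' @param delta Mass delta in Da; optional if `formula` is given (must
#'   agree within 1e-4 Da when both are supplied).
#' @return Object of class `bridge_definition`.
#' @examples
#' bridge_definition("EK_isopeptide", "E", "K", formula = "H-2 O-1")
#' @export
bridge_definition <- function(name, donors, acceptors, formula = NULL,
                              delta = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  donors <- toupper(as.character(donors))
  acceptors <- toupper(as.character(acceptors))
  if (!length(donors) || !length(acceptors)) {
    stop("donor and acceptor residue sets must be nonempty", call. = FALSE)
  }
  if (is.null(delta) && is.null(formula)) {
    stop("bridge needs a delta or a formula", call. = FALSE)
  }
  fmass <- if (!is.null(formula)) formula_mass(formula) else NULL
  if (is.null(delta)) delta <- fmass
  if (!is.null(fmass) && abs(delta - fmass) > 1e-4) {
    stop("bridge '", name, "': delta disagrees with formula mass",
         call. = FALSE)
  }
  structure(list(name = name, donors = donors, acceptors = acceptors,
                 formula = formula, delta = delta),
            class = "bridge_definition")
}

#' @export
print.bridge_definition <- function(x, ...) {
  cat(sprintf("<bridge> %s  {%s}<->{%s}  %+0.4f Da\n", x$name,
              paste(x$donors, collapse = ""),
              paste(x$acceptors, collapse = ""), x$delta))
  invisible(x)
}

#' Built-in bridge chemistries
#'
#' `EK_isopeptide` is the zero-length glutamate-lysine isopeptide bond
#' (-18.0106 Da). The three `YK_*` bridges are hypothetical
#' tyrosine-lysine chemistries searched as expected-negative modes: loss
#' of water (-18.0106), loss of ammonia (-17.0265), and an
#' ethoxyphosphoryl-containing link (+89.9871 Da, C2H3O2P).
#'
#' @return Named list of `bridge_definition` objects.
#' @export
builtin_bridges <- function() {
  list(
    EK_isopeptide      = bridge_definition("EK_isopeptide", "E", "K",
                                           formula = "H-2 O-1"),
    YK_loss_water      = bridge_definition("YK_loss_water", "Y", "K",
                                           formula = "H-2 O-1"),
    YK_loss_ammonia    = bridge_definition("YK_loss_ammonia", "Y", "K",
                                           formula = "H-3 N-1"),
    YK_ethoxyphosphoryl = bridge_definition("YK_ethoxyphosphoryl", "Y", "K",
                                            formula = "C2H3O2P")
  )
}

#' Load bridge definitions from a JSON config
#'
#' Each entry: `name`, `donors`, `acceptors`, and `formula` and/or `delta`.
#' @param path JSON file with an array of bridge definitions.
#' @return Named list of `bridge_definition` objects.
#' @export
read_bridges <- function(path) {
  defs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(defs, function(d) {
    bridge_definition(d$name, unlist(d$donors), unlist(d$acceptors),
                      formula = if (!is.null(d$formula)) d$formula,
                      delta = if (!is.null(d$delta)) as.numeric(d$delta))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

.site_residue_ok <- function(res_a, res_b, bridge) {
  (res_a %in% bridge$donors && res_b %in% bridge$acceptors) ||
    (res_a %in% bridge$acceptors && res_b %in% bridge$donors)
}

#' Construct a cross-link candidate
#'
#' Two modified peptides joined side chain to side chain at the given
#' 1-based residue indices through a bridge. One linked residue must be in
#' the bridge's donor set and the other in its acceptor set.
#'
#' @param peptide_a,peptide_b `modified_peptide` objects or sequences.
#' @param site_a,site_b 1-based linked-residue indices.
#' @param bridge A `bridge_definition`.
#' @param protein_a,protein_b Optional protein identifiers.
#' @param pos_a,pos_b Optional 1-based protein positions of the linked
#'   residues (e.g. 55 for E55).
#' @return Object of class `crosslink_candidate`.
#' @examples
#' crosslink_candidate("TIGGGDDSFNTFFSETGA", 15, "STKSPR", 3,
#'                     builtin_bridges()$EK_isopeptide)
#' @export
crosslink_candidate <- function(peptide_a, site_a, peptide_b, site_b, bridge,
                                protein_a = NA_character_,
                                protein_b = NA_character_,
                                pos_a = NA_integer_, pos_b = NA_integer_) {
  stopifnot(inherits(bridge, "bridge_definition"))
  a <- modified_peptide(peptide_a)
  b <- modified_peptide(peptide_b)
  site_a <- as.integer(site_a); site_b <- as.integer(site_b)
  if (site_a < 1L || site_a > length(a$residues) ||
      site_b < 1L || site_b > length(b$residues)) {
    stop("linked-site index outside peptide sequence", call. = FALSE)
  }
  if (!.site_residue_ok(a$residues[site_a], b$residues[site_b], bridge)) {
    stop("linked residues ", a$residues[site_a], "/", b$residues[site_b],
         " not eligible for bridge '", bridge$name, "'", call. = FALSE)
  }
  structure(list(peptide_a = a, site_a = site_a,
                 peptide_b = b, site_b = site_b, bridge = bridge,
                 protein_a = protein_a, protein_b = protein_b,
                 pos_a = as.integer(pos_a), pos_b = as.integer(pos_b)),
            class = "crosslink_candidate")
}

#' @export
print.crosslink_candidate <- function(x, ...) {
  cat(sprintf("<crosslink> %s(%s%d) x %s(%s%d) via %s  M = %.4f Da\n",
              x$peptide_a$sequence, x$peptide_a$residues[x$site_a], x$site_a,
              x$peptide_b$sequence, x$peptide_b$residues[x$site_b], x$site_b,
              x$bridge$name, crosslink_mass(x)))
  invisible(x)
}

#' Neutral mass of a cross-linked pair
#'
#' `mass(a) + mass(b) + bridge delta`; for the isopeptide bridge this is
#' the sum of the peptide masses minus one water.
#' @param x A `crosslink_candidate`.
#' @return Neutral monoisotopic mass in Da.
#' @export
crosslink_mass <- function(x) {
  stopifnot(inherits(x, "crosslink_candidate"))
  peptide_mass(x$peptide_a) + peptide_mass(x$peptide_b) + x$bridge$delta
}

#' Precursor m/z of a cross-linked pair
#'
#' @param x A `crosslink_candidate`.
#' @param charge Positive integer precursor charge.
#' @return m/z of the MHz+ precursor ion.
#' @examples
#' x <- crosslink_candidate("TIGGGDDSFNTFFSETGA", 15, "STKSPR", 3,
#'                          builtin_bridges()$EK_isopeptide)
#' crosslink_precursor_mz(x, 3)   # 827.0506
#' @export
crosslink_precursor_mz <- function(x, charge) {
  mz_from_mass(crosslink_mass(x), charge)
}

.empty_ion_table <- function() {
  data.frame(peptide = character(0), series = character(0),
             index = integer(0), charge = integer(0), mz = numeric(0),
             carries_bridge = logical(0), stringsAsFactors = FALSE)
}

# Neutral b/y fragment masses of one peptide given its per-position mass
# vector. Returns list(b = <n-1 vector>, y = <n-1 vector>).
.neutral_fragments <- function(pos_masses) {
  n <- length(pos_masses)
  cs <- cumsum(pos_masses)
  # y_i sums the last i position masses
  list(b = cs[-n], y = cumsum(rev(pos_masses))[-n] + .WATER)
}

#' Theoretical b/y ions of a linear modified peptide
#'
#' b_i is the sum of the first i position masses (residue + any
#' modification delta) plus protons; y_i the sum of the last i plus water
#' plus protons. A diethyl phosphate adduct inside a fragment's span
#' shifts that fragment by +136.0289 Da, which is what localizes the site.
#'
#' @param p `modified_peptide` or sequence (length >= 2).
#' @param charges Integer vector of fragment charges (nonempty, positive).
#' @param series Subset of `c("b", "y")`.
#' @return `data.frame` with columns `peptide` (`"sole"`), `series`,
#'   `index`, `charge`, `mz`, `carries_bridge` (all `FALSE`);
#'   `(n-1) * |series| * |charges|` rows.
#' @examples
#' ions <- linear_fragment_ions("STKSPR", charges = 1)
#' subset(ions, series == "y" & index == 1)$mz   # 175.1190
#' @export
linear_fragment_ions <- function(p, charges = c(1L, 2L), series = c("b", "y")) {
  p <- modified_peptide(p)
  n <- length(p$residues)
  if (n < 2L) stop("peptide must have at least 2 residues", call. = FALSE)
  charges <- as.integer(charges)
  if (!length(charges) || any(charges < 1L)) {
    stop("charges must be a nonempty set of positive integers", call. = FALSE)
  }
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  frags <- .neutral_fragments(.position_masses(p))
  out <- list()
  for (s in series) {
    neutral <- frags[[s]]
    for (z in charges) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = "sole", series = s, index = seq_len(n - 1L), charge = z,
        mz = (neutral + z * .PROTON) / z, carries_bridge = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Theoretical ions of a cross-linked peptide pair
#'
#' For each peptide of the pair, fragments whose residue span excludes the
#' linked site are ordinary linear b/y ions; fragments spanning the linked
#' site additionally carry the partner peptide plus the bridge delta and
#' are flagged `carries_bridge` (the cross-link specific ions, which
#' contain sequence from both peptides).
#'
#' @param x A `crosslink_candidate`.
#' @param charges Integer vector of fragment charges; empty gives an empty
#'   table.
#' @param series Subset of `c("b", "y")`.
#' @return `data.frame` as in [linear_fragment_ions()], with `peptide` in
#'   `c("a", "b")`.
#' @export
crosslink_fragment_ions <- function(x, charges = c(1L, 2L),
                                    series = c("b", "y")) {
  stopifnot(inherits(x, "crosslink_candidate"))
  charges <- as.integer(charges)
  if (!length(charges)) return(.empty_ion_table())
  if (any(charges < 1L)) stop("charges must be positive", call. = FALSE)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  members <- list(
    list(label = "a", self = x$peptide_a, site = x$site_a, partner = x$peptide_b),
    list(label = "b", self = x$peptide_b, site = x$site_b, partner = x$peptide_a)
  )
  out <- list()
  for (m in members) {
    n <- length(m$self$residues)
    if (n < 2L) next
    frags <- .neutral_fragments(.position_masses(m$self))
    partner_add <- peptide_mass(m$partner) + x$bridge$delta
    for (s in series) {
      idx <- seq_len(n - 1L)
      spans_site <- if (s == "b") idx >= m$site else idx >= (n - m$site + 1L)
      neutral <- frags[[s]] + ifelse(spans_site, partner_add, 0)
      for (z in charges) {
        out[[length(out) + 1L]] <- data.frame(
          peptide = m$label, series = s, index = idx, charge = z,
          mz = (neutral + z * .PROTON) / z, carries_bridge = spans_site,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_ion_table())
  do.call(rbind, out)
}

#' Write an ion table as tab-separated text
#'
#' @param ions Ion `data.frame` from [linear_fragment_ions()] or
#'   [crosslink_fragment_ions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(ions, path) {
  utils::write.table(ions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
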