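# Functional-group catalogues.
#
# The published table of SMARTS definitions renders double-bond characters
# as inline glyphs, which are lost in plain-text copies; the strings below
# restore the '=' bonds so every carbonyl-bearing definition matches real
# carbonyls. The alkene row is corrupted beyond certain reconstruction: the
# chemically sensible reading "[CX3]=[CX3]" is the default, and the literal
# two-connected reading "[$([CX2]=[X2])]" is available via
# `alkene_variant = "two_connected"` (the two differ only on cumulated or
# otherwise exotic double bonds).

fg_defs_original <- function(alkene_smarts) data.frame(
  name = c("alkane", "alkene", "alkyne", "arene", "ketone", "ester", "amide",
           "carboxylic_acid", "alcohol", "amine", "nitrile", "alkyl_halide",
           "acyl_halide"),
  smarts = c(
    "[CX4]",
    alkene_smarts,
    "[$([CX2]#C)]",
    "[c]",
    "[#6][CX3](=O)[#6]",
    "[#6][CX3](=O)[OX2H0][#6]",
    "[NX3][CX3](=[OX1])[#6]",
    "[CX3](=O)[OX2H1]",
    "[CHX4][OX2H]",
    "[NX3;H2,H1;!$(NCO)]",
    "[NX1]#[CX2]",
    "[CX4][F,Cl,Br,I]",
    "[CX3](=[OX1])[F,Cl,Br,I]"),
  stringsAsFactors = FALSE)

#' Functional-group definition catalogue
#'
#' Returns the ordered catalogue of functional-group definitions (name +
#' SMARTS pattern) that fixes the label-vector order for every downstream
#' label matrix. Two definition sets are available:
#' \describe{
#'   \item{\code{"original_13"}}{13 groups: alkane, alkene, alkyne, arene,
#'     ketone, ester, amide, carboxylic acid, alcohol, amine, nitrile,
#'     alkyl halide, acyl halide.}
#'   \item{\code{"extended_16"}}{the same set with the alkane definition
#'     narrowed to exclude methyl carbons (\code{[CX4;H0,H1,H2]}) plus three
#'     additional groups: ether, nitro and methyl.}
#' }
#'
#' @param set \code{"original_13"} or \code{"extended_16"}.
#' @param alkene_variant \code{"three_connected"} (default,
#'   \code{[CX3]=[CX3]}) or \code{"two_connected"}
#'   (\code{[$([CX2]=[X2])]}); see the source comment for why both exist.
#' @param include_aldehyde add an optional aldehyde group
#'   (\code{[CX3H1](=O)[#6]}); off by default.
#' @return data frame of class \code{fg_catalogue} with columns \code{name},
#'   \code{smarts}, \code{definition_set}. Row order defines label order.
#' @examples
#' fg_catalogue("original_13")$name
#' @export
fg_catalogue <- function(set = c("original_13", "extended_16"),
                         alkene_variant = c("three_connected", "two_connected"),
                         include_aldehyde = FALSE) {
  set <- match.arg(set)
  alkene_variant <- match.arg(alkene_variant)
  alkene_smarts <- if (alkene_variant == "three_connected") "[CX3]=[CX3]"
                   else "[$([CX2]=[X2])]"
  defs <- fg_defs_original(alkene_smarts)
  if (set == "extended_16") {
    defs$smarts[defs$name == "alkane"] <- "[CX4;H0,H1,H2]"
    defs <- rbind(defs, data.frame(
      name = c("ether", "nitro", "methyl"),
      smarts = c("[OD2]([#6])[#6]",
                 "[$([NX3](=O)=O),$([NX3+](=O)[O-])][!#8]",
                 "[CH3X4]"),
      stringsAsFactors = FALSE))
  }
  if (include_aldehyde)
    defs <- rbind(defs, data.frame(name = "aldehyde",
                                   smarts = "[CX3H1](=O)[#6]",
                                   stringsAsFactors = FALSE))
  defs$definition_set <- set
  validate_catalogue(defs)
  class(defs) <- c("fg_catalogue", "data.frame")
  defs
}

# SMARTS patterns are validated once, at catalogue construction / load time,
# so bad patterns fail loudly before any matching happens.
validate_catalogue <- function(defs) {
  stopifnot(is.data.frame(defs),
            all(c("name", "smarts") %in% names(defs)))
  if (anyDuplicated(defs$name))
    stop("fg_catalogue: duplicate group names: ",
         paste(unique(defs$name[duplicated(defs$name)]), collapse = ", "))
  for (i in seq_len(nrow(defs))) {
    ok <- tryCatch({
      ChemmineOB::forEachMol("SMILES", "C", function(mol)
        ChemmineOB::smartsSearch_OB(list(mol), defs$smarts[i],
                                    uniqueMatches = FALSE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop("fg_catalogue: SMARTS for group '", defs$name[i],
           "' does not parse: ", defs$smarts[i])
  }
  invisible(defs)
}

#' Read a functional-group catalogue from CSV
#'
#' Expects columns \code{name}, \code{smarts} and optionally
#' \code{definition_set}; every SMARTS pattern is validated at load time.
#' @param path CSV file path.
#' @return an \code{fg_catalogue} data frame.
#' @export
read_catalogue <- function(path) {
  defs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(defs$definition_set)) defs$definition_set <- "custom"
  validate_catalogue(defs)
  class(defs) <- c("fg_catalogue", "data.frame")
  defs
}

#' Write a functional-group catalogue to CSV
#' @param defs an \code{fg_catalogue}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_catalogue <- function(defs, path) {
  utils::write.csv(as.data.frame(defs)[, c("name", "smarts", "definition_set")],
                   path, row.names = FALSE)
  invisible(path)
}
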