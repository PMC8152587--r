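#' Multi-label vector over a functional-group catalogue
#'
#' @param groups character vector of group names (fixed catalogue order).
#' @param bits 0/1 (or logical) vector aligned with \code{groups}.
#' @return object of class \code{label_vector}: a named integer 0/1 vector.
#' @export
label_vector <- function(groups, bits) {
  groups <- as.character(groups)
  bits <- as.integer(bits)
  if (length(groups) != length(bits))
    stop("label_vector: groups and bits lengths differ")
  if (any(!bits %in% c(0L, 1L))) stop("label_vector: bits must be 0/1")
  structure(stats::setNames(bits, groups), class = "label_vector")
}

#' Label vector from a set of present group names
#' @param present character vector naming the groups that are present.
#' @param groups full ordered catalogue of group names.
#' @return a [label_vector()].
#' @export
label_from_set <- function(present, groups) {
  unknown <- setdiff(present, groups)
  if (length(unknown))
    stop("label_from_set: groups not in catalogue: ",
         paste(unknown, collapse = ", "))
  label_vector(groups, as.integer(groups %in% present))
}

#' @export
print.label_vector <- function(x, ...) {
  on <- names(x)[x == 1L]
  cat("<label_vector> {", paste(on, collapse = ", "), "} of ",
      length(x), " groups\n", sep = "")
  invisible(x)
}

# Parse a SMILES or InChI string into an OpenBabel molecule and apply `f`.
# InChI input (detected by its "InChI=" prefix) is converted to SMILES first
# because the stream reader only accepts SMILES input reliably.
with_molecule <- function(structure, f) {
  stopifnot(is.character(structure), length(structure) == 1L)
  smi <- structure
  if (grepl("^InChI=", structure)) {
    smi <- tryCatch(ChemmineOB::convertFormat("INCHI", "SMI", structure),
                    error = function(e) "")
    smi <- trimws(sub("\t.*$", "", smi))
    if (!nzchar(smi))
      stop("assign_groups: unparseable InChI: ", structure)
  }
  out <- NULL
  got <- FALSE
  tryCatch(
    ChemmineOB::forEachMol("SMILES", smi, function(mol) {
      if (!got) { out <<- f(mol); got <<- TRUE }
    }),
    error = function(e)
      stop("assign_groups: unparseable structure: ", structure,
           " (", conditionMessage(e), ")", call. = FALSE))
  if (!got) stop("assign_groups: unparseable structure: ", structure)
  out
}

#' Assign functional-group labels to a molecular structure
#'
#' Performs independent SMARTS substructure matching of every catalogue
#' definition against the molecule: bit i is 1 iff definition i has at least
#' one substructure match. Because each pattern is tested independently, a
#' molecule can (and usually does) carry several labels. A molecule matching
#' no definition keeps an all-zero label rather than being rejected.
#'
#' @param structure a SMILES string, or an InChI string (detected by its
#'   \code{"InChI="} prefix).
#' @param defs an [fg_catalogue()] (or any data frame with \code{name} and
#'   \code{smarts} columns).
#' @return a [label_vector()] in catalogue order.
#' @examples
#' \donttest{
#' assign_groups("CC(=O)C", fg_catalogue("original_13"))  # alkane + ketone
#' }
#' @export
assign_groups <- function(structure, defs) {
  stopifnot(is.data.frame(defs))
  bits <- with_molecule(structure, function(mol) {
    vapply(defs$smarts, function(s)
      ChemmineOB::smartsSearch_OB(list(mol), s, uniqueMatches = FALSE) > 0,
      logical(1), USE.NAMES = FALSE)
  })
  label_vector(defs$name, as.integer(bits))
}

#' Label matrix for a vector of structures
#'
#' @param structures character vector of SMILES/InChI strings.
#' @param defs an [fg_catalogue()].
#' @return integer 0/1 matrix, one row per structure, columns named by group.
#' @export
assign_groups_matrix <- function(structures, defs) {
  m <- t(vapply(structures, function(s) as.integer(assign_groups(s, defs)),
                integer(nrow(defs))))
  dimnames(m) <- list(names(structures) %||% NULL, defs$name)
  m
}

#' Union of label vectors (mixture ground truth)
#'
#' A mixture carries the set of all functional groups present in any of its
#' components, i.e. the element-wise OR of the members' label vectors.
#'
#' @param members list of [label_vector()]s over the same catalogue.
#' @return a [label_vector()].
#' @export
union_labels <- function(members) {
  stopifnot(is.list(members), length(members) >= 1L)
  g <- names(members[[1]])
  for (m in members) {
    if (!identical(names(m), g))
      stop("union_labels: members use different group catalogues")
  }
  bits <- Reduce(`|`, lapply(members, function(m) as.integer(m) == 1L))
  label_vector(g, as.integer(bits))
}
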