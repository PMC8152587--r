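#' Assemble a labeled dataset from a manifest of spectra
#'
#' Reads the spectra listed in a manifest, standardizes them onto the given
#' grids, assigns functional-group labels, and returns the aligned feature
#' and label matrices used for training. In \code{"FTIR_MS"} mode the two
#' standardized vectors are concatenated \code{[FTIR || MS]} and the named
#' \code{feature_blocks} record which columns belong to which technique.
#'
#' The manifest is a data frame (or CSV path) with columns
#' \code{compound_id}, \code{ftir_path}, \code{ms_path} and either a
#' \code{structure} column (SMILES/InChI, labeled via [assign_groups()]
#' against \code{defs}) or no structure column, in which case a \code{labels}
#' matrix must be supplied directly (synthetic data ships its truth labels
#' this way). Rows missing a spectrum required by \code{mode} are skipped
#' with a message; duplicate compound ids keep the first occurrence.
#'
#' @param manifest data frame or CSV path (see Details).
#' @param defs an [fg_catalogue()]; required when labels come from structures.
#' @param mode \code{"FTIR"}, \code{"MS"} or \code{"FTIR_MS"}.
#' @param ftir_grid,ms_grid bin grids (defaults: [default_ftir_grid()],
#'   [default_ms_grid()]).
#' @param labels optional 0/1 matrix of known labels with rownames (or row
#'   order) matching the manifest's \code{compound_id}s; overrides
#'   structure-derived labels.
#' @param spectra optional named list, per compound id, of
#'   \code{list(ftir = , ms = )} [raw_spectrum()] objects; when present these
#'   are used instead of reading the manifest's file paths (the in-memory
#'   fast path used by the synthetic generator).
#' @return object of class \code{labeled_dataset}: list with
#'   \code{compound_ids}, \code{features}, \code{labels},
#'   \code{feature_blocks}, \code{mode}, \code{grids}, \code{groups},
#'   \code{folds} (NULL until [assign_folds()] is called).
#' @export
build_dataset <- function(manifest, defs = NULL,
                          mode = c("FTIR_MS", "FTIR", "MS"),
                          ftir_grid = default_ftir_grid(),
                          ms_grid = default_ms_grid(),
                          labels = NULL, spectra = NULL) {
  mode <- match.arg(mode)
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(manifest), "compound_id" %in% names(manifest))
  manifest$compound_id <- as.character(manifest$compound_id)
  if (anyDuplicated(manifest$compound_id)) {
    message("build_dataset: dropping ",
            sum(duplicated(manifest$compound_id)),
            " duplicate compound id(s), keeping first occurrence")
    manifest <- manifest[!duplicated(manifest$compound_id), ]
  }
  need_ftir <- mode %in% c("FTIR", "FTIR_MS")
  need_ms <- mode %in% c("MS", "FTIR_MS")

  if (is.null(labels)) {
    if (is.null(defs) || is.null(manifest$structure))
      stop("build_dataset: need either a 'structure' manifest column plus ",
           "defs, or an explicit labels matrix")
    labels <- assign_groups_matrix(
      stats::setNames(manifest$structure, manifest$compound_id), defs)
    groups <- defs$name
  } else {
    labels <- as.matrix(labels)
    groups <- colnames(labels)
    if (is.null(groups)) stop("build_dataset: labels matrix must have column names")
    if (!is.null(rownames(labels))) {
      miss <- setdiff(manifest$compound_id, rownames(labels))
      if (length(miss))
        stop("build_dataset: labels missing for ", length(miss), " compound(s)")
      labels <- labels[manifest$compound_id, , drop = FALSE]
    } else if (nrow(labels) != nrow(manifest)) {
      stop("build_dataset: unnamed labels matrix must match manifest rows")
    }
  }

  get_spec <- function(id, row, which) {
    if (!is.null(spectra)) return(spectra[[id]][[which]])
    col <- paste0(which, "_path")
    p <- if (col %in% names(manifest)) row[[col]] else NA
    if (is.null(p) || is.na(p) || !nzchar(p) || !file.exists(p)) return(NULL)
    read_jcamp(p, compound_id = id)
  }

  rows <- list(); ids <- character(0); skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$compound_id[i]
    f_raw <- if (need_ftir) get_spec(id, manifest[i, , drop = FALSE], "ftir") else NULL
    m_raw <- if (need_ms) get_spec(id, manifest[i, , drop = FALSE], "ms") else NULL
    if ((need_ftir && is.null(f_raw)) || (need_ms && is.null(m_raw))) {
      message("build_dataset: skipping '", id, "' (missing ",
              if (need_ftir && is.null(f_raw)) "FTIR" else "MS", " spectrum)")
      skipped <- skipped + 1L
      next
    }
    feat <- c(if (need_ftir) standardize_ftir(f_raw, ftir_grid)$values,
              if (need_ms) standardize_ms(m_raw, ms_grid)$values)
    rows[[length(rows) + 1L]] <- feat
    ids <- c(ids, id)
  }
  if (length(rows) == 0L)
    stop("build_dataset: no usable rows (", skipped, " skipped)")
  features <- do.call(rbind, rows)
  rownames(features) <- ids
  nf <- if (need_ftir) ftir_grid$n_bins else 0L
  nm <- if (need_ms) ms_grid$n_bins else 0L
  blocks <- list()
  if (need_ftir) blocks$FTIR <- c(1L, nf)
  if (need_ms) blocks$MS <- c(nf + 1L, nf + nm)
  labels <- labels[match(ids, manifest$compound_id), , drop = FALSE]
  rownames(labels) <- ids
  structure(list(compound_ids = ids, features = features,
                 labels = labels, feature_blocks = blocks, mode = mode,
                 grids = list(FTIR = if (need_ftir) ftir_grid,
                              MS = if (need_ms) ms_grid),
                 groups = groups, folds = NULL),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d compounds x %d features (%s), %d groups%s\n",
              nrow(x$features), ncol(x$features), x$mode, ncol(x$labels),
              if (is.null(x$folds)) "" else sprintf(", %d folds",
                                                    length(unique(x$folds)))))
  invisible(x)
}

#' Assign cross-validation folds
#'
#' Plain random (non-stratified) assignment of each compound to one of
#' \code{k} folds, balanced to within one compound, deterministic given
#' \code{seed}. Optional label-aware stratification keeps each group's
#' prevalence roughly even across folds by randomizing within label-pattern
#' strata.
#'
#' @param dataset a \code{labeled_dataset}.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @param stratify stratify by label pattern (default FALSE).
#' @return the dataset with \code{folds} set (integers in \code{0:(k-1)}).
#' @export
assign_folds <- function(dataset, k = 5L, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$features)
  if (k < 2L) stop("assign_folds: k must be at least 2")
  if (k > n) stop("assign_folds: k = ", k, " exceeds n = ", n, " compounds")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (!stratify) {
    folds <- sample(rep(seq_len(k) - 1L, length.out = n))
  } else {
    pattern <- apply(dataset$labels, 1, paste, collapse = "")
    folds <- integer(n)
    for (p in unique(pattern)) {
      ii <- which(pattern == p)
      folds[ii] <- sample(rep(seq_len(k) - 1L, length.out = length(ii)))
    }
  }
  dataset$folds <- folds
  dataset
}

# Seed scoping helpers: run seeded code without clobbering the caller's RNG.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Save an assembled dataset to a columnar file with a JSON sidecar
#'
#' The feature and label matrices round-trip through one CSV; the sidecar
#' records the mode, grids, group catalogue order, feature blocks and fold
#' assignment, so [load_dataset()] reconstructs the object exactly.
#'
#' @param dataset a \code{labeled_dataset}.
#' @param path CSV path; the sidecar is written to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(compound_id = dataset$compound_ids,
                   dataset$features,
                   dataset$labels, check.names = FALSE)
  names(df) <- c("compound_id",
                 paste0("f", seq_len(ncol(dataset$features))),
                 paste0("label.", colnames(dataset$labels)))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(mode = dataset$mode,
               grids = lapply(dataset$grids,
                              function(g) if (!is.null(g)) unclass(g)),
               groups = dataset$groups,
               feature_blocks = dataset$feature_blocks,
               folds = dataset$folds)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a dataset written by [save_dataset()]
#' @param path CSV path given to [save_dataset()].
#' @return a \code{labeled_dataset}.
#' @export
load_dataset <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df$compound_id)
  lab_cols <- grep("^label\\.", names(df))
  labels <- as.matrix(df[lab_cols])
  colnames(labels) <- sub("^label\\.", "", names(df)[lab_cols])
  features <- as.matrix(df[-c(1L, lab_cols)])
  rownames(features) <- ids
  rownames(labels) <- ids
  colnames(features) <- NULL
  grids <- lapply(side$grids, function(g)
    if (!is.null(g) && length(g) >= 3L)
      bin_grid(as.numeric(g$low), as.numeric(g$high), as.numeric(g$width)))
  blocks <- lapply(side$feature_blocks, as.integer)
  structure(list(compound_ids = ids, features = features, labels = labels,
                 feature_blocks = blocks, mode = side$mode,
                 grids = grids, groups = side$groups,
                 folds = if (length(side$folds)) as.integer(side$folds)),
            class = "labeled_dataset")
}

#' Rows of a dataset as a (features, labels) pair
#' @param dataset a \code{labeled_dataset}.
#' @param rows integer or logical row index.
#' @return list with \code{features} and \code{labels} matrices.
#' @export
dataset_rows <- function(dataset, rows) {
  list(features = dataset$features[rows, , drop = FALSE],
       labels = dataset$labels[rows, , drop = FALSE])
}
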