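#' Default infrared band table for the synthetic generator
#'
#' Gaussian absorption dips per functional group, at the band positions
#' standard correlation charts place them (alkane C-H near 3000 cm^-1,
#' arene ring modes at 1400-1600 cm^-1, the alkene bend near 900 cm^-1,
#' C-O stretching near 1150 cm^-1, carbonyl stretching at 1600-1750 cm^-1,
#' O-H stretching near 3500 cm^-1, the nitrile band at 2210-2260 cm^-1 and
#' the twin nitro bands near 1520/1350 cm^-1). \code{width} is the Gaussian
#' standard deviation in cm^-1, \code{depth} the dip below the unit
#' transmittance baseline, and \code{presence_probability} the chance the
#' band appears when its group is present.
#'
#' @return data frame with columns \code{group}, \code{center},
#'   \code{width}, \code{depth}, \code{presence_probability}.
#' @export
default_band_table <- function() {
  b <- function(group, center, width, depth, p = 1)
    data.frame(group = group, center = center, width = width, depth = depth,
               presence_probability = p)
  rbind(
    b("alkane", 2930, 30, 0.85), b("alkane", 2870, 25, 0.50),
    b("alkane", 1460, 20, 0.40),
    b("arene", 1500, 15, 0.70), b("arene", 1600, 12, 0.50),
    b("arene", 3030, 15, 0.30), b("arene", 750, 15, 0.40),
    b("alkene", 910, 12, 0.60), b("alkene", 1640, 12, 0.45),
    b("alkene", 3080, 12, 0.30),
    b("ether", 1120, 25, 0.80),
    b("carbonyl", 1715, 15, 0.90),
    b("alcohol", 3450, 80, 0.70), b("alcohol", 1050, 20, 0.45),
    b("nitrile", 2240, 12, 0.60),
    b("nitro", 1520, 14, 0.80), b("nitro", 1350, 14, 0.70),
    b("alkyl_halide", 700, 20, 0.60),
    b("amine", 3350, 40, 0.50), b("amine", 1615, 15, 0.40),
    b("amide", 1660, 18, 0.85), b("amide", 3300, 50, 0.45),
    b("ester", 1735, 14, 0.85), b("ester", 1200, 25, 0.60),
    b("carboxylic_acid", 2950, 200, 0.50), b("carboxylic_acid", 1710, 15, 0.85),
    b("methyl", 1378, 10, 0.50), b("methyl", 2960, 20, 0.60))
}

#' Default EI-MS fragment table for the synthetic generator
#'
#' Characteristic fragment ions (\code{kind = "mz"}, absolute m/z) and
#' neutral losses from the molecular ion (\code{kind = "loss"}) per group,
#' with relative abundances. Halide-bearing groups additionally produce the
#' halogen isotope doublet: an M+2 companion of the molecular ion (and of
#' halogen-retaining fragments) at the configured intensity ratio.
#'
#' @return data frame with columns \code{group}, \code{kind}, \code{mass},
#'   \code{rel}, \code{halogen} (logical: fragment carries the halogen).
#' @export
default_fragment_table <- function() {
  f <- function(group, kind, mass, rel, halogen = FALSE)
    data.frame(group = group, kind = kind, mass = mass, rel = rel,
               halogen = halogen)
  rbind(
    f("alkane", "mz", 43, 60), f("alkane", "mz", 57, 45),
    f("arene", "mz", 91, 60), f("arene", "mz", 77, 50),
    f("alkene", "mz", 41, 50),
    f("ether", "mz", 59, 45), f("ether", "loss", 31, 40),
    f("carbonyl", "mz", 43, 55), f("carbonyl", "loss", 43, 35),
    f("alcohol", "loss", 18, 50), f("alcohol", "mz", 31, 40),
    f("nitrile", "loss", 26, 40), f("nitrile", "mz", 52, 20),
    f("nitro", "mz", 30, 50), f("nitro", "mz", 46, 35), f("nitro", "loss", 46, 40),
    f("alkyl_halide", "loss", 35, 45, halogen = FALSE),
    f("amine", "mz", 30, 55), f("amine", "loss", 16, 30),
    f("amide", "mz", 44, 50), f("amide", "loss", 42, 25),
    f("ester", "loss", 31, 40), f("ester", "mz", 43, 30),
    f("carboxylic_acid", "loss", 45, 45), f("carboxylic_acid", "loss", 17, 25),
    f("methyl", "mz", 15, 35), f("methyl", "loss", 15, 45))
}

#' Groups carrying a halogen isotope doublet in the default tables
#' @return character vector.
#' @export
halogen_groups <- function() c("alkyl_halide", "acyl_halide")

#' The eight-group benchmark catalogue of the synthetic generator
#'
#' The default set used by the package's synthetic benchmark: eight groups
#' whose infrared bands span the full mid-IR range with realistic partial
#' overlaps (the 1520 cm^-1 nitro band sits next to the 1500 cm^-1 arene
#' ring mode).
#' @return character vector of group names.
#' @export
benchmark_groups <- function()
  c("alkane", "arene", "alkene", "ether", "carbonyl", "alcohol",
    "nitrile", "nitro")

#' Band windows of each group (for saliency localization checks)
#' @param groups group names.
#' @param band_table a band table (default [default_band_table()]).
#' @param n_sd window half-width in band standard deviations (default 2).
#' @return named list of two-column matrices \code{cbind(low, high)} in
#'   cm^-1, one row per band.
#' @export
band_windows <- function(groups, band_table = default_band_table(),
                         n_sd = 2) {
  stats::setNames(lapply(groups, function(g) {
    bb <- band_table[band_table$group == g, , drop = FALSE]
    cbind(low = bb$center - n_sd * bb$width,
          high = bb$center + n_sd * bb$width)
  }), groups)
}

#' Generate the paired FTIR and EI-MS spectra of one synthetic compound
#'
#' FTIR: a unit transmittance baseline minus one Gaussian dip per band of
#' every present group (each band included with its
#' \code{presence_probability}), plus Gaussian noise, clipped to [0, 1],
#' sampled at the grid's bin centers. EI-MS: a pseudo-molecular ion plus
#' the present groups' characteristic fragments with log-normal abundance
#' jitter; halide groups add the M+2 isotope companion at
#' \code{isotope_ratio}. Fully seeded and deterministic.
#'
#' @param groups a [label_vector()] (or named 0/1 vector) saying which
#'   groups are present; an all-zero vector is allowed and produces a flat
#'   baseline plus molecular ion.
#' @param band_table,fragment_table generator tables (see
#'   [default_band_table()], [default_fragment_table()]).
#' @param noise_sd standard deviation of the FTIR baseline noise (>= 0).
#' @param seed integer seed, or NULL to consume the current RNG stream.
#' @param compound_id identifier for the emitted spectra.
#' @param mol_mass molecular ion m/z; drawn uniformly from 100-400 if NULL.
#' @param ftir_grid,ms_grid grids whose bin centers are sampled.
#' @param sample_every sample the FTIR curve at every k-th bin center
#'   (k > 1 leaves gaps for the spline to fill; default 1).
#' @param isotope_ratio M+2 : M abundance ratio for halogen groups
#'   (default 0.32, the chlorine isotope signature).
#' @return list with elements \code{ftir} and \code{ms}, both
#'   [raw_spectrum()]s, plus \code{mol_mass}.
#' @export
generate_compound <- function(groups,
                              band_table = default_band_table(),
                              fragment_table = default_fragment_table(),
                              noise_sd = 0.02, seed = NULL,
                              compound_id = "synthetic",
                              mol_mass = NULL,
                              ftir_grid = default_ftir_grid(),
                              ms_grid = default_ms_grid(),
                              sample_every = 1L,
                              isotope_ratio = 0.32) {
  if (noise_sd < 0) stop("generate_compound: noise_sd must be non-negative")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  present <- names(groups)[as.integer(groups) == 1L]

  x <- bin_centers(ftir_grid)
  x <- x[seq(1L, length(x), by = sample_every)]
  y <- rep(1, length(x))
  bands <- band_table[band_table$group %in% present, , drop = FALSE]
  for (i in seq_len(nrow(bands))) {
    if (stats::runif(1) > bands$presence_probability[i]) next
    y <- y - bands$depth[i] * exp(-(x - bands$center[i])^2 /
                                    (2 * bands$width[i]^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  y <- pmin(pmax(y, 0), 1)
  ftir <- raw_spectrum(compound_id, "FTIR", x, y, "TRANSMITTANCE")

  if (is.null(mol_mass))
    mol_mass <- sample(100:400, 1L)
  mz <- mol_mass
  ab <- 45
  frs <- fragment_table[fragment_table$group %in% present, , drop = FALSE]
  if (nrow(frs)) {
    fmz <- ifelse(frs$kind == "loss", mol_mass - frs$mass, frs$mass)
    fab <- frs$rel * stats::rlnorm(nrow(frs), meanlog = 0, sdlog = 0.25)
    ok <- fmz >= ms_grid$low & fmz < ms_grid$high
    mz <- c(mz, fmz[ok]); ab <- c(ab, fab[ok])
  }
  if (any(present %in% halogen_groups())) {
    mz <- c(mz, mol_mass + 2)
    ab <- c(ab, 45 * isotope_ratio)
  }
  agg <- tapply(ab, mz, sum)
  ms <- raw_spectrum(compound_id, "MS", as.numeric(names(agg)),
                     as.numeric(agg), "ABUNDANCE")
  list(ftir = ftir, ms = ms, mol_mass = mol_mass)
}

#' Generate a synthetic multi-label spectral dataset
#'
#' Draws each compound's functional groups independently with the requested
#' prevalences, generates the paired FTIR/EI-MS spectra with
#' [generate_compound()], and returns everything needed downstream: an
#' in-memory spectra list, the ground-truth label matrix and a manifest.
#' With \code{dir} set, the spectra are also written as JCAMP-DX files next
#' to a \code{manifest.csv} and \code{labels.csv}, the same on-disk layout
#' user-supplied reference data would use (and a round-trip exercise for
#' the JCAMP reader).
#'
#' @param n number of compounds.
#' @param groups group names (default [benchmark_groups()]).
#' @param prevalences per-group presence probability, recycled (default 0.5).
#' @param noise_sd FTIR noise level (default 0.02).
#' @param seed integer seed governing labels, spectra and jitter.
#' @param dir optional output directory for JCAMP files + manifest.
#' @param ... further arguments passed to [generate_compound()].
#' @return list with \code{manifest} (data frame), \code{labels}
#'   (0/1 matrix), \code{spectra} (named list of \code{list(ftir, ms)}),
#'   \code{groups}, \code{seed}.
#' @export
generate_dataset <- function(n, groups = benchmark_groups(),
                             prevalences = 0.5, noise_sd = 0.02,
                             seed = 1L, dir = NULL, ...) {
  stopifnot(n >= 1L)
  prevalences <- rep_len(prevalences, length(groups))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  labels <- sapply(prevalences, function(p)
    as.integer(stats::runif(n) < p))
  labels <- matrix(labels, nrow = n, dimnames = list(NULL, groups))
  ids <- sprintf("syn%05d", seq_len(n))
  rownames(labels) <- ids
  spectra <- vector("list", n)
  names(spectra) <- ids
  for (i in seq_len(n)) {
    spectra[[i]] <- generate_compound(
      label_vector(groups, labels[i, ]), noise_sd = noise_sd,
      seed = NULL, compound_id = ids[i], ...)
  }
  manifest <- data.frame(compound_id = ids,
                         ftir_path = NA_character_, ms_path = NA_character_,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      fp <- file.path(dir, paste0(ids[i], "_ftir.jdx"))
      mp <- file.path(dir, paste0(ids[i], "_ms.jdx"))
      write_jcamp(spectra[[i]]$ftir, fp)
      write_jcamp(spectra[[i]]$ms, mp)
      manifest$ftir_path[i] <- fp
      manifest$ms_path[i] <- mp
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(compound_id = ids, labels),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  list(manifest = manifest, labels = labels, spectra = spectra,
       groups = groups, seed = seed)
}
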