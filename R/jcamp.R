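#' Read a JCAMP-DX spectrum
#'
#' Parses a single-block JCAMP-DX record into a [raw_spectrum()]. Two data
#' table dialects are supported, which covers the records distributed by
#' public reference collections:
#' \itemize{
#'   \item \code{##XYDATA=(X++(Y..Y))} with plain (AFFN) numbers and evenly
#'     spaced abscissae derived from \code{##FIRSTX/##LASTX/##NPOINTS}
#'     (or \code{##DELTAX});
#'   \item \code{##PEAK TABLE=(XY..XY)} with explicit x,y pairs.
#' }
#' Compressed ASDF encodings (SQZ/DIF/DUP/PAC letter digits) are detected and
#' rejected with an explicit unsupported-dialect error. \code{##XFACTOR} and
#' \code{##YFACTOR} scaling is applied. The technique is inferred from
#' \code{##DATA TYPE} (\code{INFRARED} -> FTIR, \code{MASS} -> MS) and the
#' ordinate unit from \code{##YUNITS}.
#'
#' @param path path to a JCAMP-DX file.
#' @param compound_id identifier for the spectrum; defaults to the record's
#'   \code{##TITLE}, falling back to the file name.
#' @return a [raw_spectrum()].
#' @export
read_jcamp <- function(path, compound_id = NULL) {
  if (!file.exists(path)) stop("read_jcamp: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop("read_jcamp: empty file: ", path)

  is_ldr <- grepl("^\\s*##", lines)
  ldr_at <- which(is_ldr)
  if (length(ldr_at) == 0L)
    stop("read_jcamp: no labelled data records found (not JCAMP-DX?): ", path)

  fields <- list()
  ldr_name <- character(length(ldr_at))
  for (k in seq_along(ldr_at)) {
    ln <- sub("^\\s*##", "", lines[ldr_at[k]])
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) { name <- ln; val <- "" }
    else { name <- substr(ln, 1, eq - 1); val <- substr(ln, eq + 1, nchar(ln)) }
    name <- toupper(gsub("[ _-]", "", name))
    ldr_name[k] <- name
    fields[[name]] <- trimws(val)
  }

  title <- fields[["TITLE"]] %||% ""
  dtype <- toupper(fields[["DATATYPE"]] %||% "")
  technique <-
    if (grepl("INFRARED|IR ", dtype) || grepl("^IR", dtype)) "FTIR"
    else if (grepl("MASS", dtype)) "MS"
    else stop("read_jcamp: cannot infer technique from ##DATA TYPE='",
              dtype, "' in ", path)
  yunits <- toupper(fields[["YUNITS"]] %||% "")
  y_unit <-
    if (grepl("ABSORBANCE", yunits)) "ABSORBANCE"
    else if (technique == "MS") "ABUNDANCE"
    else "TRANSMITTANCE"
  xfactor <- as.numeric(fields[["XFACTOR"]] %||% "1")
  yfactor <- as.numeric(fields[["YFACTOR"]] %||% "1")
  if (!is.finite(xfactor) || !is.finite(yfactor))
    stop("read_jcamp: non-numeric XFACTOR/YFACTOR in ", path)

  table_at <- which(ldr_name %in% c("XYDATA", "PEAKTABLE"))
  if (length(table_at) == 0L)
    stop("read_jcamp: no ##XYDATA or ##PEAK TABLE block in ", path)
  k <- table_at[1]
  block_start <- ldr_at[k]
  block_end <- if (k < length(ldr_at)) ldr_at[k + 1] - 1L else length(lines)
  body <- lines[setdiff(seq.int(block_start + 1L, block_end),
                        which(!nzchar(trimws(lines))))]
  body <- body[!grepl("^\\s*\\$\\$", body)]     # comment lines
  body <- sub("\\$\\$.*$", "", body)            # trailing comments
  body <- trimws(body)
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    stop("read_jcamp: data table under line ", block_start, " of ", path,
         " is empty")
  # ASDF compressed forms use letters as digits; AFFN is plain numbers
  bad <- grep("[A-DF-Za-df-z@%?]", body)
  if (length(bad))
    stop("read_jcamp: unsupported compressed (ASDF) data dialect at line ",
         block_start + bad[1], " of ", path,
         "; only AFFN XYDATA and PEAK TABLE records are supported")

  variable_list <- toupper(gsub("\\s", "", fields[[ldr_name[k]]]))
  if (ldr_name[k] == "XYDATA") {
    if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", variable_list))
      stop("read_jcamp: unsupported XYDATA variable list '",
           fields[["XYDATA"]], "' in ", path)
    npoints <- as.numeric(fields[["NPOINTS"]] %||% NA)
    firstx <- as.numeric(fields[["FIRSTX"]] %||% NA)
    lastx <- as.numeric(fields[["LASTX"]] %||% NA)
    deltax <- as.numeric(fields[["DELTAX"]] %||% NA)
    x <- numeric(0); y <- numeric(0)
    for (i in seq_along(body)) {
      toks <- strsplit(body[i], "[,;[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      vals <- suppressWarnings(as.numeric(toks))
      if (any(is.na(vals)))
        stop("read_jcamp: malformed numeric token in XYDATA at line ",
             block_start + i, " of ", path)
      if (length(vals) < 2L)
        stop("read_jcamp: XYDATA line with no ordinates at line ",
             block_start + i, " of ", path)
      x0 <- vals[1]
      ys <- vals[-1]
      dx <- if (is.finite(deltax)) deltax / xfactor
            else if (is.finite(firstx) && is.finite(lastx) && is.finite(npoints) &&
                     npoints > 1) (lastx - firstx) / xfactor / (npoints - 1)
            else stop("read_jcamp: cannot determine x spacing ",
                      "(need DELTAX or FIRSTX/LASTX/NPOINTS) in ", path)
      x <- c(x, x0 + dx * (seq_along(ys) - 1L))
      y <- c(y, ys)
    }
    if (is.finite(npoints) && length(y) != npoints)
      warning("read_jcamp: NPOINTS=", npoints, " but ", length(y),
              " ordinates parsed in ", path)
  } else {
    if (!grepl("XY\\.\\.XY", variable_list) && nzchar(variable_list))
      stop("read_jcamp: unsupported PEAK TABLE variable list '",
           fields[["PEAKTABLE"]], "' in ", path)
    x <- numeric(0); y <- numeric(0)
    for (i in seq_along(body)) {
      toks <- strsplit(body[i], "[;[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      for (tok in toks) {
        pair <- suppressWarnings(as.numeric(strsplit(tok, ",", fixed = TRUE)[[1]]))
        if (length(pair) != 2L || any(is.na(pair)))
          stop("read_jcamp: malformed x,y pair '", tok, "' at line ",
               block_start + i, " of ", path)
        x <- c(x, pair[1]); y <- c(y, pair[2])
      }
    }
  }
  raw_spectrum(compound_id %||% (if (nzchar(title)) title else basename(path)),
               technique, x * xfactor, y * yfactor, y_unit)
}

#' Write a raw spectrum as JCAMP-DX
#'
#' FTIR spectra with evenly spaced abscissae are written as AFFN
#' \code{##XYDATA=(X++(Y..Y))}; everything else (notably MS peak lists) as
#' \code{##PEAK TABLE=(XY..XY)}. Round-trips through [read_jcamp()].
#'
#' @param s a [raw_spectrum()].
#' @param path output file path.
#' @param dialect \code{"auto"} (default), \code{"xydata"} or
#'   \code{"peaktable"}. \code{"xydata"} requires evenly spaced abscissae.
#' @return \code{path}, invisibly.
#' @export
write_jcamp <- function(s, path, dialect = c("auto", "xydata", "peaktable")) {
  stopifnot(inherits(s, "raw_spectrum"))
  dialect <- match.arg(dialect)
  dx <- diff(s$x)
  even <- length(s$x) >= 2L && all(abs(dx - dx[1]) < 1e-9 * max(abs(dx)))
  if (dialect == "auto")
    dialect <- if (s$technique == "FTIR" && even) "xydata" else "peaktable"
  if (dialect == "xydata" && !even)
    stop("write_jcamp: XYDATA dialect requires evenly spaced abscissae")
  hdr <- c(
    sprintf("##TITLE=%s", s$compound_id),
    "##JCAMP-DX=4.24",
    sprintf("##DATA TYPE=%s",
            if (s$technique == "FTIR") "INFRARED SPECTRUM" else "MASS SPECTRUM"),
    sprintf("##XUNITS=%s", if (s$technique == "FTIR") "1/CM" else "M/Z"),
    sprintf("##YUNITS=%s", switch(s$y_unit,
                                  TRANSMITTANCE = "TRANSMITTANCE",
                                  ABSORBANCE = "ABSORBANCE",
                                  ABUNDANCE = "RELATIVE ABUNDANCE")),
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.8g", s$x[1]),
    sprintf("##LASTX=%.8g", s$x[length(s$x)]),
    sprintf("##NPOINTS=%d", length(s$x)))
  if (dialect == "xydata") {
    rows <- split(seq_along(s$x), ceiling(seq_along(s$x) / 8))
    tbl <- vapply(rows, function(ii)
      paste(c(format(s$x[ii[1]], digits = 10),
              format(s$y[ii], digits = 8)), collapse = " "),
      character(1))
    body <- c("##XYDATA=(X++(Y..Y))", tbl)
  } else {
    rows <- split(seq_along(s$x), ceiling(seq_along(s$x) / 6))
    tbl <- vapply(rows, function(ii)
      paste(sprintf("%.8g,%.8g", s$x[ii], s$y[ii]), collapse = " "),
      character(1))
    body <- c("##PEAK TABLE=(XY..XY)", tbl)
  }
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}
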