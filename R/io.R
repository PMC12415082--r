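# plain-text lattice-state format, two-column scattering profiles,
# PNG/TIFF grayscale images

#' Write a LatticeState as plain text
#'
#' Format: header lines \code{box <L>} and \code{periodic 1 1 1}, one line
#' per monomer \code{idx x y z species molecule_id reactive consumed}
#' (0-based idx), then one line per bond \code{i j kind} (0-based).
#' Round-trips bit-exactly through [readLatticeState()].
#'
#' @param state a [LatticeState-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLatticeState <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("box %d", boxEdge(state)), con)
  writeLines(paste("periodic", paste(as.integer(state@periodic), collapse = " ")), con)
  n <- nMonomers(state)
  if (n > 0) {
    p <- state@positions
    writeLines(sprintf("%d %d %d %d %s %d %d %d",
                       0:(n - 1), p[, 1], p[, 2], p[, 3], state@species,
                       state@moleculeId, as.integer(state@reactive),
                       as.integer(state@consumed)), con)
  }
  if (nrow(state@bonds) > 0)
    writeLines(sprintf("%d %d %s", state@bonds$i - 1L, state@bonds$j - 1L,
                       state@bonds$kind), con)
  invisible(path)
}

#' Read a LatticeState written by [writeLatticeState()]
#'
#' @param path input file path.
#' @return a [LatticeState-class].
#' @export
readLatticeState <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "box ") ||
      !startsWith(lines[2], "periodic "))
    stop("not a lattice-state file: ", path)
  L <- as.integer(strsplit(lines[1], " ")[[1]][2])
  body <- lines[-(1:2)]
  tok <- strsplit(body, " ", fixed = TRUE)
  nf <- lengths(tok)
  mono <- tok[nf == 8]
  bond <- tok[nf == 3]
  if (length(mono) == 0)
    return(latticeState(L, matrix(integer(), 0, 3), character()))
  m <- do.call(rbind, mono)
  ord <- order(as.integer(m[, 1]))
  m <- m[ord, , drop = FALSE]
  bonds <- if (length(bond)) {
    b <- do.call(rbind, bond)
    data.frame(i = as.integer(b[, 1]) + 1L, j = as.integer(b[, 2]) + 1L,
               kind = b[, 3])
  } else data.frame(i = integer(), j = integer(), kind = character())
  latticeState(L,
               cbind(as.integer(m[, 2]), as.integer(m[, 3]), as.integer(m[, 4])),
               m[, 5], as.integer(m[, 6]), bonds,
               as.logical(as.integer(m[, 7])),
               as.logical(as.integer(m[, 8])))
}

#' Write a scattering profile as two-column text
#'
#' Columns q (1/nm) and intensity (a.u.) with a \code{# units} header.
#'
#' @param profile a [ScatteringProfile-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScatteringProfile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: nm^-1, a.u.", con)
  if (nchar(profile@label)) writeLines(paste("# label:", profile@label), con)
  writeLines(sprintf("%.10g %.10g", profile@q, profile@intensity), con)
  invisible(path)
}

#' Read a two-column scattering profile
#'
#' @param path input path (whitespace- or comma-separated, \code{#}
#'   comments allowed).
#' @return a [ScatteringProfile-class].
#' @export
readScatteringProfile <- function(path) {
  lines <- readLines(path)
  lab <- sub("^# label: ", "", grep("^# label: ", lines, value = TRUE))
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  scatteringProfile(m[, 1], m[, 2],
                    label = if (length(lab)) lab[1] else "")
}

#' Write a GrayImage as 8-bit PNG or TIFF
#'
#' @param image a [GrayImage-class].
#' @param path output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  x <- round(imagePixels(image)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(x, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read an 8-bit grayscale PNG or TIFF
#'
#' @param path input path.
#' @param pixelSizeNm physical pixel size (nm/px) to attach.
#' @param provenance provenance tag (default "external").
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path, pixelSizeNm, provenance = "external") {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") png::readPNG(path)
       else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else stop("unsupported image extension: ", ext)
  if (length(dim(x)) == 3) x <- x[, , 1]
  grayImage(round(x * 255), pixelSizeNm, provenance)
}
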