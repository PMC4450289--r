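#' Read an 8-bit grayscale image
#'
#' Loads a PNG or PGM (plain `P2` or binary `P5`) raster as a numeric
#' matrix of intensities in \code{[0, 255]}. RGB(A) PNG input is collapsed
#' to gray by the unweighted channel average.
#'
#' @param path Path to a `.png`, `.pgm` file.
#' @return Numeric matrix (rows x columns) with values in \code{[0, 255]}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_gray(matrix(c(0, 128, 255, 64), 2, 2), f)
#' img <- load_gray(f)
load_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- rowMeans(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], dims = 2L)
      round(a * 255)
    },
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, " (expected png or pgm)")
  )
  if (nrow(img) < 1L || ncol(img) < 1L || length(img) == 0L)
    stop_validation("image has zero size: ", path)
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale image or binary mask
#'
#' Values in \code{[0, 255]} (or \code{[0, 1]}, auto-detected) are written
#' as 8-bit PNG or PGM. Masks should be written from 0/1 matrices; they
#' come back from [load_gray()] as 0/255.
#'
#' @param img Numeric matrix.
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  check_matrix(img)
  if (max(img) <= 1) img <- img * 255
  img <- pmin(pmax(round(img), 0), 255)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img / 255, path),
    pgm = write_pgm(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

# Plain-text (P2) and binary (P5) PGM, 8-bit only. Hand-rolled because no
# installed raster reader speaks PGM; the format is two header lines plus
# whitespace-separated samples.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  toks <- character(0)
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path)
    if (ch == "#") { # comment to end of line
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 %in% c("\n", "")) break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (!grepl("[0-9]", c2)) break
        tok <- paste0(tok, c2)
      }
      toks <- c(toks, tok)
    }
  }
  dims <- as.integer(toks)
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  if (maxval > 255) stop("only 8-bit PGM supported: ", path)
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h) stop("truncated PGM data: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(as.integer(t(img))), con)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#' @param mask 0/1 matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
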