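#' @useDynLib mammotrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Conventions used throughout the package:
#  * images are integer matrices (rows x cols) with intensities in [0, 255],
#    origin at the top-left, row index increasing downward;
#  * pixel coordinates are 0-based (row, col);
#  * boundaries are n x 2 integer matrices with columns "row","col",
#    ordered along the (open) curve.

validate_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop(sprintf("`%s` must contain intensities in [0, 255]", arg),
         call. = FALSE)
  }
  invisible(image)
}

validate_boundary <- function(boundary, arg = "boundary") {
  if (!is.matrix(boundary) || ncol(boundary) != 2L) {
    stop(sprintf("`%s` must be an n x 2 matrix of (row, col) coordinates", arg),
         call. = FALSE)
  }
  if (nrow(boundary) > 0 && (anyNA(boundary) || min(boundary) < 0)) {
    stop(sprintf("`%s` contains missing or negative coordinates", arg),
         call. = FALSE)
  }
  invisible(boundary)
}

#' Construct a boundary from row/col coordinate vectors
#'
#' @param row,col integer vectors of equal length, 0-based pixel coordinates.
#' @return An n x 2 integer matrix with columns `row`, `col`.
#' @export
boundary_points <- function(row, col) {
  stopifnot(length(row) == length(col))
  b <- cbind(row = as.integer(round(row)), col = as.integer(round(col)))
  validate_boundary(b)
  b
}

#' Read an 8-bit grayscale image
#'
#' Supports PGM (both the ASCII `P2` and binary `P5` encodings) and 8-bit
#' grayscale PNG. RGB and 16-bit inputs are rejected.
#'
#' @param path path to a `.pgm` or `.png` file.
#' @return An integer matrix of intensities in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    return(read_png_gray(path))
  }
  read_pgm(path)
}

read_png_gray <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8L) {
    stop("unsupported PNG bit depth: ", info$bit.depth,
         " (only 8-bit grayscale is supported)", call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    stop("RGB(A) PNG not supported; provide an 8-bit grayscale image",
         call. = FALSE)
  }
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  validate_image(m)
  m
}

#' Read a PGM image (P2 or P5)
#'
#' @param path path to the file.
#' @return An integer matrix of intensities in \[0, 255\].
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") { # comment: skip to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[ \t\r\n]", ch)) {
        if (nzchar(tok)) return(tok)
        next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (expected P2 or P5, got '", magic, "')", call. = FALSE)
  }
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(width) || is.na(height) || is.na(maxval)) {
    stop("malformed PGM header", call. = FALSE)
  }
  if (maxval > 255L) {
    stop("unsupported PGM depth (maxval ", maxval, " > 255)", call. = FALSE)
  }
  n <- width * height
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      chunk <- scan(con, what = integer(), n = n - length(vals), quiet = TRUE)
      if (length(chunk) == 0L) stop("truncated P2 pixel data", call. = FALSE)
      vals <- c(vals, chunk)
    }
  }
  if (length(vals) < n) stop("truncated PGM pixel data", call. = FALSE)
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  validate_image(m)
  m
}

#' Write an 8-bit grayscale image as PGM
#'
#' @param image integer matrix with intensities in \[0, 255\].
#' @param path output path.
#' @param ascii write the ASCII `P2` encoding instead of binary `P5`.
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  validate_image(image)
  h <- nrow(image); w <- ncol(image)
  vals <- as.integer(round(t(image))) # row-major order
  if (ascii) {
    con <- file(path, "wb") # binary mode keeps LF line endings on all platforms
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    writeLines(paste(vals, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read a boundary CSV
#'
#' The file must have a `row,col` header followed by one 0-based integer
#' coordinate pair per line, in trace order. CRLF and LF line endings are
#' accepted.
#'
#' @param path path to the CSV file.
#' @return An n x 2 integer matrix with columns `row`, `col`.
#' @export
read_boundary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || tolower(gsub(" ", "", lines[1L])) != "row,col") {
    stop("boundary CSV must start with a 'row,col' header: ", path,
         call. = FALSE)
  }
  if (length(lines) == 1L) return(boundary_points(integer(0), integer(0)))
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  rows <- cols <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) != 2L || anyNA(p) || any(p < 0) || any(p != round(p))) {
      stop(sprintf("malformed boundary row at line %d of %s", i + 1L, path),
           call. = FALSE)
    }
    rows[i] <- p[1L]; cols[i] <- p[2L]
  }
  boundary_points(rows, cols)
}

#' Write a boundary CSV
#'
#' @param boundary n x 2 matrix of (row, col) coordinates.
#' @param path output path.
#' @export
write_boundary <- function(boundary, path) {
  validate_boundary(boundary)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("row,col",
               paste(boundary[, 1L], boundary[, 2L], sep = ",")), con)
  invisible(path)
}

#' Convert 1-based (x, y) annotations to the package's (row, col) convention
#'
#' @param xy n x 2 matrix of 1-based (x, y) = (column, row-from-top) pairs.
#' @return An n x 2 0-based (row, col) boundary matrix.
#' @export
xy_to_boundary <- function(xy) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L)
  boundary_points(xy[, 2L] - 1L, xy[, 1L] - 1L)
}
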