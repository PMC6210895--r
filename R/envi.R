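#' Read an ENVI-format hyperspectral cube
#'
#' Reads a cube from an ENVI header (`.hdr`) plus raw binary file. BSQ is the
#' native interleave; BIL and BIP files are converted to band-sequential order
#' on read. Only integer sample formats are supported (DN cubes).
#'
#' @param header_path Path to the `.hdr` file. The raw file is located from the
#'   header's directory: same basename without `.hdr`, or with `.raw`/`.img`/
#'   `.dat` extension.
#' @return A [hyperspectral_cube()].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path, call. = FALSE)
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)

  a <- as.integer(hdr[["lines"]])     # rows
  b <- as.integer(hdr[["samples"]])   # cols
  c_ <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr[["interleave"]] %||% "bsq")
  byte_order <- as.integer(hdr[["byte order"]] %||% "0")
  offset <- as.integer(hdr[["header offset"]] %||% "0")

  type_info <- switch(as.character(dtype),
    "1"  = list(size = 1L, signed = FALSE),
    "2"  = list(size = 2L, signed = TRUE),
    "3"  = list(size = 4L, signed = TRUE),
    "12" = list(size = 2L, signed = FALSE),
    stop("unsupported ENVI data type ", dtype, " (integer samples only)", call. = FALSE)
  )

  raw_path <- find_envi_raw(header_path)
  n <- a * b * c_
  expected <- offset + n * type_info$size
  actual <- file.info(raw_path)$size
  if (is.na(actual) || actual < expected) {
    stop(sprintf("raw file %s has %s bytes; header implies at least %d",
                 raw_path, ifelse(is.na(actual), "unknown", actual), expected),
         call. = FALSE)
  }

  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  endian <- if (byte_order == 1L) "big" else "little"
  vals <- if (type_info$size == 4L) {
    readBin(con, integer(), n = n, size = 4L, endian = endian)
  } else {
    readBin(con, integer(), n = n, size = type_info$size,
            signed = type_info$signed, endian = endian)
  }
  if (length(vals) != n) stop("raw file truncated while reading samples", call. = FALSE)

  # ENVI sample order is col-fastest within a line; map to (row, col, band).
  arr <- array(0, dim = c(a, b, c_))
  if (interleave == "bsq") {
    arr <- aperm(array(vals, dim = c(b, a, c_)), c(2L, 1L, 3L))
  } else if (interleave == "bil") {
    arr <- aperm(array(vals, dim = c(b, c_, a)), c(3L, 1L, 2L))
  } else if (interleave == "bip") {
    arr <- aperm(array(vals, dim = c(c_, b, a)), c(3L, 2L, 1L))
  } else {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }

  bit_depth <- as.integer(hdr[["pssahcs bit depth"]] %||%
                            switch(as.character(dtype), "1" = 8L, "2" = 15L, "12" = 16L, "3" = 31L))
  wl <- NULL
  if (!is.null(hdr[["wavelength"]])) {
    wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1L]])
    if (length(wl) != c_) stop("wavelength list length does not match band count", call. = FALSE)
  }
  hyperspectral_cube(arr, bit_depth = bit_depth, wavelengths = wl)
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<stem>.hdr` and a band-sequential raw file `<stem>.raw`. The sample
#' type is the smallest unsigned integer that holds the cube's bit depth; the
#' exact bit depth is recorded in the header so a round-trip reproduces the
#' cube bit-exactly.
#'
#' @param cube A [hyperspectral_cube()].
#' @param header_path Destination `.hdr` path (the raw file is written next to
#'   it with extension `.raw`).
#' @export
write_envi <- function(cube, header_path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  d <- dim(cube$data)
  dtype <- if (cube$bit_depth <= 8L) 1L else if (cube$bit_depth <= 16L) 12L else 3L
  size <- c("1" = 1L, "12" = 2L, "3" = 4L)[[as.character(dtype)]]
  stem <- sub("\\.hdr$", "", header_path)
  raw_path <- paste0(stem, ".raw")

  lines_out <- c(
    "ENVI",
    "description = {pssahcs export}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    "interleave = bsq",
    "byte order = 0",
    sprintf("pssahcs bit depth = %d", cube$bit_depth)
  )
  if (!is.null(cube$wavelengths)) {
    lines_out <- c(lines_out, "wavelength units = nm",
                   paste0("wavelength = {", paste(sprintf("%.17g", cube$wavelengths),
                                                  collapse = ", "), "}"))
  }
  writeLines(lines_out, header_path)

  vals <- as.integer(aperm(cube$data, c(2L, 1L, 3L)))  # col-fastest BSQ order
  if (size == 2L) vals <- ifelse(vals > 32767L, vals - 65536L, vals)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = size, endian = "little")
  invisible(NULL)
}

# ENVI headers are "key = value" lines; {...} blocks may span lines.
parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  if (!length(txt) || toupper(txt[1L]) != "ENVI") {
    stop("not an ENVI header (missing leading 'ENVI' line): ", path, call. = FALSE)
  }
  txt <- txt[-1L]
  # join continuation lines of { ... } blocks
  joined <- character(0)
  buf <- ""
  for (ln in txt) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    n_open <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    n_close <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (n_open == n_close) {
      joined <- c(joined, buf)
      buf <- ""
    }
  }
  if (nzchar(buf)) joined <- c(joined, buf)
  out <- list()
  for (ln in joined) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- tolower(trimws(substr(ln, 1L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    val <- gsub("^\\{|\\}$", "", val)
    out[[key]] <- trimws(val)
  }
  out
}

find_envi_raw <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path)
  cands <- c(stem, paste0(stem, c(".raw", ".img", ".dat", ".bsq")))
  hit <- cands[file.exists(cands)]
  if (!length(hit)) stop("raw data file not found for header ", header_path, call. = FALSE)
  hit[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
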