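# Minimal MATLAB level-5 MAT-file I/O: enough to write and read the study's
# record layout (named double arrays of any rank, character scalars).
# Little-endian only; uncompressed elements are written, compressed elements
# are decompressed on read where the zlib stream is readable.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L
MX_CHAR <- 4L; MX_DOUBLE <- 6L

pad8 <- function(n) (8 - n %% 8) %% 8

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

mat_element_raw <- function(type, payload) {
  c(u32(type), u32(length(payload)), payload, raw(pad8(length(payload))))
}

mat_matrix_raw <- function(name, value) {
  if (is.character(value)) {
    stopifnot(length(value) == 1)
    cls <- MX_CHAR
    dims <- c(1L, nchar(value))
    data_raw <- mat_element_raw(
      MI_UINT16,
      writeBin(as.integer(utf8ToInt(value)), raw(), size = 2, endian = "little"))
  } else {
    cls <- MX_DOUBLE
    dims <- if (is.null(dim(value))) c(1L, length(value)) else dim(value)
    data_raw <- mat_element_raw(
      MI_DOUBLE, writeBin(as.double(value), raw(), endian = "little"))
  }
  flags <- mat_element_raw(MI_UINT32, c(u32(cls), u32(0L)))
  dims_raw <- mat_element_raw(MI_INT32, u32(as.integer(dims)))
  name_raw <- mat_element_raw(MI_INT8, charToRaw(name))
  body <- c(flags, dims_raw, name_raw, data_raw)
  c(u32(MI_MATRIX), u32(length(body)), body)
}

#' Write variables to a MAT (level 5) file
#'
#' @param vars Named list of numeric arrays/vectors and character scalars.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, Platform: R ssvepkit, Created on: %s",
                  "2026-01-01")  # fixed date keeps writes byte-reproducible
  header <- charToRaw(desc)
  header <- c(header, rep(charToRaw(" "), 116 - length(header)))
  header <- c(header, raw(8),
              writeBin(c(256L), raw(), size = 2, endian = "little"),
              charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm) mat_matrix_raw(nm, vars[[nm]])))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

read_u32 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
}

mat_read_numeric <- function(type, payload) {
  switch(as.character(type),
    "1" = as.double(readBin(payload, "integer", n = length(payload), size = 1, endian = "little")),
    "2" = as.double(readBin(payload, "integer", n = length(payload), size = 1,
                            signed = FALSE, endian = "little")),
    "3" = as.double(readBin(payload, "integer", n = length(payload) / 2, size = 2, endian = "little")),
    "4" = as.double(readBin(payload, "integer", n = length(payload) / 2, size = 2,
                            signed = FALSE, endian = "little")),
    "5" = as.double(readBin(payload, "integer", n = length(payload) / 4, size = 4, endian = "little")),
    "6" = as.double(readBin(payload, "integer", n = length(payload) / 4, size = 4, endian = "little")),
    "9" = readBin(payload, "double", n = length(payload) / 8, endian = "little"),
    stop("unsupported MAT data type: ", type, call. = FALSE))
}

# Read one data element starting at byte offset `off` (0-based) in `raw`.
# Returns list(type, payload, next_off).
mat_next_element <- function(raw, off) {
  word <- read_u32(raw, off)
  small_size <- bitwAnd(bitwShiftR(word, 16), 0xFFFFL)
  if (small_size != 0L) {
    type <- bitwAnd(word, 0xFFFFL)
    payload <- raw[(off + 5):(off + 4 + small_size)]
    list(type = type, payload = payload, next_off = off + 8)
  } else {
    type <- word
    size <- read_u32(raw, off + 4)
    payload <- if (size > 0) raw[(off + 9):(off + 8 + size)] else raw(0)
    list(type = type, payload = payload, next_off = off + 8 + size + pad8(size))
  }
}

mat_parse_matrix <- function(payload) {
  el <- mat_next_element(payload, 0)              # array flags
  flags <- readBin(el$payload[1:4], "integer", size = 4, endian = "little")
  cls <- bitwAnd(flags, 0xFFL)
  el2 <- mat_next_element(payload, el$next_off)   # dimensions
  dims <- readBin(el2$payload, "integer", n = length(el2$payload) / 4,
                  size = 4, endian = "little")
  el3 <- mat_next_element(payload, el2$next_off)  # name
  name <- rawToChar(el3$payload)
  el4 <- mat_next_element(payload, el3$next_off)  # real part
  if (cls == MX_CHAR) {
    val <- if (el4$type == MI_UTF8) rawToChar(el4$payload)
    else intToUtf8(mat_read_numeric(el4$type, el4$payload))
    return(list(name = name, value = val))
  }
  vals <- mat_read_numeric(el4$type, el4$payload)
  if (length(dims) > 2 || (length(dims) == 2 && all(dims > 1))) {
    dim(vals) <- dims
  } else if (length(dims) == 2 && dims[1] == 1) {
    # row vector -> plain vector
  } else if (length(dims) == 2) {
    dim(vals) <- dims
  }
  list(name = name, value = vals)
}

#' Read a MAT (level 5) file
#'
#' Supports named numeric arrays (any rank, stored as any integer or double
#' type) and character arrays; compressed elements are inflated when the
#' platform zlib stream can be decoded.
#'
#' @param path File path.
#' @return Named list of variables.
#' @export
read_mat <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128) stop("not a MAT v5 file (too short): ", path, call. = FALSE)
  endian_tag <- rawToChar(raw[127:128])
  if (endian_tag == "MI")
    stop("big-endian MAT files are not supported", call. = FALSE)
  if (endian_tag != "IM")
    stop("not a MAT v5 file (bad endian tag): ", path, call. = FALSE)
  out <- list()
  off <- 128
  while (off < length(raw)) {
    el <- mat_next_element(raw, off)
    if (el$type == MI_COMPRESSED) {
      inflated <- tryCatch(
        memDecompress(el$payload, type = "gzip"),
        error = function(e) stop("compressed MAT element could not be inflated",
                                 call. = FALSE))
      inner <- mat_next_element(inflated, 0)
      if (inner$type == MI_MATRIX) {
        v <- mat_parse_matrix(inner$payload)
        out[[v$name]] <- v$value
      }
    } else if (el$type == MI_MATRIX) {
      v <- mat_parse_matrix(el$payload)
      out[[v$name]] <- v$value
    }
    off <- el$next_off
  }
  out
}
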