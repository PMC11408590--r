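#' @importFrom rlang %||%
NULL

# ---- CRC32 (for PNG chunk checksums) ----------------------------------------

the_crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(the_crc_env$tab)) return(the_crc_env$tab)
  poly <- -306674912L            # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  the_crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L                     # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u32_be <- function(x) {          # x may be a signed 32-bit pattern (CRC)
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(x, 255L)))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

# ---- pinned 1-bit PNG encoder ----------------------------------------------

# Deterministic minimal PNG: 1-bit grayscale, filter type 0 on every
# scanline, a single zlib-deflate IDAT, no ancillary chunks. State 1 is
# rendered black (gray bit 0), matching the figure convention.
encode_png_1bit <- function(L) {
  stopifnot(is.matrix(L))
  h <- nrow(L); w <- ncol(L)
  scanlines <- unlist(lapply(seq_len(h), function(r)
    c(as.raw(0L), pack_bits_msb(1L - L[r, ]))))
  ihdr <- c(u32_be(w), u32_be(h),
            as.raw(c(1L, 0L, 0L, 0L, 0L)))  # bit depth 1, grayscale
  idat <- memCompress(scanlines, type = "gzip")   # zlib stream
  c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0)))
}

# ---- portable bitmap --------------------------------------------------------

write_pbm <- function(L, path, ascii = TRUE) {
  h <- nrow(L); w <- ncol(L)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    lines <- c(sprintf("P1\n%d %d", w, h),
               apply(L, 1L, paste, collapse = " "))
    writeLines(lines, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P4\n%d %d\n", w, h), con, eos = NULL)
    for (r in seq_len(h)) writeBin(pack_bits_msb(L[r, ]), con)
  }
  invisible(path)
}

pbm_header <- function(bytes) {
  # returns list(width, height, offset of first payload byte);
  # works on raw bytes because P4 payloads may contain NULs
  b <- as.integer(bytes)
  is_digit <- function(x) x >= 48L & x <= 57L
  is_space <- function(x) x %in% c(32L, 9L, 10L, 13L, 11L, 12L)
  i <- 3L                        # past the 2-byte magic
  fields <- integer(0)
  n <- length(b)
  while (length(fields) < 2L && i <= n) {
    ch <- b[i]
    if (ch == 35L) {             # '#': comment to end of line
      while (i <= n && b[i] != 10L) i <- i + 1L
    } else if (is_space(ch)) {
      i <- i + 1L
    } else if (is_digit(ch)) {
      j <- i
      while (j <= n && is_digit(b[j])) j <- j + 1L
      fields <- c(fields, as.integer(paste(b[i:(j - 1L)] - 48L, collapse = "")))
      i <- j
    } else {
      stop(sprintf("PBM format error at byte offset %d: unexpected '%s'",
                   i, rawToChar(bytes[i])), call. = FALSE)
    }
  }
  if (length(fields) < 2L)
    stop("PBM format error: missing width/height in header", call. = FALSE)
  list(width = fields[1L], height = fields[2L], offset = i + 1L)
}

read_pbm <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(bytes[1:2])
  hdr <- pbm_header(bytes)
  w <- hdr$width; h <- hdr$height
  if (magic == "P1") {
    body <- rawToChar(bytes[hdr$offset:length(bytes)])
    body <- gsub("#[^\n]*", "", body)
    digits <- strsplit(gsub("[^01]", "", body), "")[[1]]
    if (length(digits) != w * h)
      stop(sprintf(
        "PBM format error at byte offset %d: header says %d x %d = %d bits, payload has %d",
        hdr$offset, w, h, w * h, length(digits)), call. = FALSE)
    L <- matrix(as.integer(digits), nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P4") {
    bpr <- ceiling(w / 8)
    payload <- bytes[hdr$offset:length(bytes)]
    if (length(payload) < h * bpr)
      stop(sprintf(
        "PBM format error at byte offset %d: need %d payload bytes, found %d",
        hdr$offset, h * bpr, length(payload)), call. = FALSE)
    L <- matrix(0L, h, w)
    for (r in seq_len(h)) {
      rowbytes <- payload[((r - 1L) * bpr + 1L):(r * bpr)]
      bits <- as.integer(rawToBits(rowbytes))
      # rawToBits is LSB-first within bytes; PBM packs MSB-first
      bits <- bits[as.vector(matrix(seq_along(bits), nrow = 8L)[8:1, ])]
      L[r, ] <- bits[seq_len(w)]
    }
  } else {
    stop("PBM format error: unknown magic '", magic, "'", call. = FALSE)
  }
  L
}

# ---- user-facing diagram I/O ------------------------------------------------

#' Write and read space-time diagrams
#'
#' Diagrams round-trip losslessly through three on-disk formats: ASCII
#' portable bitmap (`"pbm-ascii"`, P1), binary portable bitmap
#' (`"pbm-binary"`, P4), and 1-bit grayscale PNG written by the package's
#' pinned encoder (fixed filter 0, single IDAT, no ancillary chunks), so
#' a saved PNG's file size equals [lz_complexity()]'s `"png-fixed"`
#' value. State 1 is the foreground (black) in every format. PNG files
#' from other encoders are read through the \pkg{png} package.
#'
#' @param diagram A `ca_diagram` or 0/1 matrix.
#' @param path Output/input file path.
#' @param format One of `"pbm-ascii"`, `"pbm-binary"`, `"png"`; for
#'   [read_diagram()] the format is detected from the file's magic bytes.
#' @return [write_diagram()]: the path, invisibly. [read_diagram()]: a
#'   `ca_diagram`.
#' @export
write_diagram <- function(diagram, path,
                          format = c("pbm-ascii", "pbm-binary", "png")) {
  format <- match.arg(format)
  L <- unclass(diagram)
  storage.mode(L) <- "integer"
  if (format == "png") {
    writeBin(encode_png_1bit(L), path)
  } else {
    write_pbm(L, path, ascii = format == "pbm-ascii")
  }
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  magic <- readBin(path, "raw", n = 8L)
  L <- if (length(magic) >= 8L &&
           identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    # black (0) is state 1
    matrix(as.integer(img < 0.5), nrow = nrow(img))
  } else if (rawToChar(magic[1:2]) %in% c("P1", "P4")) {
    read_pbm(path)
  } else {
    stop("format error: unrecognised magic bytes in ", path, call. = FALSE)
  }
  new_ca_diagram(L)
}

#' Run provenance sidecar
#'
#' Writes (or reads back) the JSON sidecar that makes a saved diagram
#' bit-identically reproducible: rule id, arity, boundary, initial
#' condition, seed, lattice size, step count and package version.
#'
#' @param diagram A `ca_diagram`.
#' @param path Sidecar path (conventionally `<diagram>.json`).
#' @return [write_provenance()]: the path, invisibly;
#'   [read_provenance()]: a named list.
#' @export
write_provenance <- function(diagram, path) {
  meta <- list(
    rule_id = attr(diagram, "rule_id"),
    arity = attr(diagram, "arity"),
    boundary = attr(diagram, "boundary"),
    init = attr(diagram, "init"),
    seed = attr(diagram, "seed"),
    cells = ncol(diagram),
    steps = nrow(diagram) - 1L,
    package = "colloidca",
    version = as.character(utils::packageVersion("colloidca"))
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
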