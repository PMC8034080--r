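# Minimal multipage TIFF I/O for uncompressed 8/16-bit grayscale stacks.
# One TIFF page per z slice; pixel order within a page is x fastest, then
# rows (y), which matches R's column-major array layout with
# dim = c(nx, ny, nz). Only the baseline feature set this package writes
# is read back; anything else (compression, tiles, float samples) is
# rejected with a clear message.

read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("unreadable TIFF: file too short", call. = FALSE)
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("unreadable TIFF: bad byte-order mark", call. = FALSE))
  rd_int <- function(off, size) {
    # readBin only supports unsigned for 1- and 2-byte integers; 4-byte
    # offsets stay below 2^31 for any file this package writes
    readBin(raw[(off + 1):(off + size)], "integer", size = size,
            endian = endian, signed = size > 2L)
  }
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stop("unreadable TIFF: bad magic number", call. = FALSE)
  ifd_off <- rd_int(4L, 4L)
  slices <- list()
  width <- height <- bits <- NULL
  while (ifd_off != 0L) {
    n_entries <- rd_int(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd_int(eoff, 2L)
      type <- rd_int(eoff + 2L, 2L)
      count <- rd_int(eoff + 4L, 4L)
      tsize <- c(1L, 1L, 2L, 4L, 8L)[type] # BYTE ASCII SHORT LONG RATIONAL
      if (is.na(tsize)) next
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) eoff + 8L else rd_int(eoff + 8L, 4L)
      vals <- if (type %in% c(3L, 4L)) {
        vapply(seq_len(count), function(i)
          rd_int(voff + (i - 1L) * tsize, tsize), integer(1))
      } else NULL
      tags[[as.character(tag)]] <- vals
    }
    getv <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- getv(256L); h <- getv(257L)
    bps <- getv(258L, 8L)[1]
    comp <- getv(259L, 1L)
    fmt <- getv(339L, 1L)[1]
    if (is.null(w) || is.null(h))
      stop("unreadable TIFF: missing dimensions", call. = FALSE)
    if (comp != 1L)
      stop("unsupported TIFF: compressed data", call. = FALSE)
    if (fmt == 3L)
      stop("unsupported bit depth: float TIFF samples are not supported; ",
           "convert to 8- or 16-bit first", call. = FALSE)
    if (!bps %in% c(8L, 16L))
      stop("unsupported bit depth: ", bps, "-bit TIFF", call. = FALSE)
    if (getv(277L, 1L)[1] != 1L)
      stop("unsupported TIFF: multi-sample pixels", call. = FALSE)
    if (is.null(width)) { width <- w; height <- h; bits <- bps }
    else if (w != width || h != height || bps != bits)
      stop("unreadable TIFF: pages differ in shape or depth", call. = FALSE)
    offs <- getv(273L); cnts <- getv(279L)
    if (is.null(offs) || is.null(cnts))
      stop("unreadable TIFF: missing strip layout", call. = FALSE)
    pix <- unlist(lapply(seq_along(offs), function(i) {
      bytes <- raw[(offs[i] + 1L):(offs[i] + cnts[i])]
      readBin(bytes, "integer", n = cnts[i] / (bps / 8L), size = bps / 8L,
              endian = endian, signed = FALSE)
    }))
    if (length(pix) != w * h)
      stop("unreadable TIFF: strip data does not match page size",
           call. = FALSE)
    slices[[length(slices) + 1L]] <- pix
    ifd_off <- rd_int(ifd_off + 2L + n_entries * 12L, 4L)
  }
  if (length(slices) < 2L)
    stop("not a 3D volume: TIFF has fewer than 2 pages", call. = FALSE)
  data <- array(unlist(slices), dim = c(width, height, length(slices)))
  list(data = data, bit_depth = as.integer(bits))
}

write_tiff_stack <- function(data, path, bit_depth = 8L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  bytes_pp <- bit_depth / 8L
  page_bytes <- nx * ny * bytes_pp
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  # layout: 8-byte header, then all pixel data, then the IFD chain
  data_start <- 8L
  ifd_start <- data_start + nz * page_bytes
  ifd_size <- 2L + 10L * 12L + 4L
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  w4(ifd_start)
  vals <- as.integer(round(data))
  vals[vals < 0L] <- 0L
  vals[vals > 2^bit_depth - 1] <- as.integer(2^bit_depth - 1)
  for (z in seq_len(nz)) {
    v <- vals[(1L + (z - 1L) * nx * ny):(z * nx * ny)]
    if (bit_depth == 8L) {
      writeBin(as.raw(v), con)
    } else {
      v[v > 32767L] <- v[v > 32767L] - 65536L # two's complement for writeBin
      writeBin(v, con, size = 2L, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (z in seq_len(nz)) {
    w2(10L) # number of directory entries
    entry(256L, 4L, 1L, nx)                  # ImageWidth
    entry(257L, 4L, 1L, ny)                  # ImageLength
    entry(258L, 3L, 1L, bit_depth)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)                  # Compression: none
    entry(262L, 3L, 1L, 1L)                  # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_start + (z - 1L) * page_bytes) # StripOffsets
    entry(277L, 3L, 1L, 1L)                  # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                  # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)          # StripByteCounts
    entry(339L, 3L, 1L, 1L)                  # SampleFormat: unsigned int
    w4(if (z < nz) ifd_start + z * ifd_size else 0L) # next IFD
  }
  invisible(path)
}
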