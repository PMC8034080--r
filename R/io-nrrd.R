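# Minimal NRRD I/O: raw encoding, 3D uint8/uint16, little endian.
# Voxel size travels in the `spacings` header field (micrometers).

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("unreadable NRRD: bad magic line", call. = FALSE)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("unreadable NRRD: no end-of-header blank line", call. = FALSE)
    if (line == "") break
    if (!startsWith(line, "#")) header <- c(header, line)
  }
  fields <- list()
  for (line in header) {
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  type <- fields[["type"]]
  bit_depth <- switch(type,
                      uchar = , uint8 = , `unsigned char` = 8L,
                      ushort = , uint16 = , `unsigned short` = 16L,
                      stop("unsupported bit depth: NRRD type '", type, "'",
                           call. = FALSE))
  if (!identical(fields[["encoding"]], "raw"))
    stop("unsupported NRRD: only raw encoding is handled", call. = FALSE)
  ndim <- as.integer(fields[["dimension"]])
  if (!identical(ndim, 3L))
    stop("not a 3D volume: NRRD dimension is ", ndim, call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  voxel_size_um <- NULL
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
    voxel_size_um <- sp[1]
  }
  n <- prod(sizes)
  v <- readBin(con, "integer", n = n, size = bit_depth / 8L,
               endian = endian, signed = FALSE)
  if (length(v) != n)
    stop("unreadable NRRD: truncated data", call. = FALSE)
  list(data = array(v, sizes), bit_depth = bit_depth,
       voxel_size_um = voxel_size_um)
}

write_nrrd <- function(data, path, bit_depth = 8L, voxel_size_um = 45) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  type <- if (bit_depth == 8L) "uint8" else "uint16"
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(rep(voxel_size_um, 3), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con)
  v <- as.integer(round(data))
  v[v < 0L] <- 0L
  v[v > 2^bit_depth - 1] <- as.integer(2^bit_depth - 1)
  if (bit_depth == 8L) writeBin(as.raw(v), con)
  else {
    v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = 2L, endian = "little")
  }
  invisible(path)
}
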