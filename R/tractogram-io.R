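#' Streamline tractogram container
#'
#' Streamlines are ordered polylines of 3-D vertices held in world mm,
#' whatever the on-disk convention of the file they came from. The source
#' affine is kept so voxel-referenced formats (TRK) can be written back.
#'
#' @param streamlines list of n_i x 3 numeric matrices (world mm).
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @return A `tractogram` object.
#' @export
tractogram <- function(streamlines, affine) {
  stopifnot(is.list(streamlines))
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2) {
      stop("validation error: each streamline needs >= 2 vertices (n x 3)",
           call. = FALSE)
    }
    if (!all(is.finite(s))) {
      stop("validation error: non-finite streamline vertex", call. = FALSE)
    }
  }
  structure(list(streamlines = streamlines,
                 space = list(units = "mm", affine = affine)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  nv <- sum(vapply(x$streamlines, nrow, 1L))
  cat(sprintf("<tractogram> %d streamlines, %d vertices (world mm)\n",
              length(x$streamlines), nv))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

n_vertices <- function(t) sum(vapply(t$streamlines, nrow, 1L))

#' Write a tractogram to TRK or TCK
#'
#' TCK stores vertices in world (scanner) mm directly; TRK stores them in
#' TrackVis voxel-mm convention (corner of voxel (0,0,0) at the origin), so
#' the tractogram's affine is used to convert, and is embedded in the TRK
#' header for the return trip. Coordinates survive a round trip to float32
#' precision.
#'
#' @param t a [tractogram()].
#' @param path output path ending in `.trk` or `.tck`.
#' @param allow_empty write a valid file even with 0 streamlines.
#' @return Invisibly, `path`.
#' @export
write_tractogram <- function(t, path, allow_empty = FALSE) {
  stopifnot(inherits(t, "tractogram"))
  if (length(t$streamlines) == 0 && !allow_empty) {
    stop("validation error: empty tractogram (set allow_empty = TRUE)",
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = write_tck(t, path),
    trk = write_trk(t, path),
    stop(sprintf("format error: unknown tractogram extension '.%s'", ext),
         call. = FALSE))
  invisible(path)
}

#' Read a TRK or TCK tractogram
#'
#' @param path path ending in `.trk` or `.tck`.
#' @param affine reference affine for TCK files (world-mm native; only kept
#'   as metadata). Ignored for TRK, which embeds its own.
#' @return A [tractogram()] with vertices in world mm.
#' @export
read_tractogram <- function(path, affine = diag(4)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = read_tck(path, affine),
    trk = read_trk(path),
    stop(sprintf("format error: unknown tractogram extension '.%s'", ext),
         call. = FALSE))
}

## ---- TCK (MRtrix) ----------------------------------------------------------

write_tck <- function(t, path) {
  n <- length(t$streamlines)
  hdr_body <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n, "\n")
  # The 'file' line records the byte offset of the binary section, which
  # depends on its own length; pad the offset to a fixed width.
  offset_field <- function(off) sprintf("file: . %-10d\nEND\n", off)
  off <- nchar(hdr_body) + nchar(offset_field(0))
  hdr <- paste0(hdr_body, offset_field(off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

read_tck <- function(path, affine) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:13]), "mrtrix tracks")) {
    stop("format error: not a TCK file (bad magic)", call. = FALSE)
  }
  # Header is ASCII key:value lines up to END (binary data follows; scan
  # raw bytes for the terminator before text conversion).
  pat <- charToRaw("END\n")
  cand <- which(raw == pat[1])
  hdr_end <- NA_integer_
  for (i in cand) {
    if (i + 3 <= length(raw) && identical(raw[i:(i + 3)], pat)) {
      hdr_end <- i + 3; break
    }
  }
  if (is.na(hdr_end)) stop("format error: TCK header missing END",
                           call. = FALSE)
  lines <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\n", fixed = TRUE)[[1]]
  kv <- lines[2:(length(lines) - 1)]
  file_line <- grep("^file:", kv, value = TRUE)
  if (!length(file_line)) stop("format error: TCK header missing file offset",
                               call. = FALSE)
  off <- as.integer(trimws(sub("^file:\\s*\\.\\s*", "", file_line[1])))
  dt <- trimws(sub("^datatype:\\s*", "", grep("^datatype:", kv, value = TRUE)[1]))
  if (!identical(dt, "Float32LE")) {
    stop(sprintf("format error: unsupported TCK datatype '%s'", dt),
         call. = FALSE)
  }
  n_float <- (length(raw) - off) %/% 4
  vals <- readBin(raw[(off + 1):length(raw)], "numeric", n_float, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(pts)) > 0 & !rowSums(is.infinite(pts))
  is_inf <- rowSums(is.infinite(pts)) > 0
  stop_row <- which(is_inf)[1]
  if (!is.na(stop_row)) pts <- pts[seq_len(stop_row - 1), , drop = FALSE]
  breaks <- which(rowSums(is.na(pts)) > 0)
  starts <- c(1, breaks + 1)
  ends <- c(breaks - 1, nrow(pts))
  keep <- starts <= ends
  sl <- Map(function(a, b) pts[a:b, , drop = FALSE],
            starts[keep], ends[keep])
  sl <- sl[vapply(sl, nrow, 1L) >= 1]
  tractogram_allow(sl, affine)
}

## ---- TRK (TrackVis, version 2) ---------------------------------------------

write_trk <- function(t, path) {
  affine <- t$space$affine
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  dim3 <- c(0L, 0L, 0L)  # grid dims are not tracked by the container
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(as.raw(0), con)
  writeBin(as.integer(dim3), con, size = 2, endian = "little")
  writeBin(as.numeric(vs), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(200), con)                                      # scalar names
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(200), con)                                      # property names
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                      # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(as.raw(0), con)
  writeBin(raw(4), con)                                        # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                        # pad1
  writeBin(raw(6), con)                                        # invert/swap
  writeBin(length(t$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  inv <- solve_affine(affine)
  for (s in t$streamlines) {
    ijk <- cbind(s, 1) %*% t(inv)
    vmm <- sweep(ijk[, 1:3, drop = FALSE] + 0.5, 2, vs, `*`)
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.vector(t(vmm)), con, size = 4, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK")) {
    stop("format error: not a TRK file (bad magic)", call. = FALSE)
  }
  readBin(con, "raw", 1)
  readBin(con, "integer", 3, size = 2, endian = "little")
  vs <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  affine <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  readBin(con, "raw", 444)
  readBin(con, "raw", 4)  # voxel_order
  readBin(con, "raw", 4)
  readBin(con, "numeric", 6, size = 4, endian = "little")
  readBin(con, "raw", 2)
  readBin(con, "raw", 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L) {
    stop("format error: corrupt TRK header (hdr_size != 1000)", call. = FALSE)
  }
  if (all(affine == 0)) affine <- diag(4)  # version-1 files carry no matrix
  sl <- vector("list", max(n_count, 0))
  i <- 0
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0) break
    vals <- readBin(con, "numeric", npts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4,
                             endian = "little")
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    ijk <- sweep(m, 2, vs, `/`) - 0.5
    world <- cbind(ijk, 1) %*% t(affine)
    i <- i + 1
    if (i > length(sl)) sl <- c(sl, vector("list", 16))
    sl[[i]] <- world[, 1:3, drop = FALSE]
  }
  tractogram_allow(sl[seq_len(i)], affine)
}

# Internal: tractogram() that tolerates emptiness (I/O layer round-trips).
tractogram_allow <- function(sl, affine) {
  structure(list(streamlines = sl,
                 space = list(units = "mm", affine = affine)),
            class = "tractogram")
}
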