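# Minimal baseline-TIFF codec: little-endian, uncompressed, 16-bit
# grayscale, multipage. The guaranteed runtime has no TIFF package, and the
# interchange format is fixed (2 pages, one strip per page), so a complete
# general-purpose reader is out of scope; unsupported variants error out.

.u16 <- function(v) as.raw(as.vector(rbind(v %% 256L, (v %/% 256L) %% 256L)))
.u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256,
                         (v %/% 65536) %% 256, (v %/% 16777216) %% 256)))
}

#' Write a multipage 16-bit grayscale TIFF
#'
#' One page per matrix, values on the 16-bit scale (0-65535), stored
#' uncompressed as a single strip, little-endian.
#'
#' @param pages list of integer matrices (or a single matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  n_entries <- 10L
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout: 8-byte header, then per page pixel data, then all IFDs
  data_sizes <- vapply(pages, function(p) 2L * length(p), integer(1))
  data_off <- 8L + c(0L, cumsum(data_sizes))[seq_along(pages)]
  ifd0 <- 8L + sum(data_sizes)
  ifd_off <- ifd0 + (seq_along(pages) - 1L) * ifd_size

  entry <- function(tag, type, count, value) {
    # type 3 = SHORT, 4 = LONG; count-1 values packed into the value field
    val <- if (type == 3L) c(.u16(value), as.raw(c(0, 0))) else .u32(value)
    c(.u16(tag), .u16(type), .u32(count), val)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), .u16(42L), .u32(ifd0)), con)
  for (p in pages) {
    v <- as.integer(t(p))  # TIFF is row-major
    if (any(v < 0 | v > 65535)) stop("pixel values outside 16-bit range")
    writeBin(.u16(v), con)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    e <- c(entry(256L, 4L, 1L, ncol(p)),           # ImageWidth
           entry(257L, 4L, 1L, nrow(p)),           # ImageLength
           entry(258L, 3L, 1L, 16L),               # BitsPerSample
           entry(259L, 3L, 1L, 1L),                # Compression: none
           entry(262L, 3L, 1L, 1L),                # Photometric: BlackIsZero
           entry(273L, 4L, 1L, data_off[i]),       # StripOffsets
           entry(277L, 3L, 1L, 1L),                # SamplesPerPixel
           entry(278L, 4L, 1L, nrow(p)),           # RowsPerStrip
           entry(279L, 4L, 1L, data_sizes[i]),     # StripByteCounts
           entry(339L, 3L, 1L, 1L))                # SampleFormat: uint
    nxt <- if (i < length(pages)) ifd_off[i + 1L] else 0L
    writeBin(c(.u16(n_entries), e, .u32(nxt)), con)
  }
  invisible(path)
}

#' Read a multipage 16-bit grayscale TIFF
#'
#' Supports the interchange dialect written by [write_tiff16()] (and any
#' uncompressed, little-endian, 16-bit, single-sample baseline TIFF).
#'
#' @param path file path.
#' @return list of integer matrices, one per page.
#' @export
read_tiff16 <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  ru16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  ru32 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L]) +
    65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
  if (length(raw) < 8 || raw[1] != as.raw(0x49) || raw[2] != as.raw(0x49) ||
      ru16(2L) != 42L)
    stop("not a little-endian TIFF: ", path)
  pages <- list()
  ifd <- ru32(4L)
  while (ifd != 0) {
    n <- ru16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- ru16(e); type <- ru16(e + 2L); count <- ru32(e + 4L)
      val <- if (count == 1L) {
        if (type == 3L) ru16(e + 8L) else ru32(e + 8L)
      } else {
        off <- ru32(e + 8L)
        step <- if (type == 3L) 2L else 4L
        vapply(seq_len(count), function(j) {
          if (type == 3L) ru16(off + (j - 1L) * step)
          else ru32(off + (j - 1L) * step)
        }, numeric(1))
      }
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("malformed TIFF IFD: ", path)
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stop("unsupported TIFF compression (", tags[["259"]], "): ", path)
    bps <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    if (bps != 16L) stop("unsupported bits per sample (", bps, "): ", path)
    w <- tags[["256"]]; h <- tags[["257"]]
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    buf <- integer(0)
    for (s in seq_along(offs)) {
      o <- offs[s]; nb <- cnts[s]
      idx <- o + seq_len(nb)
      b <- raw[idx]
      buf <- c(buf, as.integer(b[seq(1, nb, 2)]) +
                 256L * as.integer(b[seq(2, nb, 2)]))
    }
    if (length(buf) != w * h) stop("TIFF strip size mismatch: ", path)
    pages[[length(pages) + 1L]] <- matrix(buf, h, w, byrow = TRUE)
    ifd <- ru32(ifd + 2L + n * 12L)
  }
  pages
}
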