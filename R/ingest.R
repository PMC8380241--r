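#' Single-cell gating configuration
#'
#' The published gate set that refines acquired events to in-focus single
#' cells: brightfield area 200-500 um^2 against aspect ratio 0.75-1.0
#' (debris/doublet removal), and brightfield gradient RMS 55-80 (focus).
#' The wider 100-900 um^2 acquisition area range is what the cytometer
#' applies at capture time. All gate boundaries are inclusive.
#'
#' @param area_range brightfield area gate, um^2.
#' @param aspect_ratio_range aspect ratio gate (minor/major axis).
#' @param gradient_rms_range focus gate.
#' @param acquisition_area_range capture-time area range, um^2.
#' @return object of class `gating_config`.
#' @export
gating_config <- function(area_range = c(200, 500),
                          aspect_ratio_range = c(0.75, 1.0),
                          gradient_rms_range = c(55, 80),
                          acquisition_area_range = c(100, 900)) {
  chk <- function(r) length(r) == 2L && r[1] <= r[2]
  stopifnot(chk(area_range), chk(aspect_ratio_range),
            chk(gradient_rms_range), chk(acquisition_area_range))
  structure(list(area_range = area_range,
                 aspect_ratio_range = aspect_ratio_range,
                 gradient_rms_range = gradient_rms_range,
                 acquisition_area_range = acquisition_area_range),
            class = "gating_config")
}

# calibration of the Sobel-based focus surrogate: chosen once so that the
# default synthetic in-focus population median sits at 67.5, the centre of
# the published 55-80 gradient-RMS focus window
.GRMS_CALIB <- 344.0

#' Compute gating features from a cell image
#'
#' Surrogates for the proprietary cytometer feature definitions, computed
#' from the brightfield channel: the object mask is found by thresholding
#' the smoothed absolute deviation from the border background level; area
#' is the mask pixel count scaled by the pixel size squared; aspect ratio
#' is the minor/major axis ratio of the mask's second-moment ellipse; and
#' the focus score is the root mean square of the Sobel gradient magnitude
#' over the mask, linearly calibrated onto the published 55-80 in-focus
#' window.
#'
#' @param image `img x img x 2` array (channel 2 = brightfield) or a single
#'   brightfield matrix, on the 16-bit (or 0-1) scale.
#' @param pixel_size microns per pixel.
#' @return list(brightfield_area, aspect_ratio, gradient_rms).
#' @export
compute_gating_features <- function(image, pixel_size = PIXEL_SIZE_UM) {
  bf <- if (length(dim(image)) == 3L) image[, , 2] else image
  bf <- bf / if (max(bf) > 1.5) 65535 else 1
  border <- c(bf[1:2, ], bf[nrow(bf) - 1:0, ], bf[, 1:2], bf[, ncol(bf) - 1:0])
  dev <- cpp_gaussian_blur(abs(bf - median(border)), 1.0)
  thr <- max(0.02, 0.3 * max(dev))
  mask <- dev >= thr
  npx <- sum(mask)
  if (npx == 0L) stop("no object: empty foreground mask")
  area <- npx * pixel_size^2
  ij <- which(mask, arr.ind = TRUE)
  cov_m <- stats::cov(ij) * (npx - 1) / npx + diag(1 / 12, 2)  # pixel extent
  ev <- eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values
  ar <- sqrt(max(ev[2], 0) / ev[1])
  g <- cpp_sobel_mag(bf)
  grms <- .GRMS_CALIB * sqrt(mean(g[mask]^2))
  list(brightfield_area = area, aspect_ratio = ar, gradient_rms = grms)
}

#' Gate records to in-focus single cells
#'
#' Keeps records whose features fall inside all three gates (area, aspect
#' ratio, gradient RMS), boundaries inclusive. Accepts either a list of
#' cell records (with `$features`) or a manifest-style data frame with
#' columns `area_um2`, `aspect_ratio`, `gradient_rms`.
#'
#' @param records list of cell records, or a data.frame.
#' @param cfg a [gating_config()].
#' @return list with `kept` and `rejected` (same type as the input);
#'   together they partition the input, order preserved.
#' @export
gate_single_cells <- function(records, cfg = gating_config()) {
  stopifnot(inherits(cfg, "gating_config"))
  feats <- if (is.data.frame(records)) {
    data.frame(area = records$area_um2, ar = records$aspect_ratio,
               g = records$gradient_rms)
  } else {
    data.frame(
      area = vapply(records, function(r) r$features$brightfield_area, numeric(1)),
      ar = vapply(records, function(r) r$features$aspect_ratio, numeric(1)),
      g = vapply(records, function(r) r$features$gradient_rms, numeric(1)))
  }
  keep <- !is.na(feats$area) & !is.na(feats$ar) & !is.na(feats$g) &
    feats$area >= cfg$area_range[1] & feats$area <= cfg$area_range[2] &
    feats$ar >= cfg$aspect_ratio_range[1] & feats$ar <= cfg$aspect_ratio_range[2] &
    feats$g >= cfg$gradient_rms_range[1] & feats$g <= cfg$gradient_rms_range[2]
  if (is.data.frame(records)) {
    list(kept = records[keep, , drop = FALSE],
         rejected = records[!keep, , drop = FALSE])
  } else {
    list(kept = records[keep], rejected = records[!keep])
  }
}

#' Min/max rescale a channel onto the full 16-bit range
#'
#' `(x - min) / (max - min)` mapped to 0-65535 (illumination
#' normalisation). Order-preserving and idempotent up to quantisation;
#' half-range values quantise to 32768 (round-half-even at 32767.5). A
#' constant image maps to all zeros with a warning.
#'
#' @param image numeric matrix (any scale).
#' @return integer matrix on the 16-bit scale.
#' @export
normalize_channel <- function(image) {
  stopifnot(length(image) > 0)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image: normalize_channel returns all zeros")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  matrix(as.integer(round((image - lo) / (hi - lo) * 65535)),
         nrow(image), ncol(image))
}

#' Centre crop / zero-pad to a square target size
#'
#' Dimensions smaller than `target` are centre-padded with zeros (extra
#' pixel goes to the bottom/right); larger dimensions are centre-cropped
#' (starting at `floor((n - target) / 2) + 1`).
#'
#' @param image numeric matrix.
#' @param target output side length.
#' @return `target x target` matrix.
#' @export
crop_pad <- function(image, target = 64L) {
  fix_dim <- function(m, n, byrow) {
    cur <- if (byrow) nrow(m) else ncol(m)
    if (cur == n) return(m)
    if (cur > n) {
      start <- floor((cur - n) / 2) + 1L
      idx <- start:(start + n - 1L)
      if (byrow) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    } else {
      pre <- floor((n - cur) / 2); post <- n - cur - pre
      if (byrow) {
        rbind(matrix(0, pre, ncol(m)), m, matrix(0, post, ncol(m)))
      } else {
        cbind(matrix(0, nrow(m), pre), m, matrix(0, nrow(m), post))
      }
    }
  }
  out <- fix_dim(fix_dim(image, target, TRUE), target, FALSE)
  if (is.integer(image)) storage.mode(out) <- "integer"
  out
}

.MANIFEST_COLS <- c("file", "label", "lab", "compound", "concentration",
                    "replicate", "area_um2", "aspect_ratio", "gradient_rms")

#' Write a cell image dataset (TIFFs + CSV manifest)
#'
#' Each record becomes one two-page 16-bit TIFF (page 1 nuclear
#' fluorescence, page 2 brightfield) plus one manifest row holding its
#' label, provenance and gating features.
#'
#' @param records list of cell records (see [sample_population()]).
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within `dir`.
#' @return path to the manifest CSV, invisibly.
#' @export
write_dataset <- function(records, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    fn <- sprintf("cell_%06d.tif", i)
    write_tiff16(list(r$image[, , 1], r$image[, , 2]), file.path(dir, fn))
    m <- r$meta
    rows[[i]] <- data.frame(
      file = fn, label = r$label,
      lab = if (is.null(m$lab)) "" else m$lab,
      compound = if (is.null(m$compound)) "" else m$compound,
      concentration = if (is.null(m$concentration)) NA_real_ else m$concentration,
      replicate = if (is.null(m$replicate)) NA_integer_ else m$replicate,
      area_um2 = r$features$brightfield_area,
      aspect_ratio = r$features$aspect_ratio,
      gradient_rms = r$features$gradient_rms,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  path <- file.path(dir, manifest)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell image dataset from its manifest
#'
#' Validates that every TIFF has exactly two pages and every label is in
#' the nine-class taxonomy (errors name the offending manifest row).
#'
#' @param manifest path to the manifest CSV written by [write_dataset()].
#' @return list of cell records.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  missing <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing) > 0)
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  dir <- dirname(manifest)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!(df$label[i] %in% PHENOTYPE_CLASSES))
      stop("manifest row ", i, ": unknown label '", df$label[i], "'")
    path <- file.path(dir, df$file[i])
    pages <- read_tiff16(path)
    if (length(pages) != 2L)
      stop("manifest row ", i, ": expected a 2-page TIFF, got ",
           length(pages), " page(s) in ", df$file[i])
    img <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), 2))
    img[, , 1] <- pages[[1]]; img[, , 2] <- pages[[2]]
    records[[i]] <- list(
      image = img, label = df$label[i],
      features = list(brightfield_area = df$area_um2[i],
                      aspect_ratio = df$aspect_ratio[i],
                      gradient_rms = df$gradient_rms[i]),
      meta = list(lab = df$lab[i], compound = df$compound[i],
                  concentration = df$concentration[i],
                  replicate = df$replicate[i], file = df$file[i]))
  }
  records
}

#' Standardise a raw image stack for the network
#'
#' Applies the pre-processing used on extracted cytometer images: each
#' channel min/max rescaled to the full 16-bit range, then centre
#' cropped/zero-padded to `target` pixels square.
#'
#' @param image 2-channel array or list of 2 matrices.
#' @param target output side length.
#' @return `target x target x 2` integer array.
#' @export
standardize_image <- function(image, target = 64L) {
  chans <- if (is.list(image)) image else list(image[, , 1], image[, , 2])
  out <- array(0L, dim = c(target, target, 2))
  for (c in 1:2)
    out[, , c] <- crop_pad(suppressWarnings(normalize_channel(chans[[c]])),
                           target)
  out
}
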