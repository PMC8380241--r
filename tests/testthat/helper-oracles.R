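# Independent test oracles. These deliberately avoid the package's own
# image-analysis code paths: connected components are found by a plain BFS
# flood fill on a mid-intensity threshold, metrics by one-vs-rest tallies.

# Connected components (8-connectivity) of the fluorescence channel after
# thresholding at mid-intensity ((max+min)/2). Returns a data.frame of
# component sizes and equivalent-circle diameters, largest first.
blob_oracle <- function(fluor) {
  thr <- (max(fluor) + min(fluor)) / 2
  mask <- fluor > thr
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  sizes <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cur
    sz <- 0L
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      sz <- sz + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  d <- data.frame(size = sizes, diameter = 2 * sqrt(sizes / pi))
  d[order(-d$size), , drop = FALSE]
}

# Classify a rendered cell by the blob oracle using the CBMN size rule:
# components with diameter > 1/3 of the largest blob diameter are nuclei,
# those within [1/16, 1/3] (and >= 2 px) are micronuclei.
blob_phenotype <- function(image) {
  blobs <- blob_oracle(image[, , 1])
  blobs <- blobs[blobs$size >= 3, , drop = FALSE]   # discard noise specks
  if (nrow(blobs) == 0) return(NA_character_)
  ref <- blobs$diameter[1]
  n_nuc <- sum(blobs$diameter > ref / 3)
  n_mn <- sum(blobs$diameter <= ref / 3 & blobs$diameter >= ref / 16 &
                blobs$diameter >= 2)
  if (n_nuc < 1 || n_nuc > 4) return(NA_character_)
  phenotype_from_counts(n_nuc, n_mn > 0)
}

# Brute-force one-vs-rest confusion metrics, independent of the package's
# vectorised implementation.
brute_metrics <- function(truth, predicted, classes) {
  out <- NULL
  for (cl in classes) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    out <- rbind(out, data.frame(
      class = cl,
      precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_))
  }
  out
}

# Deterministic small rendered dataset shared by several test files.
make_test_records <- function(labels, seed0 = 900) {
  recs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- mnflow:::withr_seed(seed0 + 7L * i, random_cell_spec(labels[i]))
    recs[[i]] <- list(image = render_cell(sp, lab_profile(), seed = seed0 + 7L * i + 1L),
                      label = labels[i], spec = sp,
                      meta = list(lab = "testlab"))
  }
  recs
}
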