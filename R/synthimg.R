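#' Laboratory rendering profile
#'
#' Captures the between-laboratory nuisance variation the classifier must
#' tolerate: stain brightness, background offset, focus blur, illumination
#' gradient across the field and sensor noise. The default profile renders
#' an in-focus, well-stained population; alternative profiles emulate other
#' cytometers/stains.
#'
#' @param name profile label stored in record metadata.
#' @param fluor_gain stain brightness multiplier (> 0).
#' @param background_level fluorescence background, fraction of dynamic
#'   range in `[0, 1)`.
#' @param blur_sigma_px Gaussian point-spread sigma in pixels (>= 0).
#' @param illumination_tilt fractional intensity gradient across the field.
#' @param channel_noise_sd additive Gaussian noise sd, fraction of range.
#' @return object of class `lab_profile`.
#' @export
lab_profile <- function(name = "default", fluor_gain = 1.0,
                        background_level = 0.05, blur_sigma_px = 0.8,
                        illumination_tilt = 0.04, channel_noise_sd = 0.015) {
  stopifnot(fluor_gain > 0, background_level >= 0, background_level < 1,
            blur_sigma_px >= 0, channel_noise_sd >= 0)
  structure(list(name = name, fluor_gain = fluor_gain,
                 background_level = background_level,
                 blur_sigma_px = blur_sigma_px,
                 illumination_tilt = illumination_tilt,
                 channel_noise_sd = channel_noise_sd),
            class = "lab_profile")
}

#' Pixel size of the rendered field
#'
#' Nominal 40x ImageStream calibration used to convert mask areas to square
#' microns for the gating features.
#' @export
PIXEL_SIZE_UM <- 0.33

# admissible micronucleus diameter ratio (MN diameter / mean parent nucleus
# diameter) under standard CBMN scoring rules
.MN_RATIO_MIN <- 1 / 16
.MN_RATIO_MAX <- 1 / 3

#' Geometric specification of one synthetic cell
#'
#' @param phenotype a label from [PHENOTYPE_CLASSES].
#' @param n_nuclei integer 1-4 (ignored for `other`).
#' @param n_micronuclei integer >= 0.
#' @param mn_diameter_ratios MN diameter as a fraction of the mean parent
#'   nucleus diameter; every value must lie in the admissible scoring range
#'   `[1/16, 1/3]`.
#' @param nucleus_diameters_px numeric, one diameter per nucleus.
#' @param cell_diameter_px cell disc diameter in pixels.
#' @param unscorable_kind for `other`: one of debris, doublet,
#'   out_of_focus, mitotic, dead.
#' @return object of class `cell_spec`.
#' @export
cell_spec <- function(phenotype, n_nuclei = NULL, n_micronuclei = NULL,
                      mn_diameter_ratios = NULL, nucleus_diameters_px = NULL,
                      cell_diameter_px = 57, unscorable_kind = NULL) {
  assert_phenotype(phenotype)
  if (phenotype == "other") {
    if (is.null(unscorable_kind)) unscorable_kind <- "debris"
    stopifnot(unscorable_kind %in% .UNSCORABLE_KINDS)
    n_nuclei <- if (is.null(n_nuclei)) 2L else n_nuclei
    n_micronuclei <- 0L
    mn_diameter_ratios <- numeric(0)
  } else {
    base_n <- match(sub("_mn$", "", phenotype),
                    c("mononucleate", "binucleate", "trinucleate",
                      "tetranucleate"))
    if (is.null(n_nuclei)) n_nuclei <- base_n
    if (n_nuclei != base_n)
      stop("n_nuclei = ", n_nuclei, " inconsistent with phenotype '",
           phenotype, "'")
    has_mn <- grepl("_mn$", phenotype)
    if (is.null(n_micronuclei)) n_micronuclei <- if (has_mn) 1L else 0L
    if (has_mn != (n_micronuclei > 0))
      stop("n_micronuclei = ", n_micronuclei,
           " inconsistent with phenotype '", phenotype, "'")
    if (is.null(mn_diameter_ratios))
      mn_diameter_ratios <- rep(0.22, n_micronuclei)
    if (length(mn_diameter_ratios) != n_micronuclei)
      stop("need one mn_diameter_ratio per micronucleus")
    if (n_micronuclei > 0 &&
        (any(mn_diameter_ratios < .MN_RATIO_MIN - 1e-12) ||
         any(mn_diameter_ratios > .MN_RATIO_MAX + 1e-12)))
      stop("mn_diameter_ratios must lie in [1/16, 1/3] of the parent ",
           "nucleus diameter (got ",
           paste(signif(mn_diameter_ratios, 3), collapse = ", "), ")")
  }
  if (is.null(nucleus_diameters_px)) {
    frac <- c(0.42, 0.34, 0.30, 0.27)[min(n_nuclei, 4)]
    nucleus_diameters_px <- rep(frac * cell_diameter_px, n_nuclei)
  }
  stopifnot(length(nucleus_diameters_px) == n_nuclei,
            cell_diameter_px > 0, all(nucleus_diameters_px > 0))
  structure(list(phenotype = phenotype, n_nuclei = as.integer(n_nuclei),
                 n_micronuclei = as.integer(n_micronuclei),
                 mn_diameter_ratios = mn_diameter_ratios,
                 nucleus_diameters_px = nucleus_diameters_px,
                 cell_diameter_px = cell_diameter_px,
                 unscorable_kind = unscorable_kind),
            class = "cell_spec")
}

#' Draw a random cell specification for a phenotype class
#'
#' Samples morphology from the generator's default distributions: cell
#' diameter uniform 54-60 px (disc area 236-308 um^2 at 0.33 um/px, inside
#' the 200-500 um^2 single-cell gate), nucleus diameters jittered +-8%
#' around a per-class fraction of the cell diameter, 1-2 micronuclei with
#' diameter ratios uniform on [0.15, 0.26], and a uniformly drawn
#' unscorable kind for the `other` class. Uses the current RNG stream.
#'
#' @param phenotype class label.
#' @return a [cell_spec()].
#' @export
random_cell_spec <- function(phenotype) {
  assert_phenotype(phenotype)
  cd <- runif(1, 54, 60)
  if (phenotype == "other") {
    return(cell_spec("other", cell_diameter_px = cd,
                     unscorable_kind = sample(.UNSCORABLE_KINDS, 1)))
  }
  n <- match(sub("_mn$", "", phenotype),
             c("mononucleate", "binucleate", "trinucleate", "tetranucleate"))
  has_mn <- grepl("_mn$", phenotype)
  n_mn <- if (has_mn) 1L + rbinom(1, 1, 0.25) else 0L
  frac <- c(0.42, 0.34, 0.30, 0.27)[n]
  nd <- frac * cd * runif(n, 0.92, 1.08)
  cell_spec(phenotype, n_nuclei = n, n_micronuclei = n_mn,
            mn_diameter_ratios = if (n_mn > 0) runif(n_mn, 0.15, 0.26)
                                 else NULL,
            nucleus_diameters_px = nd, cell_diameter_px = cd)
}

# soft-edged disc on an img x img grid (row = y, col = x), 1-based centre
.blob <- function(img, cx, cy, r, edge = 0.6) {
  x <- matrix(seq_len(img), img, img, byrow = TRUE)
  y <- matrix(seq_len(img), img, img)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  1 / (1 + exp((d - r) / edge))
}

# place n nuclei on a jittered ring around the cell centre so that every
# pair keeps a clear fluorescence valley between them (distinct connected
# components at a mid-intensity threshold); falls back to the exact regular
# polygon if the jittered draw violates the separation
.place_nuclei <- function(n, radii, cc, R_cell, gap = 2.5, margin = 1.5) {
  rmax <- max(R_cell - max(radii) - margin, 0.5)
  if (n == 1L) {
    rr <- runif(1, 0, min(3, rmax)); th <- runif(1, 0, 2 * pi)
    return(matrix(cc + rr * c(cos(th), sin(th)), 1, 2, byrow = TRUE))
  }
  sep <- max(outer(radii, radii, `+`)) + gap
  circum <- sep / (2 * sin(pi / n))
  base <- runif(1, 0, 2 * pi)
  draw <- function(jitter) {
    ang <- base + 2 * pi * seq_len(n) / n + runif(n, -jitter, jitter)
    rho <- pmin(circum * runif(n, 1.0, 1.12), rmax)
    cbind(cc[1] + rho * cos(ang), cc[2] + rho * sin(ang))
  }
  for (jit in c(0.25 / n, 0.1 / n)) {
    centers <- draw(jit)
    d <- as.matrix(dist(centers)); diag(d) <- Inf
    if (min(d) >= sep - 1e-9) return(centers)
  }
  ang <- base + 2 * pi * seq_len(n) / n   # exact polygon fallback
  rho <- min(circum * 1.05, rmax)
  cbind(cc[1] + rho * cos(ang), cc[2] + rho * sin(ang))
}

# rejection-sample n centres inside a disc (centre cc, radius R_eff per
# object), enforcing pairwise centre distance >= sep_frac*(r_i+r_j) + gap;
# used for texture fragments (debris, mitotic figures, dead-cell foci)
# where occasional contact is acceptable
.place_blobs <- function(n, radii, cc, R_cell, sep_frac = 1.0, gap = 2.5,
                         margin = 1.5, max_try = 400) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE; tries <- 0; sf <- sep_frac; g <- gap
    while (!ok) {
      tries <- tries + 1
      if (tries > max_try) { sf <- sf * 0.97; g <- g * 0.9; tries <- 0 }
      rmax <- max(R_cell - radii[i] - margin, 0.5)
      rr <- rmax * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      cand <- cc + rr * c(cos(th), sin(th))
      ok <- TRUE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          if (sqrt(sum((cand - centers[j, ])^2)) <
              sf * (radii[i] + radii[j]) + g) { ok <- FALSE; break }
        }
      }
    }
    centers[i, ] <- cand
  }
  centers
}

# apply lab nuisance effects to a [0,1] content image and quantise to 16-bit
.finish_channel <- function(content, lab, tilt_dir = 1) {
  img <- nrow(content)
  x <- matrix(seq_len(img), img, img, byrow = TRUE)
  content <- content * (1 + tilt_dir * lab$illumination_tilt *
                          (x - (img + 1) / 2) / img)
  content <- cpp_gaussian_blur(content, lab$blur_sigma_px)
  content <- content + rnorm(img * img, sd = lab$channel_noise_sd)
  content <- pmin(pmax(content, 0), 1)
  matrix(as.integer(round(content * 65535)), img, img)
}

#' Render one synthetic two-channel cell image
#'
#' Draws the nuclear fluorescence channel (one soft-edged bright blob per
#' nucleus plus one small blob per micronucleus) and the brightfield
#' channel (a textured cell disc with a darker rim on a mid-grey
#' background), then applies the laboratory profile: illumination tilt,
#' Gaussian blur, additive noise and 16-bit quantisation. Unscorable kinds
#' get dedicated renderings (debris speckle, touching doublet discs,
#' heavy defocus, fragmented mitotic texture, shrunken granular dead
#' cells). Deterministic for fixed `(spec, lab, seed)`.
#'
#' @param spec a [cell_spec()].
#' @param lab a [lab_profile()].
#' @param seed integer seed.
#' @param img image side in pixels (64, the network input size).
#' @return integer array `img x img x 2` on the 16-bit scale; channel 1 is
#'   nuclear fluorescence, channel 2 brightfield.
#' @export
render_cell <- function(spec, lab = lab_profile(), seed = 1L, img = 64L) {
  stopifnot(inherits(spec, "cell_spec"), inherits(lab, "lab_profile"))
  if (spec$n_micronuclei > 0 &&
      (any(spec$mn_diameter_ratios < .MN_RATIO_MIN - 1e-12) ||
       any(spec$mn_diameter_ratios > .MN_RATIO_MAX + 1e-12)))
    stop("mn_diameter_ratios must lie in [1/16, 1/3]")
  withr_seed(seed, .render_cell_impl(spec, lab, img))
}

.render_cell_impl <- function(spec, lab, img) {
  cc <- c((img + 1) / 2, (img + 1) / 2) + runif(2, -1.5, 1.5)
  R <- spec$cell_diameter_px / 2
  kind <- if (spec$phenotype == "other") spec$unscorable_kind else "normal"

  fl <- matrix(0, img, img)
  bf <- matrix(0.55, img, img)

  add_nuclei <- function(fl, centers, radii, amp = 0.72) {
    for (i in seq_len(nrow(centers))) {
      fl <- fl + amp * runif(1, 0.92, 1.08) *
        .blob(img, centers[i, 1], centers[i, 2], radii[i])
    }
    fl
  }
  add_cell_disc <- function(bf, cx, cy, R) {
    disc <- .blob(img, cx, cy, R)
    rim <- .blob(img, cx, cy, R + 0.8) - .blob(img, cx, cy, R - 0.8)
    tex <- cpp_gaussian_blur(matrix(rnorm(img * img, sd = 0.12), img, img), 1.2)
    bf + 0.10 * disc - 0.26 * rim + disc * tex * 0.35
  }

  if (kind == "normal" || kind == "out_of_focus" || kind == "mitotic") {
    n <- spec$n_nuclei
    radii <- spec$nucleus_diameters_px / 2
    centers <- .place_nuclei(n, radii, cc, R)
    if (kind == "mitotic") {
      # metaphase-spread-like cluster of small bright fragments
      nf <- 10L + sample.int(6L, 1)
      frag_r <- runif(nf, 1.2, 2.4)
      fc <- .place_blobs(nf, frag_r, cc, 0.45 * R, sep_frac = 0.6, gap = 0)
      fl <- add_nuclei(fl, fc, frag_r, amp = 0.8)
    } else {
      fl <- add_nuclei(fl, centers, radii)
    }
    bf <- add_cell_disc(bf, cc[1], cc[2], R)
    # nuclei faintly darken the brightfield
    if (kind != "mitotic") {
      for (i in seq_len(n))
        bf <- bf - 0.05 * .blob(img, centers[i, 1], centers[i, 2], radii[i])
    }
    if (spec$n_micronuclei > 0) {
      mean_nd <- mean(spec$nucleus_diameters_px)
      mn_r <- spec$mn_diameter_ratios * mean_nd / 2
      # place each MN clearly inside the cell, away from the nuclei
      mn_c <- matrix(NA_real_, spec$n_micronuclei, 2)
      for (m in seq_len(spec$n_micronuclei)) {
        for (t in seq_len(600)) {
          rmax <- max(R - mn_r[m] - 2.5, 1)
          rr <- rmax * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          cand <- cc + rr * c(cos(th), sin(th))
          dn <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                               byrow = TRUE))^2))
          prev_ok <- if (m > 1)
            all(sqrt(rowSums((mn_c[seq_len(m - 1), , drop = FALSE] -
              matrix(cand, m - 1, 2, byrow = TRUE))^2)) > 2 * mn_r[m] + 1)
            else TRUE
          if (all(dn > radii + mn_r[m] + 3.5) && prev_ok) break
        }
        mn_c[m, ] <- cand
        fl <- fl + 0.95 * runif(1, 0.95, 1.1) *
          .blob(img, cand[1], cand[2], mn_r[m], edge = 0.5)
      }
    }
    if (kind == "out_of_focus") lab$blur_sigma_px <- runif(1, 3.2, 4.5)
  } else if (kind == "debris") {
    nf <- 2L + sample.int(4L, 1)
    frag_r <- runif(nf, 0.8, 2.2)
    fc <- .place_blobs(nf, frag_r, cc, 6, sep_frac = 0.3, gap = 0)
    for (i in seq_len(nf))
      bf <- bf - runif(1, 0.1, 0.25) * .blob(img, fc[i, 1], fc[i, 2], frag_r[i])
    fl <- fl + 0.15 * .blob(img, fc[1, 1], fc[1, 2], frag_r[1])
  } else if (kind == "doublet") {
    R2 <- R * runif(1, 0.85, 1.0)
    off <- (R + R2) * 0.48
    th <- runif(1, 0, pi)
    c1 <- cc - off * c(cos(th), sin(th)) * 0.5
    c2 <- cc + off * c(cos(th), sin(th)) * 0.5
    bf <- add_cell_disc(bf, c1[1], c1[2], R * 0.75)
    bf <- add_cell_disc(bf, c2[1], c2[2], R2 * 0.75)
    r1 <- 0.34 * R * 0.75; r2 <- 0.34 * R2 * 0.75
    fl <- add_nuclei(fl, rbind(c1, c2), c(r1, r2))
  } else if (kind == "dead") {
    Rd <- R * runif(1, 0.40, 0.55)
    disc <- .blob(img, cc[1], cc[2], Rd)
    gran <- cpp_gaussian_blur(matrix(rnorm(img * img, sd = 0.5), img, img), 0.8)
    bf <- bf - 0.18 * disc + disc * gran * 0.5
    nf <- 3L + sample.int(4L, 1)
    frag_r <- runif(nf, 1.0, 2.5)
    fc <- .place_blobs(nf, frag_r, cc, Rd, sep_frac = 0.5, gap = 0)
    fl <- add_nuclei(fl, fc, frag_r, amp = 0.5)
  }

  fl <- pmin(lab$background_level + fl * lab$fluor_gain, 1.2)
  out <- array(0L, dim = c(img, img, 2))
  out[, , 1] <- .finish_channel(fl, lab, tilt_dir = 1)
  out[, , 2] <- .finish_channel(bf, lab, tilt_dir = -1)
  out
}

#' Population sampling specification
#'
#' @param class_frequencies probability vector over [PHENOTYPE_CLASSES]
#'   (named or in taxonomy order); must sum to 1.
#' @param n_cells number of cells to draw (> 0).
#' @param lab a [lab_profile()].
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(class_frequencies, n_cells, lab = lab_profile(),
                            seed = 1L) {
  if (!is.null(names(class_frequencies))) {
    stopifnot(setequal(names(class_frequencies), PHENOTYPE_CLASSES))
    class_frequencies <- class_frequencies[PHENOTYPE_CLASSES]
  }
  stopifnot(length(class_frequencies) == 9L,
            abs(sum(class_frequencies) - 1) < 1e-8,
            all(class_frequencies >= 0))
  if (n_cells <= 0) stop("n_cells must be > 0")
  structure(list(class_frequencies = as.numeric(class_frequencies),
                 n_cells = as.integer(n_cells), lab = lab,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a labelled synthetic cell population
#'
#' Draws class labels from the population's class frequencies, renders each
#' cell with [render_cell()], and attaches gating features computed with
#' [compute_gating_features()]. Deterministic for a fixed spec.
#'
#' @param pop a [population_spec()].
#' @param meta optional named list merged into each record's metadata
#'   (e.g. compound, concentration, replicate).
#' @param render if FALSE, skip image rendering: records carry the label
#'   and cell spec only (fast label/spec sampling for large populations).
#' @return list of cell records: each has `image` (64x64x2 integer array,
#'   or NULL when `render = FALSE`), `label`, `spec`, `features`
#'   (brightfield_area, aspect_ratio, gradient_rms) and `meta`.
#' @export
sample_population <- function(pop, meta = list(), render = TRUE) {
  stopifnot(inherits(pop, "population_spec"))
  withr_seed(pop$seed, {
    labels <- sample(PHENOTYPE_CLASSES, pop$n_cells, replace = TRUE,
                     prob = pop$class_frequencies)
    cell_seeds <- sample.int(.Machine$integer.max - 1L, pop$n_cells)
    specs <- lapply(labels, random_cell_spec)
  })
  records <- vector("list", pop$n_cells)
  if (!render) {
    for (i in seq_len(pop$n_cells)) {
      records[[i]] <- list(image = NULL, label = labels[i],
                           spec = specs[[i]],
                           features = list(brightfield_area = NA_real_,
                                           aspect_ratio = NA_real_,
                                           gradient_rms = NA_real_),
                           meta = c(list(lab = pop$lab$name), meta))
    }
    return(records)
  }
  for (i in seq_len(pop$n_cells)) {
    imgarr <- render_cell(specs[[i]], pop$lab, seed = cell_seeds[i])
    feats <- tryCatch(compute_gating_features(imgarr), error = function(e)
      list(brightfield_area = 0, aspect_ratio = NA_real_,
           gradient_rms = NA_real_))
    records[[i]] <- list(image = imgarr, label = labels[i],
                         spec = specs[[i]], features = feats,
                         meta = c(list(lab = pop$lab$name), meta))
  }
  records
}

#' Dose-response experiment specification
#'
#' Mirrors the three-concentration-plus-control, triplicate design with
#' 2000 scored events per sample. The true binucleated-cell MN frequency
#' follows a Hill-shaped induction curve
#' `f(x) = f0 * (1 + (F - 1) * x^d / (b^d + x^d))`
#' with median-preserving lognormal replicate noise.
#'
#' @param concentrations exposure concentrations (ug/mL); must include 0.
#' @param replicates replicates per concentration (>= 1).
#' @param n_scored_per_sample events scored per replicate sample.
#' @param background_mn_freq vehicle-control MN frequency `f0` in (0, 1).
#' @param potency_param Hill half-maximal concentration `b` (ug/mL).
#' @param max_fold_induction plateau fold-change `F` over background.
#' @param steepness Hill log-steepness `d`.
#' @param noise_model lognormal (natural-log) sd of replicate noise.
#' @param seed integer seed.
#' @return object of class `dose_response_spec`.
#' @export
dose_response_spec <- function(concentrations = c(0, 0.8, 1.2, 1.6),
                               replicates = 3L, n_scored_per_sample = 2000L,
                               background_mn_freq = 0.01,
                               potency_param = 1.0, max_fold_induction = 8,
                               steepness = 2, noise_model = 0.15,
                               seed = 1L) {
  if (!any(concentrations == 0))
    stop("concentrations must include 0 (vehicle control)")
  stopifnot(background_mn_freq > 0, background_mn_freq < 1, replicates >= 1,
            potency_param > 0, max_fold_induction >= 1, steepness > 0,
            noise_model >= 0, n_scored_per_sample > 0)
  structure(list(concentrations = sort(unique(concentrations)),
                 replicates = as.integer(replicates),
                 n_scored_per_sample = as.integer(n_scored_per_sample),
                 background_mn_freq = background_mn_freq,
                 potency_param = potency_param,
                 max_fold_induction = max_fold_induction,
                 steepness = steepness, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "dose_response_spec")
}

#' Hill-shaped mean induction curve
#'
#' @param x concentration(s).
#' @param f0 background frequency.
#' @param fold plateau fold-change over background.
#' @param b half-maximal concentration.
#' @param d log-steepness.
#' @return expected MN frequency at `x`.
#' @export
induction_curve <- function(x, f0, fold, b, d) {
  f0 * (1 + (fold - 1) * x^d / (b^d + x^d))
}

#' Simulate a full dose-response experiment
#'
#' For each concentration x replicate, draws a per-replicate expected MN
#' frequency from the induction curve with lognormal noise, then scores
#' `n_scored_per_sample` events from a multinomial phenotype mix whose
#' binucleate-with-MN share realises that frequency. Returns the
#' per-replicate binucleated-cell MN frequencies plus, as attributes, the
#' generating curve and its closed-form ground-truth BMD at the given CES.
#'
#' @param drspec a [dose_response_spec()].
#' @param ces critical effect size used for the reported ground-truth BMD.
#' @param render_images if TRUE, also render the image population for each
#'   sample (slow; sized by `n_images_per_sample`).
#' @param n_images_per_sample images per sample when rendering.
#' @param lab a [lab_profile()] used when rendering.
#' @return data.frame with columns concentration, replicate, response
#'   (binucleated-cell MN frequency), n_binucleated, n_scored; attributes
#'   `true_bmd`, `curve` (list of f0, fold, b, d) and, when rendered,
#'   `images` (list of record lists, one per row).
#' @export
simulate_experiment <- function(drspec, ces = 0.5, render_images = FALSE,
                                n_images_per_sample = 200L,
                                lab = lab_profile()) {
  stopifnot(inherits(drspec, "dose_response_spec"))
  f0 <- drspec$background_mn_freq
  fold <- drspec$max_fold_induction
  b <- drspec$potency_param; d <- drspec$steepness
  # baseline phenotype mix of a cytochalasin-B-blocked TK6 population
  base <- c(mononucleate = 0.28, binucleate = 0.55, trinucleate = 0.035,
            tetranucleate = 0.020, other = 0.115)
  rows <- expand.grid(replicate = seq_len(drspec$replicates),
                      concentration = drspec$concentrations)[, 2:1]
  out <- NULL
  images <- list()
  withr_seed(drspec$seed, {
    img_seeds <- sample.int(.Machine$integer.max - 1L, nrow(rows))
    for (r in seq_len(nrow(rows))) {
      x <- rows$concentration[r]
      p_mean <- induction_curve(x, f0, fold, b, d)
      p_rep <- min(p_mean * exp(rnorm(1, 0, drspec$noise_model)), 0.5)
      # split each nucleation class into with/without MN at the replicate's
      # frequency (mono at a reduced rate: MN expression needs division)
      freqs <- c(base["mononucleate"] * c(1 - 0.5 * p_rep, 0.5 * p_rep),
                 base["binucleate"] * c(1 - p_rep, p_rep),
                 base["trinucleate"] * c(1 - p_rep, p_rep),
                 base["tetranucleate"] * c(1 - p_rep, p_rep),
                 base["other"])
      names(freqs) <- PHENOTYPE_CLASSES
      counts <- as.integer(rmultinom(1, drspec$n_scored_per_sample, freqs))
      names(counts) <- PHENOTYPE_CLASSES
      n_bn <- counts["binucleate"] + counts["binucleate_mn"]
      resp <- if (n_bn > 0) counts["binucleate_mn"] / n_bn else NA_real_
      out <- rbind(out, data.frame(concentration = x,
                                   replicate = rows$replicate[r],
                                   response = as.numeric(resp),
                                   n_binucleated = as.integer(n_bn),
                                   n_scored = drspec$n_scored_per_sample))
      if (render_images) {
        pop <- population_spec(freqs, n_images_per_sample, lab = lab,
                               seed = img_seeds[r])
        images[[r]] <- sample_population(pop, meta = list(
          compound = "synthetic", concentration = x,
          replicate = rows$replicate[r]))
      }
    }
  })
  attr(out, "curve") <- list(f0 = f0, fold = fold, b = b, d = d)
  attr(out, "true_bmd") <- {
    h <- ces / (fold - 1)
    if (fold <= 1 + ces) NA_real_ else b * (h / (1 - h))^(1 / d)
  }
  if (render_images) attr(out, "images") <- images
  out
}
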