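#' Network architecture configuration
#'
#' Describes the Inception-style dual-path classifier used for nine-class
#' CBMN scoring: a 3x3 stem convolution, then `length(block_widths)` scales
#' each holding `n_blocks_per_scale` dual-path subunits (a 1x1 and a 3x3
#' convolution, each followed by batch normalisation and ReLU, concatenated
#' to `block_widths[s]` channels), 2x2 max pools between scales, global
#' average pooling and a softmax classification layer. `stem_pool` inserts a
#' 2x2 max pool after the stem so the scales run at 32/16/8 px, keeping
#' single-CPU training tractable.
#'
#' @param n_classes number of output classes (9, or 6 for the merged
#'   polynucleated variant).
#' @param block_widths concatenated channel width per scale.
#' @param n_blocks_per_scale dual-path subunits per scale (recycled).
#' @param stem_width stem convolution channels.
#' @param stem_pool logical; max-pool directly after the stem.
#' @param img square input size in pixels.
#' @param in_channels input channels (nuclear fluorescence, brightfield).
#' @param seed integer seed for weight initialisation.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_classes = 9L, block_widths = c(32L, 64L, 128L),
                           n_blocks_per_scale = 2L, stem_width = 32L,
                           stem_pool = TRUE, img = 64L, in_channels = 2L,
                           seed = 1L) {
  n_blocks_per_scale <- rep_len(as.integer(n_blocks_per_scale),
                                length(block_widths))
  stopifnot(n_classes >= 2, all(block_widths %% 2 == 0),
            all(block_widths > 0), all(n_blocks_per_scale >= 1),
            stem_width > 0, img %% (2^(length(block_widths) - 1 + stem_pool)) == 0)
  structure(list(n_classes = as.integer(n_classes),
                 block_widths = as.integer(block_widths),
                 n_blocks_per_scale = n_blocks_per_scale,
                 stem_width = as.integer(stem_width),
                 stem_pool = isTRUE(stem_pool), img = as.integer(img),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Training hyper-parameters
#'
#' Defaults follow the published DeepFlow training schedule: 30 epochs,
#' batch size 88, ADAM with cross-entropy loss, initial learning rate
#' 5e-3 dropping by a factor 0.9 every 5 epochs, L2 regularisation 1e-4,
#' ADAM epsilon 1e-8, per-epoch shuffling, and augmentation by random x/y
#' reflection, rotation, translation and 90-110% scaling.
#'
#' @param epochs,batch_size,lr0,lr_drop_factor,lr_drop_period,l2,epsilon
#'   optimisation schedule (see description).
#' @param shuffle_each_epoch logical.
#' @param augmentation list with `reflect_x`, `reflect_y` (logical),
#'   `rotation_deg`, `translation_px` (half-ranges), `scale_range`
#'   (length 2); `NULL` disables augmentation.
#' @param class_weights optional numeric vector of per-class loss weights
#'   (in label-encoding order), or `NULL` for unweighted training.
#' @param seed integer; seeds shuffling, augmentation draws and batching.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 88L, lr0 = 5e-3,
                         lr_drop_factor = 0.9, lr_drop_period = 5L,
                         l2 = 1e-4, epsilon = 1e-8,
                         shuffle_each_epoch = TRUE,
                         augmentation = list(reflect_x = TRUE, reflect_y = TRUE,
                                             rotation_deg = 15,
                                             translation_px = 4,
                                             scale_range = c(0.90, 1.10)),
                         class_weights = NULL, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0, lr_drop_factor > 0,
            lr_drop_period >= 1, l2 >= 0, epsilon > 0)
  if (!is.null(augmentation)) {
    stopifnot(all(augmentation$scale_range > 0),
              all(augmentation$scale_range < 2))
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period), l2 = l2,
                 epsilon = epsilon,
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 augmentation = augmentation, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' `lr0 * lr_drop_factor^floor((epoch - 1) / lr_drop_period)`: the rate is
#' held for `lr_drop_period` epochs, then multiplied by the drop factor.
#'
#' @param epoch integer epoch number, 1-based.
#' @param cfg a [train_config()].
#' @return learning rate for that epoch.
#' @export
lr_at_epoch <- function(epoch, cfg = train_config()) {
  if (any(epoch < 1)) stop("epoch must be >= 1")
  cfg$lr0 * cfg$lr_drop_factor^floor((epoch - 1) / cfg$lr_drop_period)
}

#' Draw augmentation parameters
#'
#' Draws one set of random transform parameters from the current RNG
#' stream (reflections Bernoulli(0.5) where enabled, rotation/translation
#' uniform on their half-ranges, scale uniform on `scale_range`).
#'
#' @param aug the `augmentation` list of a [train_config()].
#' @return list(flip_x, flip_y, angle, tx, ty, scale).
#' @export
draw_augment_params <- function(aug) {
  list(flip_x = isTRUE(aug$reflect_x) && runif(1) < 0.5,
       flip_y = isTRUE(aug$reflect_y) && runif(1) < 0.5,
       angle = runif(1, -aug$rotation_deg, aug$rotation_deg),
       tx = runif(1, -aug$translation_px, aug$translation_px),
       ty = runif(1, -aug$translation_px, aug$translation_px),
       scale = runif(1, aug$scale_range[1], aug$scale_range[2]))
}

#' Augment a standardised cell image
#'
#' Applies random x/y reflection, rotation, translation and scaling with
#' bilinear resampling and zero padding, per channel. The output has the
#' same 64x64x2 shape. With `params = NULL`, parameters are drawn from a
#' local RNG stream seeded by `seed`.
#'
#' @param image numeric array `img x img x channels`.
#' @param params transform parameters from [draw_augment_params()], or NULL.
#' @param aug augmentation ranges (see [train_config()]).
#' @param seed integer used when `params` is NULL.
#' @return augmented array of identical shape.
#' @export
augment <- function(image, params = NULL,
                    aug = train_config()$augmentation, seed = 1L) {
  stopifnot(length(dim(image)) == 3L)
  if (is.null(params)) {
    params <- withr_seed(seed, draw_augment_params(aug))
  }
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- cpp_affine_warp(image[, , ch], params$flip_x,
                                   params$flip_y, params$angle, params$tx,
                                   params$ty, params$scale)
  }
  out
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.df_unit_specs <- function(cfg) {
  units <- list(list(k = 3L, cin = cfg$in_channels, cout = cfg$stem_width))
  cin <- cfg$stem_width
  for (s in seq_along(cfg$block_widths)) {
    half <- cfg$block_widths[s] %/% 2L
    for (b in seq_len(cfg$n_blocks_per_scale[s])) {
      units <- c(units, list(list(k = 1L, cin = cin, cout = half),
                             list(k = 3L, cin = cin, cout = half)))
      cin <- 2L * half
    }
  }
  units
}

#' Build an untrained classifier
#'
#' Initialises all convolution and fully connected weights (He-normal,
#' seeded from `cfg$seed`), batch-norm scales/offsets and ADAM state. The
#' untrained network already produces valid softmax probability vectors.
#'
#' @param cfg a [network_config()].
#' @param label_encoding character vector of class labels in encoding
#'   order; length must equal `cfg$n_classes`.
#' @return object of class `deepflow_model`.
#' @export
build_network <- function(cfg = network_config(),
                          label_encoding = PHENOTYPE_CLASSES) {
  stopifnot(inherits(cfg, "network_config"),
            length(label_encoding) == cfg$n_classes)
  units <- .df_unit_specs(cfg)
  params <- list(); running <- list()
  withr_seed(cfg$seed, {
    for (u in units) {
      fan_in <- u$k^2 * u$cin
      W <- matrix(rnorm(u$cout * u$k^2 * u$cin, sd = sqrt(2 / fan_in)),
                  u$cout, u$k^2 * u$cin)
      params <- c(params, list(W, rep(1, u$cout), rep(0, u$cout)))
      running <- c(running, list(rep(0, u$cout), rep(1, u$cout)))
    }
    clast <- tail(cfg$block_widths, 1)
    params <- c(params,
                list(matrix(rnorm(cfg$n_classes * clast, sd = sqrt(2 / clast)),
                            cfg$n_classes, clast),
                     rep(0, cfg$n_classes)))
  })
  zeros <- lapply(params, function(p) if (is.matrix(p)) 0 * p else
                  matrix(0, length(p), 1))
  structure(list(config = cfg, params = params, running = running,
                 adam_m = zeros, adam_v = zeros, adam_t = 0L,
                 label_encoding = label_encoding, input_mean = c(0, 0),
                 history = NULL, train_config = NULL, trained = FALSE),
            class = "deepflow_model")
}

#' Number of trainable parameters
#' @param model a `deepflow_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

.records_to_matrix <- function(records) {
  if (is.array(records) && length(dim(records)) == 4L) {
    d <- dim(records)
    return(matrix(as.numeric(records), d[1] * d[2] * d[3], d[4]) / 65535)
  }
  if (is.list(records)) {
    imgs <- lapply(records, function(r) {
      img <- if (!is.null(r$image)) r$image else r
      stopifnot(length(dim(img)) == 3L)
      as.numeric(img) / 65535
    })
    return(matrix(unlist(imgs), ncol = length(imgs)))
  }
  stop("records must be a 4-d array (h, w, channel, n) or a list of cell records")
}

#' Inverse-frequency class weights
#'
#' Weight for class c is `n / (K * n_c)`, normalised so the mean weight over
#' observed classes is 1; unobserved classes get the maximum weight.
#'
#' @param labels training labels.
#' @param encoding label encoding order.
#' @return numeric vector of length `length(encoding)`.
#' @export
class_weights_inverse <- function(labels, encoding = PHENOTYPE_CLASSES) {
  tab <- table(factor(labels, levels = encoding))
  w <- ifelse(tab > 0, 1 / pmax(tab, 1), NA)
  w <- w / mean(w, na.rm = TRUE)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  as.numeric(w)
}

#' Train the classifier
#'
#' Runs mini-batch ADAM with weighted cross-entropy, the stepped learning
#' rate schedule of [lr_at_epoch()], per-epoch reshuffling, augmentation,
#' and per-batch zero-centring of the (0-1 scaled) input channels. All
#' stochastic draws come from `cfg$seed`, so two runs with equal seed and
#' data produce identical weights.
#'
#' @param model an (un)trained `deepflow_model`.
#' @param records 4-d image array (h, w, channel, n) or list of cell
#'   records with `$image` (raw 16-bit scale).
#' @param labels character labels, one per record.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the trained `deepflow_model` with `$history` filled in.
#' @export
train_network <- function(model, records, labels, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "deepflow_model"), inherits(cfg, "train_config"))
  X <- .records_to_matrix(records)
  n <- ncol(X)
  if (n == 0L) stop("empty training set")
  if (length(labels) != n) stop("labels/records length mismatch")
  enc <- model$label_encoding
  y <- match(as.character(labels), enc) - 1L
  if (anyNA(y)) stop("label outside the model's encoding: '",
                     as.character(labels)[which(is.na(y))[1]], "'")
  K <- model$config$n_classes
  cw <- if (is.null(cfg$class_weights)) rep(1, K) else cfg$class_weights
  stopifnot(length(cw) == K, all(cw > 0))

  img <- model$config$img; nch <- model$config$in_channels
  hw <- img * img
  ch_idx <- rep(seq_len(nch), each = hw)
  model$input_mean <- vapply(seq_len(nch),
                             function(c) mean(X[ch_idx == c, ]), numeric(1))

  acfg <- list(img = img, in_channels = nch, n_classes = K,
               stem_width = model$config$stem_width,
               stem_pool = model$config$stem_pool,
               block_widths = model$config$block_widths,
               n_blocks_per_scale = model$config$n_blocks_per_scale)

  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), lr = numeric(0))
  withr_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(epoch, cfg)
      perm <- if (cfg$shuffle_each_epoch || epoch == 1L) sample.int(n) else perm
      tot_loss <- 0; tot_correct <- 0L; nb <- 0L
      for (lo in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[lo:min(n, lo + cfg$batch_size - 1L)]
        xb <- X[, idx, drop = FALSE]
        if (!is.null(cfg$augmentation)) {
          for (j in seq_along(idx)) {
            pars <- draw_augment_params(cfg$augmentation)
            for (c in seq_len(nch)) {
              rows <- ((c - 1L) * hw + 1L):(c * hw)
              xb[rows, j] <- as.numeric(cpp_affine_warp(
                matrix(xb[rows, j], img, img), pars$flip_x, pars$flip_y,
                pars$angle, pars$tx, pars$ty, pars$scale))
            }
          }
        }
        for (c in seq_len(nch)) {   # zero-center per batch, per channel
          rows <- ((c - 1L) * hw + 1L):(c * hw)
          xb[rows, ] <- xb[rows, ] - mean(xb[rows, ])
        }
        model$adam_t <- model$adam_t + 1L
        st <- cpp_df_step(model$params, model$running, model$adam_m,
                          model$adam_v, xb, y[idx], cw, acfg, lr, cfg$l2,
                          0.9, 0.999, cfg$epsilon, model$adam_t)
        model$params <- st$params; model$running <- st$running
        model$adam_m <- st$m; model$adam_v <- st$v
        tot_loss <- tot_loss + st$loss; tot_correct <- tot_correct + st$correct
        nb <- nb + 1L
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = tot_loss / nb,
                                     accuracy = tot_correct / n, lr = lr))
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  acc %.3f  lr %.2e", epoch,
                        tot_loss / nb, tot_correct / n, lr))
    }
  })
  model$history <- hist
  model$train_config <- cfg
  model$trained <- TRUE
  model$running <- .finalize_bn_stats(model, X, acfg)
  model
}

# Recompute batch-norm population statistics under the final weights: one
# train-mode pass over the training set in large chunks (inputs centred the
# same way inference centres them), chunk moments pooled by the law of
# total variance. Removes the initialisation bias an exponential moving
# average retains after short trainings.
.finalize_bn_stats <- function(model, X, acfg, chunk = 512L) {
  img <- model$config$img; hw <- img * img
  for (c in seq_len(model$config$in_channels)) {
    rows <- ((c - 1L) * hw + 1L):(c * hw)
    X[rows, ] <- X[rows, ] - model$input_mean[c]
  }
  n <- ncol(X)
  starts <- seq(1L, n, by = chunk)
  stats <- list(); w <- numeric(0)
  for (lo in starts) {
    hi <- min(n, lo + chunk - 1L)
    st <- cpp_df_bn_stats(model$params, model$running,
                          X[, lo:hi, drop = FALSE], acfg)
    stats[[length(stats) + 1L]] <- st
    w <- c(w, hi - lo + 1L)
  }
  w <- w / sum(w)
  out <- model$running
  for (u in seq_len(length(out) %/% 2L)) {
    ms <- lapply(stats, function(s) as.numeric(s[[2L * u - 1L]]))
    vs <- lapply(stats, function(s) as.numeric(s[[2L * u]]))
    m_tot <- Reduce(`+`, Map(`*`, ms, w))
    v_within <- Reduce(`+`, Map(`*`, vs, w))
    v_between <- Reduce(`+`, Map(function(m, wi) wi * (m - m_tot)^2, ms, w))
    out[[2L * u - 1L]] <- matrix(m_tot, ncol = 1)
    out[[2L * u]] <- matrix(v_within + v_between, ncol = 1)
  }
  out
}

#' Classify cell images
#'
#' @param object a trained (or untrained) `deepflow_model`.
#' @param records image array or list of cell records as in
#'   [train_network()].
#' @param ... unused.
#' @return data.frame with `label` (argmax class) and `confidence` (max
#'   softmax probability); the full probability matrix (records x classes)
#'   is attached as attribute `"prob"`.
#' @export
predict.deepflow_model <- function(object, records, ...) {
  X <- .records_to_matrix(records)
  img <- object$config$img; hw <- img * img
  for (c in seq_len(object$config$in_channels)) {
    rows <- ((c - 1L) * hw + 1L):(c * hw)
    X[rows, ] <- X[rows, ] - object$input_mean[c]
  }
  acfg <- list(img = img, in_channels = object$config$in_channels,
               n_classes = object$config$n_classes,
               stem_width = object$config$stem_width,
               stem_pool = object$config$stem_pool,
               block_widths = object$config$block_widths,
               n_blocks_per_scale = object$config$n_blocks_per_scale)
  P <- t(cpp_df_predict(object$params, object$running, X, acfg))
  colnames(P) <- object$label_encoding
  lab <- object$label_encoding[max.col(P, ties.method = "first")]
  out <- data.frame(label = lab, confidence = apply(P, 1, max),
                    stringsAsFactors = FALSE)
  attr(out, "prob") <- P
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries weights, running batch-norm moments, both
#' configurations, the label encoding and training history (RDS format,
#' versioned).
#'
#' @param model a `deepflow_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deepflow_model"))
  obj <- unclass(model)
  obj$checkpoint_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$checkpoint_version))
    stop("not an mnflow model checkpoint: ", path)
  obj$checkpoint_version <- NULL
  structure(obj, class = "deepflow_model")
}

#' @export
print.deepflow_model <- function(x, ...) {
  cat(sprintf("<deepflow_model> %d classes, %d parameters, %s\n",
              x$config$n_classes, n_parameters(x),
              if (x$trained) sprintf("trained %d epochs",
                                     nrow(x$history)) else "untrained"))
  invisible(x)
}
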