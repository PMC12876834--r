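# Pixel-level segmentation of foamy podocytes and of the glomerulus with a
# small encoder-decoder ("small_unet": two pooling stages, skip connections,
# ~25k parameters), Dice/IoU evaluation under both global-pixel and
# per-tile-mean aggregation, and the tile-positivity screening rule.

SEG_ARCHITECTURES <- c("small_unet", "unet", "deeplabv3plus", "segformer_b4")

#' Segmenter training configuration
#'
#' @param architecture `"small_unet"` (trainable here); `"unet"`,
#'   `"deeplabv3plus"`, `"segformer_b4"` are recognized plug-in names not
#'   available in this build.
#' @param target `"podocyte"` (foamy-podocyte lesions) or `"glomerulus"`.
#' @param augment random flip/rotation/colour-jitter during training.
#' @param epochs,batch_size,learning_rate,seed as in [train_config()].
#' @param input_px working resolution: the 512 px tile and its mask are
#'   area-averaged / majority-downsampled to this side before the net; must
#'   be divisible by 4. Predictions are upsampled back when asked for.
#' @param channels widths of encoder blocks.
#' @param max_pos_weight cap on the inverse-frequency weight of positive
#'   pixels in the loss.
#' @return object of class `seg_train_config`.
#' @export
seg_train_config <- function(architecture = SEG_ARCHITECTURES,
                             target = c("podocyte", "glomerulus"),
                             augment = FALSE, epochs = 5L, batch_size = 8L,
                             learning_rate = 0.003, seed = 1L,
                             input_px = 128L, channels = c(8L, 16L, 32L),
                             max_pos_weight = 20) {
  architecture <- match.arg(architecture)
  target <- match.arg(target)
  if (epochs < 1) stop("epochs must be >= 1")
  if (input_px %% 4 != 0) stop("input_px must be divisible by 4")
  structure(list(architecture = architecture, target = target,
                 augment = isTRUE(augment), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 input_px = as.integer(input_px),
                 channels = as.integer(channels),
                 max_pos_weight = max_pos_weight),
            class = "seg_train_config")
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks give 1 by convention (a correct
#' rejection counts as perfect overlap).
#'
#' @param mask_a,mask_b logical or 0/1 matrices of the same shape.
#' @return Dice in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  a <- sum(mask_a != 0); b <- sum(mask_b != 0)
  if (a + b == 0) return(1)
  2 * sum(mask_a != 0 & mask_b != 0) / (a + b)
}

#' Intersection over union of two binary masks
#'
#' `|A n B| / |A u B|`; two empty masks give 1 by convention.
#'
#' @inheritParams dice
#' @return IoU in \[0, 1\].
#' @export
iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  u <- sum(mask_a != 0 | mask_b != 0)
  if (u == 0) return(1)
  sum(mask_a != 0 & mask_b != 0) / u
}

# Pooled and per-tile Dice/IoU for lists of predicted/reference masks.
seg_metrics <- function(pred, ref) {
  inter <- sum(mapply(function(p, r) sum(p != 0 & r != 0), pred, ref))
  szp <- sum(vapply(pred, function(p) sum(p != 0), numeric(1)))
  szr <- sum(vapply(ref, function(r) sum(r != 0), numeric(1)))
  uni <- szp + szr - inter
  global <- list(
    dice = if (szp + szr == 0) 1 else 2 * inter / (szp + szr),
    iou = if (uni == 0) 1 else inter / uni,
    n_tiles = length(pred), aggregation = "global_pixel")
  per_tile <- list(
    dice = mean(mapply(dice, pred, ref)),
    iou = mean(mapply(iou, pred, ref)),
    n_tiles = length(pred), aggregation = "per_tile_mean")
  list(global_pixel = structure(global, class = "seg_metrics"),
       per_tile_mean = structure(per_tile, class = "seg_metrics"))
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("Dice %.3f | IoU %.3f (%s, %d tiles)\n",
              x$dice, x$iou, x$aggregation, x$n_tiles))
  invisible(x)
}

seg_prepare <- function(tiles, cfg) {
  mask_name <- if (cfg$target == "podocyte") "podocyte" else "glomerulus"
  X <- lapply(tiles, function(tl)
    (shrink_tile(tl$pixels, cfg$input_px) - 0.5) * 2)
  M <- lapply(tiles, function(tl) {
    m <- tl$masks[[mask_name]]
    if (is.null(m)) stop("tiles carry no '", mask_name, "' mask")
    f <- nrow(m) / cfg$input_px
    if (f != round(f)) stop("input_px must divide the tile size")
    (block_mean(m * 1, as.integer(f)) >= 0.5) * 1
  })
  list(X = X, M = M)
}

fit_small_unet <- function(X, M, cfg) {
  ch <- cfg$channels
  npos <- sum(vapply(M, sum, numeric(1)))
  ntot <- sum(vapply(M, length, numeric(1)))
  wpos <- if (npos == 0) 1 else
    min(cfg$max_pos_weight, (ntot - npos) / npos)
  theta <- init_theta(unet_blocks(ch))
  loss_grad <- function(th, idx) {
    Xb <- X[idx]; Mb <- M[idx]
    if (cfg$augment) {
      for (i in seq_along(Xb)) {
        prm <- draw_augment_params()
        Xb[[i]] <- apply_augment(Xb[[i]], prm)
        Mb[[i]] <- apply_geom(Mb[[i]], prm)
      }
    }
    unet_loss_grad(th, Xb, Mb, wpos, ch[1], ch[2], ch[3])
  }
  adam_fit(loss_grad, theta, length(X), cfg$epochs, cfg$batch_size,
           cfg$learning_rate)
}

#' Train a segmenter with case-level cross-validation
#'
#' Same fold machinery as [train_classifier()]: per fold, trains on the other
#' folds and evaluates Dice/IoU on the held-out fold under both global-pixel
#' and per-tile-mean aggregation. Seed-reproducible on one CPU with
#' `small_unet`.
#'
#' @param tiles list of `tile` objects carrying `masks$podocyte` and/or
#'   `masks$glomerulus` ground truth.
#' @param folds a [make_case_folds()] split.
#' @param cfg a [seg_train_config()].
#' @return object of class `segmenter_cv`: per-fold `models`
#'   (`tile_segmenter`), `fold_metrics`, pooled out-of-fold `metrics`, and
#'   `oof_masks` (held-out predicted masks, at `cfg$input_px` resolution)
#'   with `oof_index` into `tiles`.
#' @export
train_segmenter <- function(tiles, folds, cfg = seg_train_config()) {
  if (cfg$architecture != "small_unet")
    stop("architecture '", cfg$architecture,
         "' is not available in this build; use 'small_unet'")
  tf <- tile_fold(tiles, folds)
  if (anyNA(tf)) stop("some tiles belong to cases absent from the fold split")
  prep <- seg_prepare(tiles, cfg)
  if (cfg$target == "podocyte" &&
      sum(vapply(prep$M, sum, numeric(1))) == 0)
    stop("all podocyte masks are empty; cannot train the lesion segmenter")
  ch <- cfg$channels
  models <- list()
  oof_masks <- vector("list", length(tiles))
  fold_metrics <- vector("list", folds$k)
  for (f in sort(unique(tf))) {
    tr <- which(tf != f); va <- which(tf == f)
    theta <- with_seed(derive_seed(cfg$seed, paste0("seg", f)),
                       fit_small_unet(prep$X[tr], prep$M[tr], cfg))
    model <- structure(list(theta = theta, cfg = cfg, fold = f),
                       class = "tile_segmenter")
    models[[as.character(f)]] <- model
    if (length(va) > 0) {
      pm <- unet_predict_cpp(theta, prep$X[va], ch[1], ch[2], ch[3])
      pm <- lapply(pm, function(p) p >= 0.5)
      for (j in seq_along(va)) oof_masks[[va[j]]] <- pm[[j]]
      fold_metrics[[f + 1]] <- seg_metrics(pm, prep$M[va])
    }
  }
  have <- !vapply(oof_masks, is.null, logical(1))
  pooled <- seg_metrics(oof_masks[have], prep$M[have])
  structure(list(models = models, fold_metrics = fold_metrics,
                 metrics = pooled, oof_masks = oof_masks,
                 oof_index = which(have), cfg = cfg, folds = folds),
            class = "segmenter_cv")
}

#' Predict a binary mask for one tile
#'
#' Per-pixel probabilities thresholded at `threshold`; deterministic, and
#' masks are nested in the threshold (higher threshold, smaller mask).
#'
#' @param model a `tile_segmenter`.
#' @param tile a `tile` object (or bare H x W x 3 array) at the training
#'   spacing.
#' @param threshold probability cutoff in (0, 1).
#' @param out_px side of the returned mask; defaults to the model working
#'   resolution, pass 512 to get tile-resolution masks (nearest-neighbour
#'   upsampling).
#' @return logical mask.
#' @export
predict_mask <- function(model, tile, threshold = 0.5, out_px = NULL) {
  stopifnot(inherits(model, "tile_segmenter"))
  px <- if (inherits(tile, "tile")) tile$pixels else tile
  X <- (shrink_tile(px, model$cfg$input_px) - 0.5) * 2
  ch <- model$cfg$channels
  p <- unet_predict_cpp(model$theta, list(X), ch[1], ch[2], ch[3])[[1]]
  m <- p >= threshold
  if (!is.null(out_px) && out_px != nrow(m))
    m <- resize_nearest(m, out_px, out_px)
  m
}

#' Tile positivity from a segmentation mask
#'
#' A tile is screened positive when at least one pixel is predicted as
#' vacuolized podocyte.
#'
#' @param podocyte_mask logical or 0/1 mask.
#' @return TRUE iff the mask has any foreground pixel.
#' @export
tile_positive <- function(podocyte_mask) {
  sum(podocyte_mask != 0) > 0
}

#' Screening sensitivity and PPV from tile positivity
#'
#' @param tile_positives logical vector of predicted tile positivity.
#' @param tile_labels logical vector of true tile positivity (or
#'   `"foamy"`/`"not_foamy"` characters).
#' @return list with `sensitivity` (`NA` when no positive labels) and `ppv`
#'   (`NA` when no positive predictions).
#' @export
seg_screen_metrics <- function(tile_positives, tile_labels) {
  if (is.character(tile_labels)) tile_labels <- tile_labels == "foamy"
  if (length(tile_positives) != length(tile_labels))
    stop("prediction and label vectors differ in length")
  tp <- sum(tile_positives & tile_labels)
  fn <- sum(!tile_positives & tile_labels)
  fp <- sum(tile_positives & !tile_labels)
  list(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}
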