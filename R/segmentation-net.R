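#' Configuration of the trinary segmentation network
#'
#' An encoder-decoder (U-Net style) with three modifications: residual
#' blocks with the given filter counts instead of plain convolutional
#' blocks; spatial downsampling capped at one eighth of the input (pooling
#' after the first three encoder stages only); and an atrous spatial pyramid
#' pooling block with the given dilation rates as the last encoder layer.
#' Activations are leaky rectifiers.
#'
#' @param encoder_filters five filter counts, default `c(32, 64, 128, 256,
#'   256)`.
#' @param aspp_rates dilation rates of the pyramid, default `c(6, 12, 18,
#'   24)`.
#' @param n_classes output classes (background, nucleus, mitochondria).
#' @param leaky_slope negative slope of the leaky rectifier.
#' @param input_size nominal training resolution (images are resized to
#'   768 x 768 in the full-scale recipe); any side divisible by 8 is
#'   accepted at run time.
#' @return object of class `net_config`.
#' @export
net_config <- function(encoder_filters = c(32, 64, 128, 256, 256),
                       aspp_rates = c(6, 12, 18, 24),
                       n_classes = 3, leaky_slope = 0.01, input_size = 768) {
  if (length(encoder_filters) != 5 || any(encoder_filters < 1))
    stop("encoder_filters must be 5 positive counts")
  if (n_classes < 2) stop("need at least 2 classes")
  structure(list(encoder_filters = as.integer(encoder_filters),
                 aspp_rates = as.integer(aspp_rates),
                 n_classes = as.integer(n_classes),
                 leaky_slope = leaky_slope,
                 max_downsampling_factor = 8L,
                 input_size = as.integer(input_size)),
            class = "net_config")
}

# weight shapes for every convolution, in a fixed named order
.unet_weight_shapes <- function(config) {
  f <- config$encoder_filters
  cin <- c(1L, f[1:4])
  sh <- list()
  for (i in 1:5) {
    sh[[paste0("enc", i, "_a_w")]] <- c(3, 3, cin[i], f[i])
    sh[[paste0("enc", i, "_a_b")]] <- f[i]
    sh[[paste0("enc", i, "_b_w")]] <- c(3, 3, f[i], f[i])
    sh[[paste0("enc", i, "_b_b")]] <- f[i]
    sh[[paste0("enc", i, "_s_w")]] <- c(1, 1, cin[i], f[i])
    sh[[paste0("enc", i, "_s_b")]] <- f[i]
  }
  for (k in seq_along(config$aspp_rates)) {
    sh[[paste0("aspp", k, "_w")]] <- c(3, 3, f[5], f[5])
    sh[[paste0("aspp", k, "_b")]] <- f[5]
  }
  dcin <- c(f[5] + f[3], f[3] + f[2], f[2] + f[1])
  dout <- c(f[3], f[2], f[1])
  for (j in 1:3) {
    sh[[paste0("dec", j, "_c1_w")]] <- c(3, 3, dcin[j], dout[j])
    sh[[paste0("dec", j, "_c1_b")]] <- dout[j]
    sh[[paste0("dec", j, "_c2_w")]] <- c(3, 3, dout[j], dout[j])
    sh[[paste0("dec", j, "_c2_b")]] <- dout[j]
  }
  sh[["out_w"]] <- c(1, 1, f[1], config$n_classes)
  sh[["out_b"]] <- config$n_classes
  sh
}

#' Build the segmentation model with randomly initialized weights
#'
#' Weights use fan-in scaled uniform initialization
#' (`U(-1, 1) / sqrt(kh * kw * cin)`), biases start at zero; everything is
#' seed-controlled.
#'
#' @param config a [net_config()].
#' @param seed RNG seed for the initialization.
#' @return object of class `mito_unet` (config + named weight list).
#' @export
build_model <- function(config = net_config(), seed = 1) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  shapes <- .unet_weight_shapes(config)
  weights <- lapply(names(shapes), function(nm) {
    s <- shapes[[nm]]
    if (length(s) == 1) return(numeric(s))           # bias
    lim <- 1 / sqrt(prod(s[1:3]))
    array(runif(prod(s), -lim, lim), s)
  })
  names(weights) <- names(shapes)
  structure(list(config = config, weights = weights), class = "mito_unet")
}

#' @export
print.mito_unet <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<mito_unet> filters %s, ASPP rates %s, %d classes, %s parameters\n",
              paste(x$config$encoder_filters, collapse = "/"),
              paste(x$config$aspp_rates, collapse = "/"),
              x$config$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

.check_side <- function(image) {
  d <- dim(image)
  if (any(d %% 8 != 0))
    stop(sprintf("input sides (%d x %d) must be divisible by 8", d[1], d[2]))
  invisible(d)
}

#' Raw forward pass: per-pixel class logits and feature-map shapes
#'
#' @param model a `mito_unet`.
#' @param image numeric matrix (H x W), sides divisible by 8.
#' @return list with `logits` (H x W x n_classes) and `feature_dims`
#'   (matrix of encoder/ASPP/logit spatial shapes; the smallest encoder map
#'   has side = input side / 8).
#' @export
model_logits <- function(model, image) {
  stopifnot(inherits(model, "mito_unet"), is.matrix(image))
  .check_side(image)
  unet_forward_cpp(model$weights, image, model$config$aspp_rates,
                   model$config$leaky_slope)
}

#' Predict a per-pixel class map
#'
#' Argmax over the class logits; exact ties resolve to the lowest class
#' index.  A stack (3D array, slices along the first dimension) is predicted
#' slice by slice, independently, order preserved.
#'
#' @param model a `mito_unet`.
#' @param image matrix or `(n, H, W)` array of slices.
#' @return integer matrix (or `(n, H, W)` array) of labels in
#'   `0 .. n_classes - 1`.
#' @export
predict_mask <- function(model, image) {
  if (is.array(image) && length(dim(image)) == 3) {
    out <- array(0L, dim(image))
    for (i in seq_len(dim(image)[1]))
      out[i, , ] <- predict_mask(model, image[i, , ])
    return(out)
  }
  lg <- model_logits(model, image)$logits
  lab <- matrix(0L, dim(lg)[1], dim(lg)[2])
  best <- lg[, , 1]
  for (k in seq_len(dim(lg)[3] - 1)) {
    better <- lg[, , k + 1] > best          # strict: ties keep lower class
    lab[better] <- k
    best[better] <- lg[, , k + 1][better]
  }
  lab
}

#' Training configuration
#'
#' The full-scale recipe: Adam (`beta1 = 0.9`, `beta2 = 0.999`), initial
#' learning rate 1e-4 dropped to 1e-5 after epoch 150, 200 epochs total,
#' batch size 8, per-pixel cross-entropy, and augmentations (horizontal /
#' vertical flips, rotations in [-20, 20] degrees, zero-mean Gaussian noise
#' with sd 0.08, random crops down to 90% of height/width) each applied
#' independently with probability 0.5.  Scale the epoch counts and sizes
#' down for desk-scale experiments.
#'
#' @param epochs,batch_size,lr_initial,lr_after,lr_step_epoch schedule.
#' @param beta1,beta2,epsilon Adam moments.
#' @param augment enable the augmentation set.
#' @param aug_prob per-augmentation application probability.
#' @param rotation_range degrees.
#' @param noise_sd augmentation noise sd.
#' @param crop_min_frac smallest crop fraction of height/width.
#' @param shuffle reshuffle sample order each epoch.
#' @param seed RNG seed controlling init-independent training randomness.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 8,
                         lr_initial = 1e-4, lr_after = 1e-5, lr_step_epoch = 150,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         augment = TRUE, aug_prob = 0.5,
                         rotation_range = c(-20, 20), noise_sd = 0.08,
                         crop_min_frac = 0.9, shuffle = TRUE, seed = 1) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_after = lr_after,
                 lr_step_epoch = as.integer(lr_step_epoch),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 augment = augment, aug_prob = aug_prob,
                 rotation_range = rotation_range, noise_sd = noise_sd,
                 crop_min_frac = crop_min_frac, shuffle = shuffle,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule of a training configuration
#' @param config a [train_config()].
#' @return numeric vector, one learning rate per epoch.
#' @export
lr_schedule <- function(config) {
  ep <- seq_len(config$epochs)
  ifelse(ep <= config$lr_step_epoch, config$lr_initial, config$lr_after)
}

# ---- augmentations ---------------------------------------------------------

# sample source coordinates for output pixel grid under a transform record
.transform_coords <- function(h, w, tr) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (!is.null(tr$crop)) {
    yy <- tr$crop$y0 + (yy - 0.5) * tr$crop$ch / h + 0.5 - 1
    xx <- tr$crop$x0 + (xx - 0.5) * tr$crop$cw / w + 0.5 - 1
  }
  if (!is.null(tr$angle)) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    th <- -tr$angle * pi / 180
    y0 <- yy - cy; x0 <- xx - cx
    yy <- cy + (sin(th) * x0 + cos(th) * y0)
    xx <- cx + (cos(th) * x0 - sin(th) * y0)
  }
  if (isTRUE(tr$hflip)) xx <- w + 1 - xx
  if (isTRUE(tr$vflip)) yy <- h + 1 - yy
  list(yy = yy, xx = xx)
}

.map_bilinear <- function(img, yy, xx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(yy); x0 <- floor(xx)
  wy <- yy - y0; wx <- xx - x0
  get <- function(y, x) {
    ok <- y >= 1 & y <= h & x >= 1 & x <= w
    v <- matrix(fill, nrow(yy), ncol(yy))
    v[ok] <- img[cbind(y[ok], x[ok])]
    v
  }
  get(y0, x0) * (1 - wy) * (1 - wx) + get(y0 + 1, x0) * wy * (1 - wx) +
    get(y0, x0 + 1) * (1 - wy) * wx + get(y0 + 1, x0 + 1) * wy * wx
}

.map_nearest <- function(img, yy, xx, fill = 0L) {
  h <- nrow(img); w <- ncol(img)
  y <- round(yy); x <- round(xx)
  ok <- y >= 1 & y <= h & x >= 1 & x <= w
  v <- matrix(fill, nrow(yy), ncol(yy))
  v[ok] <- img[cbind(y[ok], x[ok])]
  v
}

#' Apply the stored geometric transform of an augmentation to a label map
#'
#' Nearest-neighbour resampling under the identical geometric transform that
#' was applied to the image, so augmented labels stay aligned with augmented
#' images.
#'
#' @param label integer label matrix.
#' @param transform the `transform` element returned by [augment_pair()].
#' @return transformed label matrix.
#' @export
apply_geometric_transform <- function(label, transform) {
  co <- .transform_coords(nrow(label), ncol(label), transform)
  .map_nearest(label, co$yy, co$xx, fill = 0L)
}

#' Randomly augment an image/label pair
#'
#' Each augmentation (horizontal flip, vertical flip, rotation, additive
#' Gaussian noise, random crop-and-resize) is applied independently with
#' probability `config$aug_prob`.  Geometric transforms use bilinear
#' resampling for the image and nearest-neighbour for the label; the noise
#' touches only the image.
#'
#' @param image numeric matrix.
#' @param label integer matrix, same shape.
#' @param config a [train_config()].
#' @return list with `image`, `label` and the `transform` record.
#' @export
augment_pair <- function(image, label, config = train_config()) {
  h <- nrow(image); w <- ncol(image)
  tr <- list()
  if (runif(1) < config$aug_prob) tr$hflip <- TRUE
  if (runif(1) < config$aug_prob) tr$vflip <- TRUE
  if (runif(1) < config$aug_prob)
    tr$angle <- runif(1, config$rotation_range[1], config$rotation_range[2])
  if (runif(1) < config$aug_prob) {
    f <- runif(1, config$crop_min_frac, 1)
    ch <- max(8, floor(h * f)); cw <- max(8, floor(w * f))
    tr$crop <- list(ch = ch, cw = cw,
                    y0 = sample.int(h - ch + 1, 1), x0 = sample.int(w - cw + 1, 1))
  }
  co <- .transform_coords(h, w, tr)
  img <- .map_bilinear(image, co$yy, co$xx, fill = stats::median(image))
  lab <- .map_nearest(label, co$yy, co$xx, fill = 0L)
  if (runif(1) < config$aug_prob) {
    tr$noise_sd <- config$noise_sd
    img <- img + rnorm(length(img), 0, config$noise_sd)
  }
  list(image = img, label = lab, transform = tr)
}

# ---- training --------------------------------------------------------------

#' Train the segmentation model
#'
#' Per-pixel cross-entropy over the classes, Adam updates, step learning-rate
#' schedule, optional augmentation.  Deterministic for a fixed seed.
#'
#' @param model a `mito_unet` from [build_model()].
#' @param images list of numeric matrices (or `(n, H, W)` array).
#' @param labels list of integer matrices with values in
#'   `0 .. n_classes - 1`, same shapes as `images`.
#' @param config a [train_config()].
#' @return list with `model` (trained) and `history` (data.frame of epoch,
#'   mean loss, learning rate).  `epochs = 0` returns the model unchanged
#'   with an empty history.
#' @export
train_model <- function(model, images, labels, config = train_config()) {
  stopifnot(inherits(model, "mito_unet"), inherits(config, "train_config"))
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[1]), function(i) images[i, , ])
  if (is.array(labels) && length(dim(labels)) == 3)
    labels <- lapply(seq_len(dim(labels)[1]), function(i) labels[i, , ])
  if (length(images) == 0) stop("empty dataset")
  if (length(images) != length(labels)) stop("images and labels differ in length")
  K <- model$config$n_classes
  for (i in seq_along(labels)) {
    if (!identical(dim(images[[i]]), dim(labels[[i]]))) stop("image/label shape mismatch")
    if (any(labels[[i]] < 0 | labels[[i]] >= K))
      stop(sprintf("label outside 0..%d in sample %d", K - 1, i))
    .check_side(images[[i]])
  }
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  if (config$epochs == 0) return(list(model = model, history = hist))

  set.seed(config$seed)
  wts <- model$weights
  mom <- lapply(wts, function(w) array(0, dim(w) %||% length(w)))
  vel <- lapply(wts, function(w) array(0, dim(w) %||% length(w)))
  tstep <- 0
  lrs <- lr_schedule(config)
  n <- length(images)
  for (ep in seq_len(config$epochs)) {
    lr <- lrs[ep]
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    nb <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      gacc <- NULL
      bloss <- 0
      for (i in idx) {
        img <- images[[i]]; lab <- labels[[i]]
        if (config$augment) {
          au <- augment_pair(img, lab, config)
          img <- au$image; lab <- au$label
        }
        res <- unet_loss_grad_cpp(wts, img, lab, model$config$aspp_rates,
                                  model$config$leaky_slope)
        bloss <- bloss + res$loss
        if (is.null(gacc)) {
          gacc <- res$grads
        } else {
          for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] + res$grads[[nm]]
        }
      }
      m <- length(idx)
      tstep <- tstep + 1
      for (nm in names(wts)) {
        g <- gacc[[nm]] / m
        mom[[nm]] <- config$beta1 * mom[[nm]] + (1 - config$beta1) * g
        vel[[nm]] <- config$beta2 * vel[[nm]] + (1 - config$beta2) * g^2
        mhat <- mom[[nm]] / (1 - config$beta1^tstep)
        vhat <- vel[[nm]] / (1 - config$beta2^tstep)
        wts[[nm]] <- wts[[nm]] - lr * mhat / (sqrt(vhat) + config$epsilon)
      }
      ep_loss <- ep_loss + bloss / m
      nb <- nb + 1
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb, lr = lr))
  }
  model$weights <- wts
  list(model = model, history = hist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
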