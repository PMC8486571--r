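# The convolutional classifier, implemented from scratch in vectorized R:
# two unpadded 3x3 convolutions (4 filters each, tanh), flatten, four dense
# relu layers with two dropout layers, and a single sigmoid output unit.
# Training uses weighted binary cross-entropy, adadelta, and per-epoch
# shuffling from a seeded stream, so runs are exactly reproducible.
#
# Feature maps are stored as n x (h*w*c) matrices with column layout
# (channel-major, then column-major within channel); convolutions are
# computed by im2col patch extraction followed by a single matrix product.

#' Frequency-proportional class weights
#'
#' Each class receives weight `N / (2 * n_c)` so that a balanced dataset
#' yields weight 1 for both classes; the positive-class weight is then
#' multiplied by `positive_class_scale` (1.06 reproduces the ovarian-cancer
#' setting that nudges sensitivity upward).
#'
#' @param labels Binary 0/1 vector (1 = positive/case).
#' @param positive_class_scale Positive multiplier for the case weight.
#' @return Named vector `c(weight_neg, weight_pos)`.
#' @export
class_weights <- function(labels, positive_class_scale = 1) {
  if (!is.numeric(positive_class_scale) || positive_class_scale <= 0) {
    stopf("positive_class_scale must be > 0")
  }
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  n <- n_pos + n_neg
  c(weight_neg = n / (2 * n_neg),
    weight_pos = n / (2 * n_pos) * positive_class_scale)
}

#' Network architecture specification
#'
#' Defaults encode the published architecture: 10 layers of which 8 are
#' hidden — two 2-D convolutional layers with four 3x3 filters and tanh
#' activation, four dense relu layers with strictly decreasing widths, and
#' two dropout layers after the first and second dense layers — plus the
#' flatten layer and a single sigmoid output unit.
#'
#' @param conv_filters Filters per convolutional layer.
#' @param kernel Kernel side length (square kernels, unpadded).
#' @param dense_units Widths of the four dense hidden layers, strictly
#'   decreasing.
#' @param dropout_rates Dropout rates after dense layers 1 and 2.
#' @param seed Seed for weight initialization.
#' @return A `network_spec`.
#' @export
network_spec <- function(conv_filters = 4, kernel = 3,
                         dense_units = c(256, 64, 16, 4),
                         dropout_rates = c(0.25, 0.25), seed = 42) {
  if (length(dense_units) != 4 || any(diff(dense_units) >= 0)) {
    stopf("dense_units must be 4 strictly decreasing widths")
  }
  if (length(dropout_rates) != 2 || any(dropout_rates < 0 | dropout_rates >= 1)) {
    stopf("dropout_rates must be 2 rates in [0, 1)")
  }
  spec <- list(conv_filters = as.integer(conv_filters),
               kernel = as.integer(kernel),
               dense_units = as.integer(dense_units),
               dropout_rates = as.numeric(dropout_rates),
               seed = as.integer(seed))
  class(spec) <- "network_spec"
  spec
}

#' Training configuration
#'
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate,rho,epsilon Adadelta hyperparameters.
#' @param positive_class_scale Extra multiplier on the positive-class
#'   weight (see [class_weights()]).
#' @param shuffle_each_epoch Reshuffle training order before every epoch.
#' @param seed Seed for the training stream (shuffling and dropout).
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, learning_rate = 1.0,
                         rho = 0.95, epsilon = 1e-7,
                         positive_class_scale = 1.0,
                         shuffle_each_epoch = TRUE, seed = 42) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (positive_class_scale <= 0) stopf("positive_class_scale must be > 0")
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, rho = rho, epsilon = epsilon,
              positive_class_scale = positive_class_scale,
              shuffle_each_epoch = isTRUE(shuffle_each_epoch),
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

# im2col index table: maps each (output position, kernel offset, channel)
# to a column of the n x (h*w*c) feature-map matrix.
im2col_index <- function(h, w, c_in, k) {
  ho <- h - k + 1; wo <- w - k + 1
  y <- rep(seq_len(ho), times = wo)
  x <- rep(seq_len(wo), each = ho)          # position l = (x-1)*ho + y
  idx <- matrix(0L, nrow = ho * wo, ncol = k * k * c_in)
  col <- 0L
  for (ch in seq_len(c_in)) {
    for (dx in 0:(k - 1)) {
      for (dy in 0:(k - 1)) {
        col <- col + 1L
        idx[, col] <- (ch - 1L) * h * w + (x + dx - 1L) * h + (y + dy)
      }
    }
  }
  list(idx = as.vector(idx), L = ho * wo, K = k * k * c_in, ho = ho, wo = wo)
}

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' Build the convolutional classifier
#'
#' Assembles the layer stack
#' conv(tanh) -> conv(tanh) -> flatten -> dense(relu) -> dropout ->
#' dense(relu) -> dropout -> dense(relu) -> dense(relu) -> dense(1, sigmoid)
#' for a given input size, with Glorot-uniform weights drawn from the
#' spec's seed (two builds with the same seed are weight-identical).
#'
#' @param input_height,input_width Image dimensions in pixels.
#' @param spec A [network_spec()].
#' @return A `cnn_model` handle; `print()` reports the parameter count.
#' @export
build_network <- function(input_height, input_width, spec = network_spec()) {
  k <- spec$kernel
  min_side <- 2 * (k - 1) + 1
  if (input_height < min_side || input_width < min_side) {
    stopf("input %d x %d too small: two unpadded %dx%d convolutions need at least %d x %d",
          input_height, input_width, k, k, min_side, min_side)
  }
  f <- spec$conv_filters
  ix1 <- im2col_index(input_height, input_width, 1L, k)
  ix2 <- im2col_index(ix1$ho, ix1$wo, f, k)
  flat <- ix2$L * f
  widths <- c(flat, spec$dense_units, 1L)

  layers <- with_seed(spec$seed, {
    # fan counts for conv layers: receptive field x channels
    conv1 <- list(W = glorot_uniform(k * k * 1, k * k * f, ix1$K, f),
                  b = numeric(f))
    conv2 <- list(W = glorot_uniform(k * k * f, k * k * f, ix2$K, f),
                  b = numeric(f))
    dense <- lapply(seq_len(length(widths) - 1), function(i) {
      list(W = glorot_uniform(widths[i], widths[i + 1], widths[i], widths[i + 1]),
           b = numeric(widths[i + 1]))
    })
    list(conv1 = conv1, conv2 = conv2, dense = dense)
  })

  n_params <- sum(vapply(c(layers$dense,
                           list(layers$conv1, layers$conv2)),
                         function(l) length(l$W) + length(l$b), 0))
  model <- list(spec = spec, input_height = as.integer(input_height),
                input_width = as.integer(input_width),
                ix1 = ix1, ix2 = ix2, flat = flat,
                layers = layers, n_params = n_params,
                trained = FALSE, history = NULL)
  class(model) <- "cnn_model"
  pl_log("DEBUG", sprintf("build_network: %d x %d input, %d parameters",
                          input_height, input_width, n_params))
  model
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "cnn_model: %d x %d input | conv(%d,tanh) x2 -> flatten(%d) -> dense(%s,relu)+2 dropout -> sigmoid | %d parameters%s\n",
    x$input_height, x$input_width, x$spec$conv_filters, x$flat,
    paste(x$spec$dense_units, collapse = ","), x$n_params,
    if (x$trained) " (trained)" else ""))
  invisible(x)
}

# images: N x H x W array -> n x (H*W) matrix; array memory order already
# gives the channel layout used by im2col_index (column j = (x-1)*H + y)
flatten_images <- function(images) {
  matrix(images, nrow = dim(images)[1])
}

conv_forward <- function(Xm, ix, W, b) {
  n <- nrow(Xm)
  Am <- matrix(Xm[, ix$idx], n * ix$L, ix$K)
  Z <- Am %*% W
  Z <- sweep(Z, 2, b, "+")
  A <- tanh(Z)
  list(Am = Am, A = A, map = matrix(A, n, ix$L * ncol(W)))
}

# forward pass; when train = TRUE, dropout masks are drawn from the current
# RNG stream and intermediate activations cached for backprop
cnn_forward <- function(model, Xm, train = FALSE) {
  ly <- model$layers
  n <- nrow(Xm)
  c1 <- conv_forward(Xm, model$ix1, ly$conv1$W, ly$conv1$b)
  c2 <- conv_forward(c1$map, model$ix2, ly$conv2$W, ly$conv2$b)
  A <- c2$map                                   # n x flat
  caches <- list(c1 = c1, c2 = c2, dense = list())
  rates <- c(model$spec$dropout_rates, 0, 0, 0)  # dropout after dense 1 and 2 only
  nd <- length(ly$dense)
  for (i in seq_len(nd)) {
    Zpre <- sweep(A %*% ly$dense[[i]]$W, 2, ly$dense[[i]]$b, "+")
    if (i < nd) {
      Act <- pmax(Zpre, 0)
      mask <- NULL
      if (train && i <= 2 && rates[i] > 0) {
        mask <- matrix((stats::runif(length(Act)) >= rates[i]) / (1 - rates[i]),
                       nrow(Act), ncol(Act))
        Act <- Act * mask
      }
      caches$dense[[i]] <- list(A_in = A, Zpre = Zpre, mask = mask)
      A <- Act
    } else {
      caches$dense[[i]] <- list(A_in = A, Zpre = Zpre, mask = NULL)
      A <- 1 / (1 + exp(-Zpre))
    }
  }
  list(p = as.numeric(A), caches = caches)
}

weighted_bce <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(w * -(y * log(p) + (1 - y) * log(1 - p)))
}

cnn_backward <- function(model, Xm, fwd, y, w) {
  ly <- model$layers
  n <- nrow(Xm)
  nd <- length(ly$dense)
  grads <- list(dense = vector("list", nd))
  p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
  dZ <- matrix(w * (p - y) / n, ncol = 1)       # d(mean weighted BCE)/d logit
  for (i in rev(seq_len(nd))) {
    cache <- fwd$caches$dense[[i]]
    grads$dense[[i]] <- list(dW = crossprod(cache$A_in, dZ), db = colSums(dZ))
    if (i > 1) {
      dA <- dZ %*% t(ly$dense[[i]]$W)
      prev <- fwd$caches$dense[[i - 1]]
      if (!is.null(prev$mask)) dA <- dA * prev$mask
      dZ <- dA * (prev$Zpre > 0)
    }
  }
  dFlat <- dZ %*% t(ly$dense[[1]]$W)            # n x flat, grad wrt conv2 map

  # conv2
  ix2 <- model$ix2; f <- model$spec$conv_filters
  dMap2 <- matrix(array(dFlat, c(n, ix2$L, f)), n * ix2$L, f)
  dZ2 <- dMap2 * (1 - fwd$caches$c2$A^2)
  grads$conv2 <- list(dW = crossprod(fwd$caches$c2$Am, dZ2), db = colSums(dZ2))
  dAm2 <- dZ2 %*% t(ly$conv2$W)                 # (n*L2) x K2
  dCols <- matrix(dAm2, n, ix2$L * ix2$K)
  dMap1 <- t(rowsum(t(dCols), group = model$ix2$idx))  # n x (h1*w1*f)

  # conv1 (input gradient not needed)
  ix1 <- model$ix1
  dM1 <- matrix(array(dMap1, c(n, ix1$L, f)), n * ix1$L, f)
  dZ1 <- dM1 * (1 - fwd$caches$c1$A^2)
  grads$conv1 <- list(dW = crossprod(fwd$caches$c1$Am, dZ1), db = colSums(dZ1))
  grads
}

adadelta_init <- function(layer) {
  lapply(layer, function(x) list(Eg = x * 0, Ed = x * 0))
}

adadelta_step <- function(param, grad, state, lr, rho, eps) {
  state$Eg <- rho * state$Eg + (1 - rho) * grad^2
  delta <- -sqrt(state$Ed + eps) / sqrt(state$Eg + eps) * grad
  state$Ed <- rho * state$Ed + (1 - rho) * delta^2
  list(param = param + lr * delta, state = state)
}

#' Train the classifier
#'
#' Minimizes class-weighted binary cross-entropy with adadelta. The
#' training order is reshuffled before each epoch from the config's seeded
#' stream; dropout masks come from the same stream, so a fixed seed yields
#' an identical training trajectory. The per-epoch history records the
#' training loss (and validation loss when a validation set is supplied).
#'
#' @param model A `cnn_model` from [build_network()].
#' @param images N x H x W array (or an `image_set`).
#' @param labels Binary 0/1 vector of length N.
#' @param weights Class weights from [class_weights()] (recomputed from
#'   `labels` and the config's scale when omitted).
#' @param cfg A [train_config()].
#' @param validation Optional list with `images` and `labels` used only to
#'   monitor `val_loss`.
#' @return The trained `cnn_model`, with `$history` (data.frame of epoch,
#'   loss, val_loss).
#' @export
train_network <- function(model, images, labels, weights = NULL,
                          cfg = train_config(), validation = NULL) {
  if (inherits(images, "image_set")) images <- images$images
  labels <- as.numeric(labels)
  n <- dim(images)[1]
  if (length(labels) != n) stopf("labels length must match image count")
  if (length(unique(labels)) < 2) stopf("need at least one sample per class")
  if (is.null(weights)) weights <- class_weights(labels, cfg$positive_class_scale)
  w <- ifelse(labels == 1, weights[["weight_pos"]], weights[["weight_neg"]])
  Xm <- flatten_images(images)
  Vm <- NULL
  if (!is.null(validation)) {
    vim <- if (inherits(validation$images, "image_set")) validation$images$images
           else validation$images
    Vm <- flatten_images(vim)
    vy <- as.numeric(validation$labels)
    vw <- ifelse(vy == 1, weights[["weight_pos"]], weights[["weight_neg"]])
  }

  states <- list(conv1 = adadelta_init(model$layers$conv1),
                 conv2 = adadelta_init(model$layers$conv2),
                 dense = lapply(model$layers$dense, adadelta_init))
  hist_loss <- numeric(cfg$epochs)
  hist_val <- rep(NA_real_, cfg$epochs)

  upd <- function(layer, grad, st) {
    rW <- adadelta_step(layer$W, grad$dW, st$W, cfg$learning_rate, cfg$rho, cfg$epsilon)
    rb <- adadelta_step(layer$b, as.numeric(grad$db), st$b,
                        cfg$learning_rate, cfg$rho, cfg$epsilon)
    list(layer = list(W = rW$param, b = rb$param),
         state = list(W = rW$state, b = rb$state))
  }

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle_each_epoch) sample.int(n) else seq_len(n)
      batch_starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        sel <- ord[bs:min(bs + cfg$batch_size - 1, n)]
        Xb <- Xm[sel, , drop = FALSE]
        fwd <- cnn_forward(model, Xb, train = TRUE)
        loss <- weighted_bce(fwd$p, labels[sel], w[sel])
        if (!is.finite(loss)) {
          stopf("non-finite training loss at epoch %d (batch starting %d); %s",
                epoch, bs, "check input scaling and learning-rate settings")
        }
        ep_loss <- ep_loss + loss * length(sel)
        grads <- cnn_backward(model, Xb, fwd, labels[sel], w[sel])
        r <- upd(model$layers$conv1, grads$conv1, states$conv1)
        model$layers$conv1 <- r$layer; states$conv1 <- r$state
        r <- upd(model$layers$conv2, grads$conv2, states$conv2)
        model$layers$conv2 <- r$layer; states$conv2 <- r$state
        for (i in seq_along(model$layers$dense)) {
          r <- upd(model$layers$dense[[i]], grads$dense[[i]], states$dense[[i]])
          model$layers$dense[[i]] <- r$layer; states$dense[[i]] <- r$state
        }
      }
      hist_loss[epoch] <- ep_loss / n
      if (!is.null(Vm)) {
        vp <- cnn_forward(model, Vm, train = FALSE)$p
        hist_val[epoch] <- weighted_bce(vp, vy, vw)
      }
    }
  })
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss,
                              val_loss = hist_val)
  model$train_config <- cfg
  model$class_weights <- weights
  model
}

#' Predict TEP scores
#'
#' Applies the network to a batch of images and returns the sigmoid output
#' per sample — the TEP score in `[0, 1]`, where values near 0 indicate a
#' healthy profile and values near 1 a tumor-educated profile. Scores are
#' independent of how samples are batched.
#'
#' @param model A `cnn_model`.
#' @param images N x H x W array or an `image_set`.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, images) {
  ids <- NULL
  if (inherits(images, "image_set")) {
    ids <- images$sample_ids
    images <- images$images
  }
  if (length(dim(images)) == 2) images <- array(images, c(1, dim(images)))
  if (dim(images)[2] != model$input_height || dim(images)[3] != model$input_width) {
    stopf("image shape %d x %d does not match model input %d x %d",
          dim(images)[2], dim(images)[3], model$input_height, model$input_width)
  }
  p <- cnn_forward(model, flatten_images(images), train = FALSE)$p
  if (!is.null(ids)) names(p) <- ids
  p
}

#' Persist a trained model with its provenance sidecar
#'
#' Writes the model to RDS plus a JSON sidecar recording the architecture
#' spec and training configuration.
#'
#' @param model A `cnn_model`.
#' @param path Output `.rds` path; the sidecar is written alongside as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec),
               train_config = if (is.null(model$train_config)) NULL
                              else unclass(model$train_config),
               input = c(model$input_height, model$input_width),
               n_params = model$n_params, trained = model$trained)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Reload a model saved with [save_model()]
#' @param path `.rds` path.
#' @return A `cnn_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cnn_model")) stopf("'%s' is not a saved cnn_model", path)
  m
}
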