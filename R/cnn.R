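# Native 3D convolutional network for seed-ROI CSE volumes.
#
# The network is small and fixed in shape, so it is implemented directly:
# an im2col gather (compiled) turns each convolution into a dense matrix
# product, pooling layers use precomputed window index maps, and batch
# normalization / fully connected layers are plain matrix algebra. All
# randomness flows through R's RNG, which makes seeded training bit
# reproducible on one CPU.

# ---- index maps -------------------------------------------------------------

# Patch index map for a valid convolution: rows = output voxels (column-major
# order), cols = kernel offsets (x fastest); entries are 1-based voxel indices.
.conv_index_map <- function(dims, k) {
  od <- dims - k + 1L
  if (any(od < 1L)) return(NULL)
  ox <- rep(seq_len(od[1L]), times = od[2L] * od[3L])
  oy <- rep(rep(seq_len(od[2L]), each = od[1L]), times = od[3L])
  oz <- rep(seq_len(od[3L]), each = od[1L] * od[2L])
  offs <- expand.grid(kx = 0:(k - 1L), ky = 0:(k - 1L), kz = 0:(k - 1L))
  p <- matrix(0L, length(ox), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    p[, j] <- (ox + offs$kx[j]) +
      (oy + offs$ky[j] - 1L) * dims[1L] +
      (oz + offs$kz[j] - 1L) * dims[1L] * dims[2L]
  }
  list(P = p, out_dims = od)
}

# Window index map for non-overlapping pooling with floor division.
.pool_index_map <- function(dims, p) {
  od <- dims %/% p
  if (any(od < 1L)) return(NULL)
  ox <- rep(seq_len(od[1L]), times = od[2L] * od[3L])
  oy <- rep(rep(seq_len(od[2L]), each = od[1L]), times = od[3L])
  oz <- rep(seq_len(od[3L]), each = od[1L] * od[2L])
  offs <- expand.grid(kx = 0:(p - 1L), ky = 0:(p - 1L), kz = 0:(p - 1L))
  pm <- matrix(0L, length(ox), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    pm[, j] <- ((ox - 1L) * p + 1L + offs$kx[j]) +
      ((oy - 1L) * p + offs$ky[j]) * dims[1L] +
      ((oz - 1L) * p + offs$kz[j]) * dims[1L] * dims[2L]
  }
  list(P = pm, out_dims = od)
}

# Replicate a per-sample index map across a batch of stacked samples.
.batch_map <- function(p, n_vox_in, batch) {
  n_out <- nrow(p)
  p[rep(seq_len(n_out), batch), , drop = FALSE] +
    rep((seq_len(batch) - 1L) * n_vox_in, each = n_out)
}

# ---- architecture spec ------------------------------------------------------

#' 3D CNN architecture specification
#'
#' Fixed layer sequence: average pooling, then three convolution blocks (the
#' first two each followed by max pooling and batch normalization), then four
#' fully connected layers. ReLU follows every trainable layer except the last
#' fully connected layer, whose softmax produces the two class
#' probabilities. All convolutions are unpadded ("valid") and pooling uses
#' floor division; set `bn_before_pool = TRUE` to swap the max-pool /
#' batch-norm order.
#'
#' The full-scale default (average pool 2^3, filters 32/64/128 with kernels
#' 3^3/3^3/2^3, fully connected widths 500/500/500/2) is intended for
#' MNI-grid volumes; `profile = "reduced"` selects a desk-scale variant
#' (average pool 1, filters 4/8/8, widths 32/32/32/2) with the identical
#' layer sequence for small toy volumes. Profile and overrides are recorded
#' in the spec for provenance.
#'
#' @param input_dim Integer vector of 3 input extents.
#' @param profile `"full"` or `"reduced"`.
#' @param avgpool_size,conv_filters,conv_kernels,pool_size,fc_widths,bn_before_pool
#'   Optional overrides of the profile values.
#' @return Object of class `cnn_spec` with the resolved layer list and
#'   per-layer output shapes.
#' @export
cnn_spec <- function(input_dim, profile = c("full", "reduced"),
                     avgpool_size = NULL, conv_filters = NULL,
                     conv_kernels = NULL, pool_size = NULL,
                     fc_widths = NULL, bn_before_pool = FALSE) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(avgpool_size = 2L, conv_filters = c(32L, 64L, 128L),
         conv_kernels = c(3L, 3L, 2L), pool_size = 2L,
         fc_widths = c(500L, 500L, 500L, 2L))
  } else {
    list(avgpool_size = 1L, conv_filters = c(4L, 8L, 8L),
         conv_kernels = c(3L, 3L, 2L), pool_size = 2L,
         fc_widths = c(32L, 32L, 32L, 2L))
  }
  avgpool_size <- as.integer(avgpool_size %||% defaults$avgpool_size)
  conv_filters <- as.integer(conv_filters %||% defaults$conv_filters)
  conv_kernels <- as.integer(conv_kernels %||% defaults$conv_kernels)
  pool_size <- as.integer(pool_size %||% defaults$pool_size)
  fc_widths <- as.integer(fc_widths %||% defaults$fc_widths)
  input_dim <- as.integer(input_dim)
  if (length(input_dim) != 3L) stop("input_dim must give 3 extents")
  if (length(conv_filters) != 3L || length(conv_kernels) != 3L)
    stop("exactly three convolution layers are expected")
  if (fc_widths[length(fc_widths)] != 2L)
    stop("final fully connected layer must have width 2")

  layers <- list()
  dims <- input_dim
  channels <- 1L
  add <- function(layer) layers[[length(layers) + 1L]] <<- layer
  fail <- function(name, need) {
    stop(sprintf(
      "input extents (%s) too small for layer %s: remaining extents (%s) < %d",
      paste(input_dim, collapse = ","), name, paste(dims, collapse = ","), need))
  }

  if (avgpool_size > 1L) {
    map <- .pool_index_map(dims, avgpool_size)
    if (is.null(map)) fail("avgpool", avgpool_size)
    add(list(type = "avgpool", size = avgpool_size, map = map,
             in_dims = dims, channels = channels))
    dims <- map$out_dims
  }
  for (i in 1:3) {
    map <- .conv_index_map(dims, conv_kernels[i])
    if (is.null(map)) fail(sprintf("conv%d (%d^3 kernel)", i, conv_kernels[i]),
                           conv_kernels[i])
    add(list(type = "conv", name = sprintf("conv%d", i),
             kernel = conv_kernels[i], filters = conv_filters[i],
             in_channels = channels, map = map, in_dims = dims))
    dims <- map$out_dims
    channels <- conv_filters[i]
    add(list(type = "relu"))
    if (i < 3L) {
      block <- list()
      pmap <- NULL
      make_pool <- function() {
        pmap <<- .pool_index_map(dims, pool_size)
        if (is.null(pmap)) fail(sprintf("maxpool after conv%d", i), pool_size)
        list(type = "maxpool", size = pool_size, map = pmap,
             in_dims = dims, channels = channels)
      }
      bn <- list(type = "batchnorm", name = sprintf("bn%d", i),
                 channels = channels)
      if (bn_before_pool) {
        add(bn); add(make_pool())
      } else {
        add(make_pool()); add(bn)
      }
      dims <- pmap$out_dims
    }
  }
  add(list(type = "flatten", in_dims = dims, channels = channels))
  width <- prod(dims) * channels
  for (j in seq_along(fc_widths)) {
    add(list(type = "dense", name = sprintf("fc%d", j),
             in_width = width, out_width = fc_widths[j]))
    width <- fc_widths[j]
    if (j < length(fc_widths)) add(list(type = "relu")) else add(list(type = "softmax"))
  }

  structure(list(input_dim = input_dim, layers = layers, profile = profile,
                 avgpool_size = avgpool_size, conv_filters = conv_filters,
                 conv_kernels = conv_kernels, pool_size = pool_size,
                 fc_widths = fc_widths, bn_before_pool = bn_before_pool,
                 cache = new.env(parent = emptyenv())),
            class = "cnn_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Architecture audit table
#'
#' Introspects a [cnn_spec()]: one row per layer with its type, kernel or
#' pool size, filter count / width, and output shape, so the realized
#' architecture can be asserted directly.
#'
#' @param spec A `cnn_spec`.
#' @return `data.frame` with columns `layer`, `type`, `kernel`, `units`,
#'   `output_shape`.
#' @export
cnn_audit <- function(spec) {
  dims <- spec$input_dim
  channels <- 1L
  width <- NA_integer_
  rows <- list()
  for (l in spec$layers) {
    kernel <- NA_integer_
    units <- NA_integer_
    if (l$type %in% c("avgpool", "maxpool")) {
      kernel <- l$size
      dims <- l$map$out_dims
    } else if (l$type == "conv") {
      kernel <- l$kernel
      units <- l$filters
      dims <- l$map$out_dims
      channels <- l$filters
    } else if (l$type == "batchnorm") {
      units <- l$channels
    } else if (l$type == "flatten") {
      width <- prod(dims) * channels
    } else if (l$type == "dense") {
      units <- l$out_width
      width <- l$out_width
    }
    shape <- if (l$type %in% c("flatten", "dense") ||
                 (length(rows) && rows[[length(rows)]]$type %in% c("flatten", "dense") &&
                  l$type %in% c("relu", "softmax"))) {
      as.character(width)
    } else {
      paste(c(dims, channels), collapse = "x")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(layer = length(rows) + 1L, type = l$type, kernel = kernel,
                 units = units, output_shape = shape, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ---- weights ----------------------------------------------------------------

.init_weights <- function(spec) {
  w <- list()
  for (l in spec$layers) {
    if (l$type == "conv") {
      fan_in <- l$kernel^3 * l$in_channels
      w[[l$name]] <- list(
        W = matrix(stats::rnorm(fan_in * l$filters, sd = sqrt(2 / fan_in)),
                   fan_in, l$filters),
        b = numeric(l$filters))
    } else if (l$type == "batchnorm") {
      w[[l$name]] <- list(gamma = rep(1, l$channels), beta = numeric(l$channels),
                          run_mean = numeric(l$channels), run_var = rep(1, l$channels))
    } else if (l$type == "dense") {
      w[[l$name]] <- list(
        W = matrix(stats::rnorm(l$in_width * l$out_width, sd = sqrt(2 / l$in_width)),
                   l$in_width, l$out_width),
        b = numeric(l$out_width))
    }
  }
  w
}

# Retrieve (building lazily) the batch-replicated index map for a layer.
.get_batch_map <- function(spec, key, p, n_vox_in, batch) {
  full_key <- sprintf("%s_b%d", key, batch)
  if (is.null(spec$cache[[full_key]]))
    spec$cache[[full_key]] <- .batch_map(p, n_vox_in, batch)
  spec$cache[[full_key]]
}

# ---- forward / backward -----------------------------------------------------

# x: input matrix (n_vox x B). Returns list(probs, caches) in training mode,
# probabilities only otherwise. Batch-norm uses batch statistics in training
# mode and running statistics at inference.
.cnn_forward <- function(spec, weights, x, training = FALSE, bn_momentum = 0.1) {
  batch <- ncol(x)
  a <- matrix(as.vector(x), ncol = 1L)  # (B*n_vox) x 1, sample-stacked
  caches <- list()
  li <- 0L
  updated <- weights
  for (l in spec$layers) {
    li <- li + 1L
    cache <- list()
    if (l$type == "avgpool") {
      pm <- .get_batch_map(spec, sprintf("l%d", li), l$map$P,
                           prod(l$in_dims), batch)
      g <- gather_patches(a, pm)
      k3 <- ncol(l$map$P)
      ch <- ncol(a)
      out <- matrix(0, nrow(g), ch)
      for (c_ in seq_len(ch))
        out[, c_] <- rowMeans(g[, (c_ - 1L) * k3 + seq_len(k3), drop = FALSE])
      cache <- list(map = pm, k3 = k3, n_in = nrow(a))
      a <- out
    } else if (l$type == "conv") {
      pm <- .get_batch_map(spec, sprintf("l%d", li), l$map$P,
                           prod(l$in_dims), batch)
      patches <- gather_patches(a, pm)
      cache <- list(patches = patches, map = pm, n_in = nrow(a))
      a <- sweep(patches %*% weights[[l$name]]$W, 2L, weights[[l$name]]$b, "+")
    } else if (l$type == "relu") {
      cache <- list(mask = a > 0)
      a <- a * cache$mask
    } else if (l$type == "maxpool") {
      pm <- .get_batch_map(spec, sprintf("l%d", li), l$map$P,
                           prod(l$in_dims), batch)
      k3 <- ncol(l$map$P)
      ch <- ncol(a)
      out <- matrix(0, nrow(pm), ch)
      amax <- matrix(0L, nrow(pm), ch)
      for (c_ in seq_len(ch)) {
        vals <- matrix(a[, c_][pm], nrow(pm), k3)
        pick <- max.col(vals, ties.method = "first")
        out[, c_] <- vals[cbind(seq_len(nrow(pm)), pick)]
        amax[, c_] <- pm[cbind(seq_len(nrow(pm)), pick)]
      }
      cache <- list(argmax = amax, n_in = nrow(a))
      a <- out
    } else if (l$type == "batchnorm") {
      wl <- weights[[l$name]]
      eps <- 1e-5
      if (training) {
        mu <- colMeans(a)
        v <- colMeans(a^2) - mu^2
        updated[[l$name]]$run_mean <- (1 - bn_momentum) * wl$run_mean + bn_momentum * mu
        updated[[l$name]]$run_var <- (1 - bn_momentum) * wl$run_var + bn_momentum * v
      } else {
        mu <- wl$run_mean
        v <- wl$run_var
      }
      inv_sd <- 1 / sqrt(v + eps)
      xhat <- sweep(sweep(a, 2L, mu, "-"), 2L, inv_sd, "*")
      cache <- list(xhat = xhat, inv_sd = inv_sd, centered = sweep(a, 2L, mu, "-"))
      a <- sweep(sweep(xhat, 2L, wl$gamma, "*"), 2L, wl$beta, "+")
    } else if (l$type == "flatten") {
      nv <- prod(l$in_dims)
      ch <- l$channels
      arr <- a
      dim(arr) <- c(nv, batch, ch)
      a <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = batch)
      cache <- list(nv = nv, ch = ch)
    } else if (l$type == "dense") {
      cache <- list(x = a)
      a <- sweep(a %*% weights[[l$name]]$W, 2L, weights[[l$name]]$b, "+")
    } else if (l$type == "softmax") {
      z <- a - apply(a, 1L, max)
      e <- exp(z)
      a <- e / rowSums(e)
    }
    caches[[li]] <- cache
  }
  if (training) list(probs = a, caches = caches, weights = updated) else a
}

# Backward pass; returns gradients keyed like the weight list.
.cnn_backward <- function(spec, weights, caches, probs, y_onehot) {
  grads <- list()
  batch <- nrow(probs)
  delta <- (probs - y_onehot) / batch  # includes softmax + cross-entropy
  for (li in rev(seq_along(spec$layers))) {
    l <- spec$layers[[li]]
    cache <- caches[[li]]
    if (l$type == "softmax") {
      # folded into the initial delta
    } else if (l$type == "dense") {
      grads[[l$name]] <- list(W = crossprod(cache$x, delta), b = colSums(delta))
      delta <- delta %*% t(weights[[l$name]]$W)
    } else if (l$type == "flatten") {
      arr <- delta
      dim(arr) <- c(batch, cache$nv, cache$ch)
      delta <- matrix(aperm(arr, c(2L, 1L, 3L)), ncol = cache$ch)
    } else if (l$type == "batchnorm") {
      wl <- weights[[l$name]]
      n <- nrow(delta)
      dgamma <- colSums(delta * cache$xhat)
      dbeta <- colSums(delta)
      dxhat <- sweep(delta, 2L, wl$gamma, "*")
      dvar <- colSums(dxhat * cache$centered) * (-0.5) * cache$inv_sd^3
      dmu <- -colSums(dxhat) * cache$inv_sd - dvar * 2 * colMeans(cache$centered)
      delta <- sweep(dxhat, 2L, cache$inv_sd, "*") +
        sweep(cache$centered, 2L, 2 * dvar / n, "*") +
        matrix(dmu / n, n, length(dmu), byrow = TRUE)
      grads[[l$name]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$type == "maxpool") {
      up <- matrix(0, cache$n_in, ncol(delta))
      for (c_ in seq_len(ncol(delta)))
        up[cbind(cache$argmax[, c_], c_)] <- delta[, c_]
      delta <- up
    } else if (l$type == "relu") {
      delta <- delta * cache$mask
    } else if (l$type == "conv") {
      wl <- weights[[l$name]]
      grads[[l$name]] <- list(W = crossprod(cache$patches, delta),
                              b = colSums(delta))
      dpatches <- delta %*% t(wl$W)
      delta <- scatter_patches(dpatches, cache$map, cache$n_in)
    } else if (l$type == "avgpool") {
      k3 <- cache$k3
      ch <- ncol(delta)
      dpatches <- matrix(0, nrow(delta), k3 * ch)
      for (c_ in seq_len(ch))
        dpatches[, (c_ - 1L) * k3 + seq_len(k3)] <- delta[, c_] / k3
      delta <- scatter_patches(dpatches, cache$map, cache$n_in)
    }
  }
  grads
}

# ---- optimizer --------------------------------------------------------------

.adam_state <- function(weights) {
  rapply(weights, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = "ANY")
}

.adam_step <- function(weights, grads, state, t, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (name in names(grads)) {
    for (par in names(grads[[name]])) {
      g <- grads[[name]][[par]]
      st <- state[[name]][[par]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      weights[[name]][[par]] <- weights[[name]][[par]] - lr * mhat / (sqrt(vhat) + eps)
      state[[name]][[par]] <- st
    }
  }
  list(weights = weights, state = state)
}

# ---- training ---------------------------------------------------------------

#' Training hyperparameters
#'
#' Defaults follow the intended full-scale regime: categorical cross-entropy
#' loss, Adam with learning rate 1e-3, batch size 32, up to 400 epochs,
#' early stopping when the monitored validation loss has not improved for
#' 60 epochs (best weights restored).
#'
#' @param max_epochs,batch_size,learning_rate,early_stop_patience,seed
#'   Standard knobs; all must be positive and `early_stop_patience <=
#'   max_epochs`.
#' @return Object of class `train_hyper`.
#' @export
train_hyper <- function(max_epochs = 400L, batch_size = 32L,
                        learning_rate = 1e-3, early_stop_patience = 60L,
                        seed = 1L) {
  max_epochs <- as.integer(max_epochs)
  early_stop_patience <- as.integer(early_stop_patience)
  if (max_epochs < 1L || batch_size < 1L || learning_rate <= 0 ||
      early_stop_patience < 1L)
    stop("all hyperparameters must be positive")
  if (early_stop_patience > max_epochs)
    stop("early_stop_patience must not exceed max_epochs")
  structure(list(max_epochs = max_epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "train_hyper")
}

# Coerce a list of cse_volume / 3D arrays into an (n_vox x B) input matrix.
.volumes_to_matrix <- function(volumes, input_dim) {
  vapply(volumes, function(v) {
    vals <- if (inherits(v, "cse_volume")) v$values else v
    if (!all(dim(vals) == input_dim))
      stop("volume extents (", paste(dim(vals), collapse = ","),
           ") do not match model input (", paste(input_dim, collapse = ","), ")")
    as.numeric(vals)
  }, numeric(prod(input_dim)))
}

.mean_ce_loss <- function(probs, y) {
  idx <- cbind(seq_along(y), y + 1L)
  -mean(log(pmax(probs[idx], 1e-12)))
}

#' Train the 3D CNN on labelled CSE volumes
#'
#' Mini-batch Adam training with categorical cross-entropy, monitoring the
#' validation loss for early stopping: training stops once the validation
#' loss has not improved for `early_stop_patience` epochs (or at
#' `max_epochs`), and the weights from the best epoch are restored. Classes
#' are one-hot encoded in the order (non-suicidal, suicidal), i.e. label 0
#' then label 1. Fully deterministic given `hyper$seed`.
#'
#' @param spec A [cnn_spec()].
#' @param train_volumes,val_volumes Lists of `cse_volume` / 3D arrays.
#' @param train_labels,val_labels Integer 0/1 labels.
#' @param hyper A [train_hyper()].
#' @return Object of class `trained_cnn`: `spec`, `weights`, `history`
#'   (per-epoch train/validation loss), `best_epoch`.
#' @export
train_cnn <- function(spec, train_volumes, train_labels,
                      val_volumes, val_labels, hyper = train_hyper()) {
  train_labels <- as.integer(train_labels)
  val_labels <- as.integer(val_labels)
  if (length(unique(train_labels)) < 2L)
    stop("training set must contain both classes")
  x_train <- .volumes_to_matrix(train_volumes, spec$input_dim)
  x_val <- .volumes_to_matrix(val_volumes, spec$input_dim)
  old <- .restore_seed(hyper$seed)
  on.exit(old())
  weights <- .init_weights(spec)
  state <- .adam_state(weights)
  t_step <- 0L
  n <- length(train_labels)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf
  best_epoch <- 0L
  best_weights <- weights
  for (epoch in seq_len(hyper$max_epochs)) {
    order_ <- sample(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = hyper$batch_size)) {
      idx <- order_[start:min(start + hyper$batch_size - 1L, n)]
      xb <- x_train[, idx, drop = FALSE]
      yb <- train_labels[idx]
      fw <- .cnn_forward(spec, weights, xb, training = TRUE)
      weights <- fw$weights  # running BN statistics
      onehot <- matrix(0, length(yb), 2L)
      onehot[cbind(seq_along(yb), yb + 1L)] <- 1
      batch_losses <- c(batch_losses, .mean_ce_loss(fw$probs, yb))
      grads <- .cnn_backward(spec, weights, fw$caches, fw$probs, onehot)
      t_step <- t_step + 1L
      upd <- .adam_step(weights, grads, state, t_step, hyper$learning_rate)
      weights <- upd$weights
      state <- upd$state
    }
    val_probs <- .cnn_forward(spec, weights, x_val, training = FALSE)
    val_loss <- .mean_ce_loss(val_probs, val_labels)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(batch_losses), val_loss = val_loss))
    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss
      best_epoch <- epoch
      best_weights <- weights
    }
    if (epoch - best_epoch >= hyper$early_stop_patience) break
  }
  structure(list(spec = spec, weights = best_weights, history = history,
                 best_epoch = best_epoch, hyper = hyper),
            class = "trained_cnn")
}

#' Predict class probabilities for CSE volumes
#'
#' @param object A `trained_cnn`.
#' @param volumes List of `cse_volume` / 3D arrays matching the model input.
#' @param ... Unused.
#' @return B x 2 matrix of softmax probabilities, columns
#'   `c("non_suicidal", "suicidal")`; rows sum to 1.
#' @export
predict.trained_cnn <- function(object, volumes, ...) {
  x <- .volumes_to_matrix(volumes, object$spec$input_dim)
  probs <- .cnn_forward(object$spec, object$weights, x, training = FALSE)
  colnames(probs) <- c("non_suicidal", "suicidal")
  probs
}

#' Hard labels from predicted probabilities
#'
#' @param probs B x 2 probability matrix.
#' @return Integer vector of 0/1 labels (argmax).
#' @export
predicted_labels <- function(probs) {
  as.integer(max.col(probs, ties.method = "last") - 1L)
}
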