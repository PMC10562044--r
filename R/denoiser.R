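#' Architecture of the dense-skip convolutional denoiser
#'
#' Describes a DenseNet-style image restoration network: one low-level
#' convolution, `n_blocks` dense blocks of `convs_per_block` convolutions
#' (each layer inside a block receives the concatenation of the block input
#' and all previous in-block outputs), a 1x1 bottleneck fed by every
#' preceding feature map, two native-resolution reconstruction convolutions
#' (the "upscaling" stages of the super-resolution lineage, run at stride 1
#' because input and output here share resolution), and a single-channel
#' reconstruction layer.
#'
#' The full-scale configuration is `network_spec(n_blocks = 8,
#' convs_per_block = 8, growth = 16, low_level_filters = 16,
#' bottleneck_filters = 256)`; it has 1 + 64 + 1 + 2 + 1 = 69 weighted
#' layers and is intended for GPU-class training.  The default is a
#' desk-scale profile trainable on one CPU core in minutes.
#'
#' @param n_blocks number of dense blocks.
#' @param convs_per_block convolution layers per dense block.
#' @param growth feature maps added by each in-block convolution.
#' @param low_level_filters filters of the first convolution layer.
#' @param bottleneck_filters filters of the 1x1 bottleneck.
#' @param upscale_stages reconstruction-stage convolutions after the
#'   bottleneck (stride 1; kept for architectural fidelity).
#' @param kernel_size spatial kernel size of all non-bottleneck layers.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(n_blocks = 2L, convs_per_block = 4L, growth = 8L,
                         low_level_filters = 8L, bottleneck_filters = 16L,
                         upscale_stages = 2L, kernel_size = 3L) {
  stopifnot(n_blocks >= 1, convs_per_block >= 1, growth >= 1,
            low_level_filters >= 1, bottleneck_filters >= 1,
            upscale_stages >= 1, kernel_size %in% c(1L, 3L))
  structure(list(n_blocks = as.integer(n_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 growth = as.integer(growth),
                 low_level_filters = as.integer(low_level_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 upscale_stages = as.integer(upscale_stages),
                 kernel_size = as.integer(kernel_size)),
            class = "network_spec")
}

#' Training configuration for the denoiser
#'
#' Defaults follow the published recipe: Adam with learning rate 1e-4,
#' first-moment decay (momentum) 0.9, weight decay 1e-4, mini-batches of
#' 32 sub-images, RMSE loss on normalised counts, MSRA (He) weight
#' initialisation with zero biases.  One iteration processes one batch.
#'
#' @param iterations number of mini-batch updates.
#' @param batch_size sub-images per batch.
#' @param learning_rate Adam step size.
#' @param beta1 Adam first-moment decay (the "momentum" of the recipe).
#' @param beta2 Adam second-moment decay.
#' @param weight_decay L2 penalty added to weight gradients (not biases).
#' @param seed integer seed fixing initialisation and batch order.
#' @param norm_quantile quantile of the label counts used as the
#'   counts-to-\[0,1\] normalisation constant.
#' @param tail_average fraction of the final iterations whose weights are
#'   averaged into the returned model (Polyak averaging; 0 keeps the last
#'   iterate).  Averaging the tail of the Adam trajectory suppresses the
#'   batch-to-batch wobble that short training budgets leave behind.
#' @return an object of class `train_config`.
#' @export
train_config <- function(iterations = 2000L, batch_size = 32L,
                         learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, seed = 1L,
                         norm_quantile = 0.999, tail_average = 0) {
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1, weight_decay >= 0,
            tail_average >= 0, tail_average <= 1)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 norm_quantile = norm_quantile, tail_average = tail_average),
            class = "train_config")
}

# Layer plan: list of conv layers, each with 0-based source block ids
# (0 = input image, i = output of layer i), kernel size, output channels
# and activation.  Dense connectivity is expressed entirely through the
# src lists; the bottleneck sees every preceding feature map.
build_plan <- function(spec) {
  layers <- list()
  channels <- c(1L)                      # block 0 = input image
  add <- function(src, k, cout, relu) {
    layers[[length(layers) + 1L]] <<- list(src = as.integer(src), k = as.integer(k),
                                           cout = as.integer(cout), relu = relu)
    channels <<- c(channels, cout)
    length(layers)                       # block id of this layer's output
  }
  low <- add(0L, spec$kernel_size, spec$low_level_filters, TRUE)
  block_in <- low                        # ids forming the current block input
  all_feats <- c(low)
  for (b in seq_len(spec$n_blocks)) {
    in_block <- integer(0)
    for (j in seq_len(spec$convs_per_block)) {
      src <- c(block_in, in_block)
      id <- add(src, spec$kernel_size, spec$growth, TRUE)
      in_block <- c(in_block, id)
    }
    all_feats <- c(all_feats, in_block)
    block_in <- c(block_in, in_block)    # next block sees everything so far
  }
  bott <- add(all_feats, 1L, spec$bottleneck_filters, TRUE)
  prev <- bott
  for (s in seq_len(spec$upscale_stages))
    prev <- add(prev, spec$kernel_size, spec$bottleneck_filters, TRUE)
  add(prev, spec$kernel_size, 1L, FALSE)
  list(layers = layers, channels = channels)
}

plan_in_channels <- function(plan, l) {
  sum(plan$channels[plan$layers[[l]]$src + 1L])
}

# MSRA / He initialisation: N(0, sqrt(2 / fan_in)), biases zero.
init_weights <- function(plan) {
  lapply(seq_along(plan$layers), function(l) {
    lay <- plan$layers[[l]]
    cin <- plan_in_channels(plan, l)
    fan_in <- lay$k^2 * cin
    matrix(stats::rnorm(lay$cout * fan_in, sd = sqrt(2 / fan_in)),
           nrow = lay$cout, ncol = fan_in)
  })
}

#' Build an untrained denoiser
#'
#' Instantiates the network of a [network_spec()] with MSRA-initialised
#' weights and zero biases.  The returned object can be trained with
#' [train_denoiser()] or passed straight to [denoiser()].
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `densenet_denoiser` with `trained = FALSE`.
#' @export
build_model <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  plan <- build_plan(spec)
  set.seed(seed)
  weights <- init_weights(plan)
  biases <- lapply(plan$layers, function(l) numeric(l$cout))
  structure(list(spec = spec, plan = plan, weights = weights, biases = biases,
                 trained = FALSE, norm_const = NA_real_,
                 loss_history = numeric(0), config = NULL, seed = seed),
            class = "densenet_denoiser")
}

#' Number of weighted layers of a network
#'
#' @param spec a [network_spec()].
#' @return integer layer count (low-level + in-block + bottleneck +
#'   reconstruction-stage + output layers).
#' @export
n_weighted_layers <- function(spec) {
  1L + spec$n_blocks * spec$convs_per_block + 1L + spec$upscale_stages + 1L
}

#' Extract co-located training sub-images from an input/label pair
#'
#' Cuts `size` x `size` sub-images on a non-overlapping stride grid.  The
#' grid origin is `offset` (0-based); when unset a random offset is drawn
#' per image so tiles never overlap yet placement varies between images.
#' Pairs whose label sub-image contains no foreground (all zero) are
#' discarded.  Only fully inside tiles are kept.
#'
#' @param input_img,label_img numeric matrices of identical shape; counts.
#' @param size sub-image side length in pixels.
#' @param stride grid stride in pixels.
#' @param offset optional length-2 integer (row, col) grid origin, 0-based.
#' @return a `patch_dataset`: list with `input` and `label` (size^2 x n
#'   matrices, one column per sub-image), `size`, and a `provenance` data
#'   frame of grid offsets.
#' @export
extract_patches <- function(input_img, label_img, size = 25L, stride = 25L,
                            offset = NULL) {
  input_img <- as_count_matrix(input_img)
  label_img <- as_count_matrix(label_img)
  if (!identical(dim(input_img), dim(label_img)))
    stop("input and label images must have the same shape")
  size <- as.integer(size); stride <- as.integer(stride)
  if (size > min(dim(input_img)))
    stop("sub-image size exceeds image dimensions")
  if (is.null(offset)) {
    slack <- pmax(dim(input_img) %% stride, 0L)
    offset <- c(sample.int(slack[1] + 1L, 1L) - 1L,
                sample.int(slack[2] + 1L, 1L) - 1L)
  }
  offset <- as.integer(offset)
  r0 <- seq.int(1L + offset[1], nrow(input_img) - size + 1L, by = stride)
  c0 <- seq.int(1L + offset[2], ncol(input_img) - size + 1L, by = stride)
  xs <- list(); ys <- list(); prov <- list()
  for (i in r0) for (j in c0) {
    lab <- label_img[i:(i + size - 1L), j:(j + size - 1L)]
    if (all(lab == 0)) next
    xs[[length(xs) + 1L]] <- as.vector(input_img[i:(i + size - 1L), j:(j + size - 1L)])
    ys[[length(ys) + 1L]] <- as.vector(lab)
    prov[[length(prov) + 1L]] <- c(i, j)
  }
  n <- length(xs)
  structure(list(
    input = if (n) matrix(unlist(xs), ncol = n) else matrix(0, size^2, 0),
    label = if (n) matrix(unlist(ys), ncol = n) else matrix(0, size^2, 0),
    size = size,
    weights = rep(1, n),
    provenance = if (n) {
      po <- do.call(rbind, prov)
      data.frame(row = po[, 1], col = po[, 2])
    } else data.frame(row = integer(0), col = integer(0))),
    class = "patch_dataset")
}

#' Concatenate patch datasets
#' @param ... `patch_dataset` objects of identical sub-image size.
#' @return a single `patch_dataset`.
#' @export
bind_patches <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) && !inherits(ds[[1]], "patch_dataset"))
    ds <- ds[[1]]
  stopifnot(all(vapply(ds, inherits, TRUE, "patch_dataset")))
  sizes <- vapply(ds, `[[`, 1L, "size")
  stopifnot(length(unique(sizes)) == 1L)
  structure(list(input = do.call(cbind, lapply(ds, `[[`, "input")),
                 label = do.call(cbind, lapply(ds, `[[`, "label")),
                 size = sizes[1],
                 weights = unlist(lapply(ds, function(d)
                   if (is.null(d$weights)) rep(1, ncol(d$input)) else d$weights)),
                 provenance = do.call(rbind, lapply(ds, `[[`, "provenance"))),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("Patch dataset: %d pairs of %dx%d sub-images\n",
              ncol(x$input), x$size, x$size))
  invisible(x)
}

#' Fit the dense-skip denoiser
#'
#' The model-fitting entry point: initialises a network from `spec` and
#' trains it on paired noisy/full-count sub-images by minimising the RMSE
#' between the network output and the label in normalised count units.
#' Counts are scaled to roughly \[0, 1\] by the `norm_quantile` quantile of
#' the label counts; the constant is stored with the model and reapplied
#' at prediction time.
#'
#' @param data a `patch_dataset` from [extract_patches()]/[bind_patches()].
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @return a fitted `densenet_denoiser` with components `weights`,
#'   `loss_history` (one RMSE per iteration), `norm_const`, `spec`,
#'   `config`.
#' @seealso [predict.densenet_denoiser()], [denoise_image()]
#' @export
denoiser <- function(data, spec = network_spec(), config = train_config()) {
  model <- build_model(spec, seed = config$seed)
  train_denoiser(model, data, config)
}

#' Train (or continue training) a denoiser
#'
#' @param model a `densenet_denoiser` from [build_model()].
#' @param data a `patch_dataset`.
#' @param config a [train_config()].
#' @return the trained model.
#' @export
train_denoiser <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "densenet_denoiser"),
            inherits(data, "patch_dataset"),
            inherits(config, "train_config"))
  n <- ncol(data$input)
  if (n == 0L) stop("empty patch dataset")
  K <- stats::quantile(data$label, config$norm_quantile, names = FALSE)
  if (!is.finite(K) || K <= 0) K <- max(data$label, 1)
  X <- data$input / K
  Y <- data$label / K
  size <- data$size
  plan <- model$plan
  W <- model$weights; B <- model$biases
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(B, function(b) b * 0); vB <- mB
  lr <- config$learning_rate; b1 <- config$beta1; b2 <- config$beta2
  wd <- config$weight_decay; eps <- 1e-8
  w <- data$weights
  if (is.null(w) || !any(w != w[1])) w <- NULL
  tail_avg <- if (is.null(config$tail_average)) 0 else config$tail_average
  n_tail <- max(1L, as.integer(round(tail_avg * config$iterations)))
  t_start <- config$iterations - n_tail + 1L
  sumW <- NULL; sumB <- NULL
  set.seed(config$seed)
  loss_hist <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n, config$batch_size, replace = TRUE, prob = w)
    xb <- as.vector(X[, idx]); yb <- as.vector(Y[, idx])
    g <- cpp_net_loss_grad(plan$layers, W, B, xb, yb,
                           size, size, length(idx))
    loss_hist[it] <- g$loss
    t_ <- it
    for (l in seq_along(W)) {
      gw <- g$dW[[l]] + wd * W[[l]]
      gb <- g$db[[l]]
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gw
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gw^2
      mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gb
      vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gb^2
      hat <- function(m, v) (m / (1 - b1^t_)) / (sqrt(v / (1 - b2^t_)) + eps)
      W[[l]] <- W[[l]] - lr * hat(mW[[l]], vW[[l]])
      B[[l]] <- B[[l]] - lr * hat(mB[[l]], vB[[l]])
    }
    if (it >= t_start && tail_avg > 0) {
      if (is.null(sumW)) {
        sumW <- W; sumB <- B
      } else {
        for (l in seq_along(W)) {
          sumW[[l]] <- sumW[[l]] + W[[l]]
          sumB[[l]] <- sumB[[l]] + B[[l]]
        }
      }
    }
  }
  if (!is.null(sumW) && tail_avg > 0 && config$iterations > 0) {
    W <- lapply(sumW, function(w) w / n_tail)
    B <- lapply(sumB, function(b) b / n_tail)
  }
  model$weights <- W
  model$biases <- B
  model$trained <- TRUE
  model$norm_const <- K
  model$loss_history <- c(model$loss_history, loss_hist)
  model$config <- config
  model
}

#' Denoise an image with a fitted model
#'
#' Normalises the image by the model's stored constant, runs the network
#' on the whole image (the stride-1 architecture accepts any size), and
#' returns un-normalised real-valued counts with negatives clamped to 0.
#'
#' @param object a trained `densenet_denoiser`.
#' @param newdata a [count_image()] or numeric matrix.
#' @param ... unused.
#' @return same type as `newdata`: a `count_image` (real-valued counts,
#'   `denoised = TRUE`) or a matrix.
#' @export
predict.densenet_denoiser <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop("model has not been trained")
  img <- as_count_matrix(newdata)
  x <- as.vector(img) / object$norm_const
  out <- cpp_net_forward(object$plan$layers, object$weights, object$biases,
                         x, nrow(img), ncol(img), 1L)
  out <- matrix(pmax(out, 0) * object$norm_const, nrow(img), ncol(img))
  if (inherits(newdata, "count_image")) {
    res <- newdata
    res$counts <- out
    res$denoised <- TRUE
    res
  } else out
}

#' @rdname predict.densenet_denoiser
#' @param model a trained `densenet_denoiser`.
#' @param image image to denoise.
#' @export
denoise_image <- function(model, image) predict(model, image)

#' @export
print.densenet_denoiser <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Dense-skip convolutional denoiser (%s)\n",
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  %d blocks x %d convs, growth %d, low-level %d, bottleneck %d\n",
              s$n_blocks, s$convs_per_block, s$growth, s$low_level_filters,
              s$bottleneck_filters))
  cat(sprintf("  weighted layers: %d, parameters: %d\n",
              n_weighted_layers(s),
              sum(vapply(x$weights, length, 1L)) + sum(vapply(x$biases, length, 1L))))
  if (isTRUE(x$trained))
    cat(sprintf("  iterations: %d, final RMSE loss: %.5f, norm const: %.3f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1),
                x$norm_const))
  invisible(x)
}

#' @export
summary.densenet_denoiser <- function(object, ...) {
  print(object)
  plan <- object$plan
  cat("  layer channels in -> out:\n")
  for (l in seq_along(plan$layers)) {
    lay <- plan$layers[[l]]
    cat(sprintf("    %2d: %dx%d conv %3d -> %3d%s\n", l, lay$k, lay$k,
                plan_in_channels(plan, l), lay$cout,
                if (lay$relu) " (relu)" else ""))
  }
  invisible(object)
}

#' @export
coef.densenet_denoiser <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
plot.densenet_denoiser <- function(x, ...) {
  if (!length(x$loss_history)) stop("no loss history to plot")
  graphics::plot(x$loss_history, type = "l", xlab = "iteration",
                 ylab = "RMSE loss (normalised counts)", ...)
  invisible(x)
}

#' Save / load a denoiser checkpoint
#'
#' Plain-text checkpoint: JSON holding the spec, config, normalisation
#' constant, loss history, and all weights.
#'
#' @param model a `densenet_denoiser`.
#' @param path file path.
#' @return `write_denoiser` returns `path` invisibly; `read_denoiser`
#'   returns the model.
#' @export
write_denoiser <- function(model, path) {
  stopifnot(inherits(model, "densenet_denoiser"))
  obj <- list(spec = unclass(model$spec),
              config = if (!is.null(model$config)) unclass(model$config),
              trained = model$trained, norm_const = model$norm_const,
              seed = model$seed, loss_history = model$loss_history,
              weights = model$weights, biases = model$biases)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_denoiser
#' @export
read_denoiser <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, as.list(obj$spec))
  model <- build_model(spec, seed = obj$seed)
  model$weights <- lapply(obj$weights, as.matrix)
  model$biases <- lapply(obj$biases, as.numeric)
  model$trained <- obj$trained
  model$norm_const <- obj$norm_const
  model$loss_history <- as.numeric(obj$loss_history)
  if (!is.null(obj$config)) model$config <- do.call(train_config, as.list(obj$config))
  model
}
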