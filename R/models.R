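# CNN and modified-ResNet scorers over binding matrices.
#
# `build_cnn()` / `build_resnet()` construct untrained scorers from config
# objects; `train_scorer()` is the fitting function and returns a classed
# `trained_scorer` with the usual S3 surface (print, summary, coef,
# predict, plot).

#' CNN scorer configuration
#'
#' The reference architecture stacks `conv_blocks` blocks of
#' (convolution, leaky ReLU, batch normalization, 2x2 max pooling where
#' scheduled, dropout), then `length(dense_units)` dense blocks
#' (dense, leaky ReLU, batch normalization, dropout), and a single
#' sigmoid output unit. Defaults follow the published full-scale recipe:
#' 6 convolutional blocks with 5x5 kernels, 2 dense blocks, dropout 0.3,
#' Adam with learning rate 0.00152, 10 epochs, batch size 32. The `"desk"`
#' profile shrinks channel widths and epochs so a training run fits in CI
#' on one CPU; the architecture shape is unchanged.
#'
#' @param profile `"full"` or `"desk"`; chooses the default widths/epochs.
#' @param conv_blocks number of convolutional blocks (>= 1).
#' @param filters channel width per conv block (recycled to `conv_blocks`).
#' @param kernel convolution kernel size, `c(height, width)`.
#' @param pool_blocks indices of blocks followed by 2x2 max pooling.
#' @param dense_units widths of the dense blocks.
#' @param dropout_rate dropout probability.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size training schedule.
#' @param leaky_alpha negative slope of the leaky ReLU.
#' @param input_dim input grid size, rows x columns (miRNA x target).
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(profile = c("full", "desk"),
                       conv_blocks = 6L,
                       filters = NULL,
                       kernel = c(5L, 5L),
                       pool_blocks = NULL,
                       dense_units = NULL,
                       dropout_rate = 0.3,
                       learning_rate = 0.00152,
                       epochs = NULL,
                       batch_size = 32L,
                       leaky_alpha = 0.3,
                       input_dim = c(20L, 50L)) {
  profile <- match.arg(profile)
  conv_blocks <- as.integer(conv_blocks)
  if (is.null(filters))
    filters <- if (profile == "full") c(32L, 32L, 64L, 64L, 128L, 128L)
               else c(8L, 8L, 16L, 16L, 32L, 32L)
  if (is.null(pool_blocks)) pool_blocks <- c(2L, 4L, 6L)
  if (is.null(dense_units))
    dense_units <- if (profile == "full") c(128L, 64L) else c(32L, 16L)
  if (is.null(epochs)) epochs <- if (profile == "full") 10L else 6L
  if (profile == "desk") {
    # CI-scale preset: fewer/wider-batched steps converge in minutes on one
    # CPU; the full profile keeps the published schedule.
    if (missing(dropout_rate)) dropout_rate <- 0.1
    if (missing(learning_rate)) learning_rate <- 0.003
    if (missing(batch_size)) batch_size <- 128L
  }
  if (conv_blocks < 1L)
    stop("a CNN scorer needs at least one convolutional block", call. = FALSE)
  if (length(dense_units) < 1L)
    stop("need at least one dense block", call. = FALSE)
  filters <- rep_len(as.integer(filters), conv_blocks)
  pool_blocks <- intersect(as.integer(pool_blocks), seq_len(conv_blocks))
  cfg <- list(profile = profile, conv_blocks = conv_blocks, filters = filters,
              kernel = as.integer(kernel), pool_blocks = pool_blocks,
              dense_units = as.integer(dense_units),
              dropout_rate = dropout_rate, learning_rate = learning_rate,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              leaky_alpha = leaky_alpha, input_dim = as.integer(input_dim))
  class(cfg) <- "cnn_config"
  cfg
}

#' Modified-ResNet scorer configuration
#'
#' A residual network adapted to the small 20 x 50 input: there is no
#' initial 7x7 convolution and no initial pooling (which would shrink the
#' grid below what later blocks need); the first operation is the first
#' residual stage's own 3x3 convolution. Stages are separated by 2x2 max
#' pooling, and the head is global average pooling into a single sigmoid
#' unit.
#'
#' @param blocks residual blocks per stage.
#' @param filters channel width per stage (same length as `blocks`).
#' @inheritParams cnn_config
#' @return list of class `resnet_config`.
#' @export
resnet_config <- function(blocks = c(2L, 2L, 2L),
                          filters = c(8L, 16L, 32L),
                          learning_rate = 0.00152,
                          epochs = 4L,
                          batch_size = 32L,
                          leaky_alpha = 0.3,
                          input_dim = c(20L, 50L)) {
  if (length(blocks) != length(filters))
    stop("`blocks` and `filters` must have the same length", call. = FALSE)
  if (length(blocks) < 1L || any(blocks < 1L))
    stop("need at least one residual block per stage", call. = FALSE)
  cfg <- list(blocks = as.integer(blocks), filters = as.integer(filters),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), leaky_alpha = leaky_alpha,
              input_dim = as.integer(input_dim))
  class(cfg) <- "resnet_config"
  cfg
}

#' Build an untrained CNN scorer
#'
#' Assembles the layer stack described by the config and initializes
#' parameters (He initialization, deterministic under `init_seed`). The
#' spatial footprint is validated: a configuration whose pooling schedule
#' would shrink a feature map below 1x1 is rejected, naming the offending
#' block.
#'
#' @param config a [cnn_config()].
#' @param init_seed seed for parameter initialization.
#' @return object of class `c("cnn_scorer", "nn_scorer")`.
#' @export
build_cnn <- function(config = cnn_config(), init_seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  H <- config$input_dim[1]
  W <- config$input_dim[2]
  layers <- list()
  cin <- 1L
  for (b in seq_len(config$conv_blocks)) {
    layers <- c(layers, list(
      nn_conv(cin, config$filters[b], config$kernel[1], config$kernel[2]),
      nn_lrelu(config$leaky_alpha),
      nn_bn2d(config$filters[b])))
    if (b %in% config$pool_blocks) {
      if (H < 2L || W < 2L)
        stop(sprintf("conv block %d: cannot pool a %dx%d feature map",
                     b, H, W), call. = FALSE)
      layers <- c(layers, list(nn_maxpool2()))
      H <- H %/% 2L
      W <- W %/% 2L
    }
    layers <- c(layers, list(nn_dropout(config$dropout_rate)))
    cin <- config$filters[b]
  }
  layers <- c(layers, list(nn_flatten()))
  din <- H * W * cin
  for (u in config$dense_units) {
    layers <- c(layers, list(nn_dense(din, u),
                             nn_lrelu(config$leaky_alpha),
                             nn_bn1d(u),
                             nn_dropout(config$dropout_rate)))
    din <- u
  }
  layers <- c(layers, list(nn_dense(din, 1L)))   # sigmoid applied in the loss
  net <- list(layers = layers)
  net <- with_seed(init_seed, nn_init(net))
  structure(list(arch = "cnn", config = config, net = net,
                 n_params = nn_count_params(net)),
            class = c("cnn_scorer", "nn_scorer"))
}

#' Build an untrained modified-ResNet scorer
#'
#' @param config a [resnet_config()].
#' @param init_seed seed for parameter initialization.
#' @return object of class `c("resnet_scorer", "nn_scorer")`.
#' @export
build_resnet <- function(config = resnet_config(), init_seed = 1L) {
  stopifnot(inherits(config, "resnet_config"))
  H <- config$input_dim[1]
  W <- config$input_dim[2]
  layers <- list()
  cin <- 1L
  for (s in seq_along(config$blocks)) {
    if (s > 1L) {
      if (H < 2L || W < 2L)
        stop(sprintf("stage %d: cannot pool a %dx%d feature map", s, H, W),
             call. = FALSE)
      layers <- c(layers, list(nn_maxpool2()))
      H <- H %/% 2L
      W <- W %/% 2L
    }
    for (b in seq_len(config$blocks[s])) {
      layers <- c(layers, list(nn_resblock(cin, config$filters[s],
                                           config$leaky_alpha)))
      cin <- config$filters[s]
    }
  }
  layers <- c(layers, list(nn_gap(), nn_dense(cin, 1L)))
  net <- list(layers = layers)
  net <- with_seed(init_seed, nn_init(net))
  structure(list(arch = "resnet", config = config, net = net,
                 n_params = nn_count_params(net)),
            class = c("resnet_scorer", "nn_scorer"))
}

# Coerce pairs / matrices / arrays into the (20, 50, 1, N) input tensor.
as_input_tensor <- function(x) {
  if (is.data.frame(x)) x <- encode_batch(x)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (length(d) == 3L) {
    x <- array(x, c(d[1], d[2], 1L, d[3]))
  } else if (length(d) != 4L) {
    stop("input must be a pair data.frame, one matrix, or a (H, W, n) array",
         call. = FALSE)
  }
  x
}

#' Train a scorer on a labeled dataset
#'
#' Optimizes binary cross-entropy (evaluated against possibly soft labels)
#' with the Adam optimizer, in shuffled mini-batches. Per-epoch training
#' and validation losses are logged; when a validation set with both
#' classes is given, the parameters of the epoch with the best validation
#' auPRC are retained (the model-selection metric for imbalanced data).
#' The whole run — initialization, shuffling, dropout — is reproducible
#' under `seed`.
#'
#' @param scorer an untrained scorer from [build_cnn()] or [build_resnet()].
#' @param train_set a `ratio_dataset` or pair data.frame with `label`.
#' @param val_set optional validation dataset of the same form.
#' @param seed integer seed controlling the full training run.
#' @param epochs,batch_size,learning_rate optional overrides of the config.
#' @param verbose print per-epoch losses.
#' @return object of class `trained_scorer`.
#' @export
train_scorer <- function(scorer, train_set, val_set = NULL, seed = 1L,
                         epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(scorer, "nn_scorer"))
  cfg <- scorer$config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  if (nrow(train_set) == 0L) stop("empty training set", call. = FALSE)
  y <- train_set$label
  if (any(!(y %in% 1 | (y >= 0 & y <= 0.5))))
    stop("training labels must lie in [0, 0.5] or equal 1", call. = FALSE)

  x <- as_input_tensor(train_set)
  has_val <- !is.null(val_set) && nrow(val_set) > 0L
  if (has_val) {
    xv <- as_input_tensor(val_set)
    yv <- val_set$label
    yv_hard <- as.numeric(yv > 0.5)
    val_two_class <- length(unique(yv_hard)) == 2L
  }

  N <- dim(x)[4]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auprc = numeric(0))
  best <- list(auprc = -Inf, net = NULL, epoch = NA_integer_)

  run <- with_seed(seed, {
    net <- nn_init(scorer$net)          # re-init under the training seed
    opt <- adam_init(net)
    for (ep in seq_len(epochs)) {
      ord <- sample(N)
      losses <- numeric(0)
      for (s in seq(1L, N, by = batch_size)) {
        e <- min(s + batch_size - 1L, N)
        take <- ord[s:e]
        xb <- x[, , , take, drop = FALSE]
        yb <- y[take]
        fw <- nn_forward(net, xb, training = TRUE)
        net <- fw$net
        lo <- bce_with_logits(as.numeric(fw$out), yb)
        if (!is.finite(lo$loss))
          stop(sprintf(
            "non-finite training loss at epoch %d (batch starting %d); last finite loss %.4f — consider lowering the learning rate",
            ep, s, if (length(losses)) losses[length(losses)] else NA_real_),
            call. = FALSE)
        dz <- matrix(lo$dz, nrow = 1L)
        grads <- nn_backward(net, fw$caches, dz)
        st <- adam_step(net, grads, opt, lr)
        net <- st$net
        opt <- st$state
        losses <- c(losses, lo$loss)
      }
      tr_loss <- mean(losses)
      vl <- NA_real_
      va <- NA_real_
      if (has_val) {
        pv <- nn_predict_probs(net, xv, batch_size = 512L)
        eps <- 1e-12
        vl <- mean(-(yv * log(pmax(pv, eps)) +
                       (1 - yv) * log(pmax(1 - pv, eps))))
        if (val_two_class) {
          va <- auprc(pv, yv_hard)
          if (va > best$auprc) best <- list(auprc = va, net = net, epoch = ep)
        }
      }
      history[ep, ] <- list(ep, tr_loss, vl, va)
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f  val loss %s  val auPRC %s",
                        ep, tr_loss,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl)),
                        ifelse(is.na(va), "-", sprintf("%.4f", va))))
    }
    list(net = net, best = best)
  })

  final_net <- if (!is.null(run$best$net)) run$best$net else run$net
  structure(list(arch = scorer$arch, config = cfg, net = final_net,
                 last_net = run$net, history = history, seed = seed,
                 n_params = scorer$n_params,
                 best_epoch = run$best$epoch,
                 provenance = list(
                   n_train = N,
                   n_positive = sum(y == 1),
                   n_soft = sum(y > 0 & y <= 0.5),
                   ratio = attr(train_set, "ratio"),
                   dataset_seed = attr(train_set, "rng_seed"),
                   epochs = epochs, batch_size = batch_size,
                   learning_rate = lr)),
            class = "trained_scorer")
}

#' Predict binding scores for miRNA:target pairs
#'
#' Inference is deterministic (dropout off, batch statistics frozen) and
#' order-preserving; batched and unbatched calls agree to within numerical
#' round-off.
#'
#' @param object a `trained_scorer`.
#' @param newdata pair data.frame, `binding_matrix`, or (20, 50, n) array.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return numeric vector of scores in [0, 1].
#' @export
predict.trained_scorer <- function(object, newdata, batch_size = 256L, ...) {
  if (is.data.frame(newdata) && nrow(newdata) == 0L) return(numeric(0))
  x <- as_input_tensor(newdata)
  nn_predict_probs(object$net, x, batch_size = batch_size)
}

#' Score pairs with a trained scorer
#'
#' Functional alias of [predict.trained_scorer()].
#'
#' @inheritParams predict.trained_scorer
#' @param scorer a `trained_scorer`.
#' @param pairs pairs to score.
#' @return numeric vector of scores in [0, 1].
#' @export
predict_scores <- function(scorer, pairs, batch_size = 256L) {
  predict(scorer, pairs, batch_size = batch_size)
}

# Score with any committee member: a trained scorer, or a plain function
# mapping a pair data.frame to scores in [0, 1] (used in tests and for
# baseline committees).
scorer_predict <- function(scorer, pairs) {
  s <- if (inherits(scorer, "trained_scorer")) predict(scorer, pairs)
       else if (is.function(scorer)) scorer(pairs)
       else stop("committee members must be trained scorers or functions",
                 call. = FALSE)
  if (length(s) != nrow(pairs))
    stop("scorer returned wrong number of scores", call. = FALSE)
  if (any(s < 0 | s > 1))
    stop("scorer output outside [0, 1]", call. = FALSE)
  s
}

#' @export
print.trained_scorer <- function(x, ...) {
  cat(sprintf("%s scorer (%s profile): %d parameters, trained %d epoch(s) on %d pairs\n",
              toupper(x$arch),
              if (!is.null(x$config$profile)) x$config$profile else "custom",
              x$n_params, nrow(x$history), x$provenance$n_train))
  if (!is.na(x$best_epoch))
    cat(sprintf("  best validation auPRC %.4f at epoch %d\n",
                max(x$history$val_auprc, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @exportS3Method base::summary
summary.trained_scorer <- function(object, ...) {
  cat(sprintf("%s scorer, seed %d\n", toupper(object$arch), object$seed))
  cat(sprintf("  parameters: %d\n", object$n_params))
  p <- object$provenance
  cat(sprintf("  training: %d pairs (%d positive, %d soft-labeled), %d epochs, batch %d, lr %g\n",
              p$n_train, p$n_positive, p$n_soft, p$epochs, p$batch_size,
              p$learning_rate))
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @exportS3Method stats::coef
coef.trained_scorer <- function(object, ...) {
  paths <- param_paths(object$net)
  out <- lapply(paths, function(p) get_param(object$net, p))
  names(out) <- vapply(paths, function(p)
    paste(na.omit(c(paste0("layer", p[1]), p[2], p[3])), collapse = "."),
    character(1))
  out
}

#' @exportS3Method graphics::plot
plot.trained_scorer <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "b", ylim = rng,
                 xlab = "Epoch", ylab = "Binary cross-entropy",
                 main = sprintf("%s training", toupper(x$arch)), ...)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2, pch = 2)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), pch = c(1, 2), bty = "n")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf("CNN config (%s): %d conv blocks (filters %s, kernel %dx%d, pool after %s), dense %s\n",
              x$profile, x$conv_blocks, paste(x$filters, collapse = ","),
              x$kernel[1], x$kernel[2],
              paste(x$pool_blocks, collapse = ","),
              paste(x$dense_units, collapse = ",")))
  cat(sprintf("  dropout %.2f, lr %g, %d epochs, batch %d\n",
              x$dropout_rate, x$learning_rate, x$epochs, x$batch_size))
  invisible(x)
}
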