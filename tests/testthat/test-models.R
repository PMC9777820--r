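# Tiny configurations keep these structural/optimization checks fast; the
# desk-scale learnability properties live in the acceptance suite.

tiny_cnn <- function(...) {
  cnn_config("desk", conv_blocks = 2, filters = c(4, 4), kernel = c(3, 3),
             pool_blocks = 1:2, dense_units = 8, dropout_rate = 0,
             epochs = 3, batch_size = 8, ...)
}

test_that("config validation rejects impossible architectures", {
  expect_error(cnn_config(conv_blocks = 0), "at least one")
  expect_error(cnn_config(dense_units = integer(0)), "dense")
  # 6 pooling stages shrink 20 rows below 1 -> rejected at build
  cfg <- cnn_config("desk", conv_blocks = 6, pool_blocks = 1:6)
  expect_error(build_cnn(cfg), "cannot pool")
  expect_error(resnet_config(blocks = c(1, 2), filters = 8), "same length")
})

test_that("the CNN stacks conv and dense blocks under a sigmoid head", {
  sc <- build_cnn(cnn_config("desk"))
  types <- vapply(sc$net$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "conv"), 6)
  expect_equal(sum(types == "dense"), 3)       # 2 dense blocks + output unit
  expect_equal(sum(types == "maxpool2"), 3)
  expect_equal(types[length(types)], "dense")  # single output unit
  expect_equal(sc$net$layers[[length(types)]]$dout, 1L)
  expect_gt(sc$n_params, 0)
  # forward pass on one matrix gives one probability
  p <- planted_pair()
  fit <- structure(list(net = sc$net, arch = "cnn"), class = "trained_scorer")
  s <- predict(fit, encode_pair(p$mirna, p$target))
  expect_length(s, 1)
  expect_true(s >= 0 && s <= 1)
})

test_that("the modified ResNet starts with a residual block, not a stem", {
  sc <- build_resnet(resnet_config(blocks = c(1, 1), filters = c(4, 8)))
  types <- vapply(sc$net$layers, `[[`, character(1), "type")
  expect_equal(types[1], "resblock")           # no 7x7 stem, no stem pooling
  expect_false(any(types[1] == "maxpool2"))
  expect_equal(types[length(types)], "dense")
  fit <- structure(list(net = sc$net, arch = "resnet"),
                   class = "trained_scorer")
  s <- predict(fit, array(runif(20 * 50 * 3), c(20, 50, 3)))
  expect_length(s, 3)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("compiled layer kernels match the plain-R reference", {
  ns <- asNamespace("mirsite")
  set.seed(103)
  x <- array(rnorm(20 * 50 * 3 * 4), c(20, 50, 3, 4))
  layer <- ns$init_layer(ns$nn_conv(3, 5, 5, 5))
  f_fast <- ns$conv_forward(layer, x)
  f_ref <- ns$conv_forward_ref(layer, x)
  expect_equal(f_fast$out, f_ref$out, tolerance = 1e-12)
  dout <- array(rnorm(length(f_fast$out)), dim(f_fast$out))
  b_fast <- ns$conv_backward(layer, dout, f_fast$cache)
  b_ref <- ns$conv_backward_ref(layer, dout, f_ref$cache)
  expect_equal(b_fast$dx, b_ref$dx, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(b_fast$grads$W, b_ref$grads$W, tolerance = 1e-12)
  expect_equal(b_fast$grads$b, b_ref$grads$b, tolerance = 1e-12)

  p_fast <- ns$maxpool2_forward(x)
  p_ref <- ns$maxpool2_forward_ref(x)
  expect_equal(p_fast$out, p_ref$out)
  dp <- array(rnorm(length(p_fast$out)), dim(p_fast$out))
  expect_equal(ns$maxpool2_backward(dp, p_fast$cache),
               ns$maxpool2_backward_ref(dp, p_ref$cache),
               ignore_attr = TRUE)

  lay <- ns$nn_lrelu(0.3)
  l_fast <- ns$lrelu_forward(lay, x)
  l_ref <- ns$lrelu_forward_ref(lay, x)
  expect_equal(l_fast$out, l_ref$out)
  expect_equal(ns$lrelu_backward(lay, dp0 <- x * 2, l_fast$cache),
               ns$lrelu_backward_ref(lay, dp0, l_ref$cache))

  bn <- ns$init_layer(ns$nn_bn2d(3))
  bn$params$gamma <- runif(3, 0.5, 2)
  bn$params$beta <- rnorm(3)
  n_fast <- ns$bn2d_forward(bn, x, training = TRUE)
  n_ref <- ns$bn2d_forward_ref(bn, x, training = TRUE)
  expect_equal(n_fast$out, n_ref$out, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(n_fast$run_mean, n_ref$run_mean, tolerance = 1e-12)
  expect_equal(n_fast$run_var, n_ref$run_var, tolerance = 1e-12)
  dbn <- array(rnorm(length(x)), dim(x))
  g_fast <- ns$bn2d_backward(bn, dbn, n_fast$cache)
  g_ref <- ns$bn2d_backward_ref(bn, dbn, n_ref$cache)
  expect_equal(g_fast$dx, g_ref$dx, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(g_fast$grads$gamma, g_ref$grads$gamma, tolerance = 1e-10)
  expect_equal(g_fast$grads$beta, g_ref$grads$beta, tolerance = 1e-10)
})

test_that("backpropagation matches numerical gradients on a tiny net", {
  ns <- asNamespace("mirsite")
  set.seed(107)
  sc <- build_cnn(tiny_cnn(), init_seed = 7)
  net <- sc$net
  x <- array(rnorm(20 * 50 * 1 * 3), c(20, 50, 1, 3))
  y <- c(1, 0, 0.4)
  loss_of <- function(nn) {
    fw <- ns$nn_forward(nn, x, training = TRUE)
    ns$bce_with_logits(as.numeric(fw$out), y)$loss
  }
  fw <- ns$nn_forward(net, x, training = TRUE)
  lo <- ns$bce_with_logits(as.numeric(fw$out), y)
  grads <- ns$nn_backward(fw$net, fw$caches, matrix(lo$dz, nrow = 1))
  eps <- 1e-6
  for (p in ns$param_paths(net)) {
    g <- ns$get_grad(grads, p)
    th <- ns$get_param(net, p)
    for (ii in unique(c(1L, length(th) %/% 2L + 1L, length(th)))) {
      tp <- th; tp[ii] <- tp[ii] + eps
      tm <- th; tm[ii] <- tm[ii] - eps
      num <- (loss_of(ns$set_param(net, p, tp)) -
                loss_of(ns$set_param(net, p, tm))) / (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-4,
                   info = paste(p, collapse = "."))
    }
  }
})

test_that("a separable toy set is overfit to near-zero loss", {
  set.seed(109)
  pos <- make_pairs(rep(strrep("A", 20), 5), rep(strrep("U", 50), 5),
                    labels = 1)
  neg <- make_pairs(rep(strrep("A", 20), 5), rep(strrep("C", 50), 5),
                    labels = 0)
  toy <- rbind(pos, neg)
  full <- cnn_config("desk", conv_blocks = 2, filters = c(4, 4),
                     kernel = c(3, 3), pool_blocks = 1:2, dense_units = 8,
                     dropout_rate = 0, batch_size = 10)
  fit <- train_scorer(build_cnn(full), toy, seed = 2, epochs = 200)
  expect_lt(tail(fit$history$train_loss, 1), 0.01)
  # and the two inputs are cleanly separated
  s <- predict(fit, toy)
  expect_true(all(s[toy$label == 1] > 0.9))
  expect_true(all(s[toy$label == 0] < 0.1))
})

test_that("training is exactly reproducible under a seed", {
  set.seed(113)
  ds <- gen_dataset(synth_spec(n_pos = 60, rng_seed = 5), k = 1)
  val <- gen_dataset(synth_spec(n_pos = 30, rng_seed = 6), k = 1)
  f1 <- train_scorer(build_cnn(tiny_cnn()), ds, val, seed = 11)
  f2 <- train_scorer(build_cnn(tiny_cnn()), ds, val, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- train_scorer(build_cnn(tiny_cnn()), ds, val, seed = 12)
  expect_false(identical(f3$history$train_loss, f1$history$train_loss))
})

test_that("batched and unbatched inference agree to 1e-6", {
  set.seed(127)
  ds <- gen_dataset(synth_spec(n_pos = 50, rng_seed = 7), k = 1)
  fit <- train_scorer(build_cnn(tiny_cnn()), ds, seed = 3, epochs = 2)
  pairs <- gen_dataset(synth_spec(n_pos = 100, rng_seed = 8), k = 1)
  s1 <- predict(fit, pairs, batch_size = 1)
  s256 <- predict(fit, pairs, batch_size = 256)
  expect_lt(max(abs(s1 - s256)), 1e-6)
  # order preserving, duplicates identical, empty in -> empty out
  expect_equal(s256[1], predict(fit, pairs[1, ]), tolerance = 1e-12)
  dup <- predict(fit, pairs[c(1, 1), ])
  expect_identical(dup[1], dup[2])
  expect_length(predict(fit, pairs[0, ]), 0)
})

test_that("training on constant labels converges to that constant", {
  set.seed(131)
  ds <- gen_dataset(synth_spec(n_pos = 100, rng_seed = 9), k = 1)
  ds$label <- 0.35
  fit <- train_scorer(build_cnn(tiny_cnn()), ds, seed = 4, epochs = 30)
  s <- predict(fit, ds)
  expect_equal(mean(s), 0.35, tolerance = 0.05)
})

test_that("scorer S3 surface prints, summarizes and plots", {
  set.seed(137)
  ds <- gen_dataset(synth_spec(n_pos = 40, rng_seed = 10), k = 1)
  fit <- train_scorer(build_cnn(tiny_cnn()), ds, seed = 1, epochs = 2)
  expect_output(print(fit), "CNN scorer")
  expect_output(h <- summary(fit), "parameters")
  expect_s3_class(h, "data.frame")
  expect_true(length(coef(fit)) > 4)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  expect_error(train_scorer(build_cnn(tiny_cnn()), ds[0, ]), "empty")
  bad <- ds
  bad$label[1] <- 0.7
  expect_error(train_scorer(build_cnn(tiny_cnn()), bad), "0.5")
})
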