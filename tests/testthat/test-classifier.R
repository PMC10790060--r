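test_that("full-scale architecture matches the reference layer stack", {
  spec <- cnn_spec(c(91, 109, 91), profile = "full")
  audit <- cnn_audit(spec)
  convs <- audit[audit$type == "conv", ]
  expect_identical(convs$units, c(32L, 64L, 128L))
  expect_identical(convs$kernel, c(3L, 3L, 2L))
  pools <- audit[audit$type %in% c("avgpool", "maxpool"), ]
  expect_identical(pools$kernel, c(2L, 2L, 2L))
  expect_identical(sum(audit$type == "maxpool"), 2L)
  expect_identical(sum(audit$type == "batchnorm"), 2L)
  dense <- audit[audit$type == "dense", ]
  expect_identical(dense$units, c(500L, 500L, 500L, 2L))
  expect_identical(audit$type[nrow(audit)], "softmax")
  # layer order: avgpool, conv, relu, maxpool, bn, conv, relu, maxpool, bn,
  # conv, relu, flatten, dense...
  expect_identical(audit$type[1:11],
                   c("avgpool", "conv", "relu", "maxpool", "batchnorm",
                     "conv", "relu", "maxpool", "batchnorm", "conv", "relu"))
})

test_that("too-small inputs raise an architecture error naming the layer", {
  expect_error(cnn_spec(c(2, 2, 2), profile = "full"), "conv|avgpool")
  expect_error(cnn_spec(c(24, 24, 24), profile = "full"), "conv3")
  # the reduced profile fits a 24^3 toy volume
  expect_s3_class(cnn_spec(c(24, 24, 24), profile = "reduced"), "cnn_spec")
})

test_that("softmax output is a probability pair and inference is deterministic", {
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  fit <- blob_volumes(4, dims = c(14, 14, 14), seed = 1)
  model <- train_cnn(spec, fit$volumes, fit$labels, fit$volumes, fit$labels,
                     train_hyper(max_epochs = 2, batch_size = 4, seed = 1,
                                 early_stop_patience = 2))
  probs <- predict(model, fit$volumes)
  expect_identical(dim(probs), c(8L, 2L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-6)
  # duplicated input gives identical probability pairs
  dup <- predict(model, fit$volumes[c(1, 1)])
  expect_identical(dup[1, ], dup[2, ])
  expect_error(predict(model, list(array(0, c(5, 5, 5)))), "extents")
})

test_that("training overfits separable toy volumes and is seed-reproducible", {
  spec <- cnn_spec(c(16, 16, 16), profile = "reduced")
  fit <- blob_volumes(10, seed = 2)
  hyper <- train_hyper(max_epochs = 60, batch_size = 8,
                       early_stop_patience = 20, seed = 7)
  model <- train_cnn(spec, fit$volumes, fit$labels, fit$volumes, fit$labels,
                     hyper)
  pred <- predicted_labels(predict(model, fit$volumes))
  expect_equal(mean(pred == fit$labels), 1.0)
  model2 <- train_cnn(spec, fit$volumes, fit$labels, fit$volumes, fit$labels,
                      hyper)
  expect_equal(min(model$history$val_loss), min(model2$history$val_loss),
               tolerance = 1e-6)
  expect_identical(model$best_epoch, model2$best_epoch)
})

test_that("early stopping halts after patience epochs without improvement", {
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  # shuffled labels: validation loss cannot improve systematically
  set.seed(3)
  fit <- blob_volumes(6, dims = c(14, 14, 14), seed = 3)
  hyper <- train_hyper(max_epochs = 200, batch_size = 12,
                       early_stop_patience = 5, seed = 3)
  model <- train_cnn(spec, fit$volumes, fit$labels,
                     fit$volumes, sample(fit$labels), hyper)
  expect_lte(nrow(model$history), 200)
  expect_identical(nrow(model$history), model$best_epoch + 5L)
  expect_lte(model$best_epoch, nrow(model$history))
})

test_that("training on shuffled labels stays at chance on held-out data", {
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  correct <- 0L
  total <- 0L
  for (rep in 1:20) {
    set.seed(300 + rep)
    fit <- blob_volumes(6, dims = c(14, 14, 14), seed = 300 + rep)
    perm <- sample(12)
    train_idx <- perm[1:8]
    val_idx <- perm[9:12]
    y_shuf <- sample(fit$labels)
    model <- train_cnn(spec, fit$volumes[train_idx], y_shuf[train_idx],
                       fit$volumes[val_idx], y_shuf[val_idx],
                       train_hyper(max_epochs = 10, batch_size = 8,
                                   early_stop_patience = 5, seed = rep))
    pred <- predicted_labels(predict(model, fit$volumes[val_idx]))
    correct <- correct + sum(pred == fit$labels[val_idx])
    total <- total + length(val_idx)
  }
  # pooled held-out accuracy within the binomial 95% band around 0.5
  band <- qbinom(c(0.025, 0.975), total, 0.5)
  expect_gte(correct, band[1])
  expect_lte(correct, band[2])
})

test_that("single-class training sets are rejected", {
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  fit <- blob_volumes(3, dims = c(14, 14, 14), seed = 5)
  expect_error(
    train_cnn(spec, fit$volumes[1:3], c(0L, 0L, 0L), fit$volumes, fit$labels,
              train_hyper(seed = 1)),
    "both classes")
})

test_that("analytic gradients match finite differences through every layer type", {
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  set.seed(5)
  x <- matrix(rnorm(14^3 * 4), ncol = 4)
  y <- c(0L, 1L, 0L, 1L)
  onehot <- matrix(0, 4, 2)
  onehot[cbind(1:4, y + 1)] <- 1
  w <- csefc:::.init_weights(spec)
  fw <- csefc:::.cnn_forward(spec, w, x, training = TRUE)
  gr <- csefc:::.cnn_backward(spec, w, fw$caches, fw$probs, onehot)
  loss_at <- function(w) {
    f <- csefc:::.cnn_forward(spec, w, x, training = TRUE)
    csefc:::.mean_ce_loss(f$probs, y)
  }
  eps <- 1e-5
  for (nm in c("conv1", "conv2", "conv3", "fc1", "fc4", "bn1", "bn2")) {
    par <- if (grepl("bn", nm)) "gamma" else "W"
    for (i in sample(length(w[[nm]][[par]]), 2)) {
      wp <- w; wp[[nm]][[par]][i] <- wp[[nm]][[par]][i] + eps
      wm <- w; wm[[nm]][[par]][i] <- wm[[nm]][[par]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(gr[[nm]][[par]][i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})
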