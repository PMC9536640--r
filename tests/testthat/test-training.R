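test_that("the learning-rate schedule decays by 0.1 every 10 epochs", {
  h <- train_hyper()
  expect_equal(lr_at_epoch(h, 0), 0.001)
  expect_equal(lr_at_epoch(h, 9), 0.001)
  expect_equal(lr_at_epoch(h, 10), 0.0001)
  expect_equal(lr_at_epoch(h, 25), 0.00001)
  expect_error(lr_at_epoch(h, -1), "non-negative")
})

test_that("hyperparameters default to the study recipe and override via YAML", {
  h <- train_hyper()
  expect_equal(h$classes, 13L)
  expect_equal(h$batch_size, 32L)
  expect_equal(h$epochs, 50L)
  expect_equal(h$momentum, 0.9)
  expect_equal(h$lr, 0.001)
  expect_equal(h$input_side, 224L)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(epochs = 5, lr = 0.01, input_side = 48), f)
  h2 <- read_train_hyper(f)
  expect_equal(h2$epochs, 5L)
  expect_equal(h2$lr, 0.01)
  expect_equal(h2$batch_size, 32L)   # untouched fields keep the recipe
})

test_that("Xavier initialization bounds weights, zeroes biases, and is seed-reproducible", {
  m <- assemble_model(tiny_config())
  initialize_weights(m, seed = 11)
  refs <- nn_parameters(m)
  for (nm in names(refs)) {
    r <- refs[[nm]]
    w <- r$env[[r$field]]
    if (r$field %in% c("bias", "beta")) {
      expect_true(all(w == 0))
    } else if (r$field == "gamma") {
      expect_true(all(w == 1))
    } else {
      d <- dim(w)
      fans <- if (length(d) == 4) c(prod(d[1:3]), d[1] * d[2] * d[4])
              else c(d[2], d[1])
      a <- sqrt(6 / sum(fans))
      expect_true(all(abs(w) <= a))
      expect_gt(stats::sd(w), 0)
    }
  }
  p1 <- ghostherd:::snapshot_params(m)
  m2 <- assemble_model(tiny_config())
  initialize_weights(m2, seed = 11)
  p2 <- ghostherd:::snapshot_params(m2)
  expect_identical(unclass(p1)[names(p1)], unclass(p2)[names(p2)])
  initialize_weights(m2, seed = 12)
  expect_false(identical(ghostherd:::snapshot_params(m2)[["fc.weight"]],
                         p1[["fc.weight"]]))
})

test_that("zero epochs yield an empty history and a checkpoint equal to initialization", {
  m <- assemble_model(tiny_config())
  x <- array(runif(32 * 32 * 3 * 12), c(32, 32, 3, 12))
  y <- rep(1:4, 3)
  run <- fit_model(m, list(x = x, y = y), val = NULL,
                   hyper = train_hyper(classes = 5, epochs = 0,
                                       input_side = 32), seed = 21)
  expect_equal(nrow(run$history), 0)
  m0 <- assemble_model(tiny_config())
  initialize_weights(m0, seed = 21)
  expect_equal(run$best$params[["fc.weight"]],
               ghostherd:::snapshot_params(m0)[["fc.weight"]])
})

test_that("loss strictly decreases over the first training steps on one repeated batch", {
  set.seed(5)
  m <- assemble_model(tiny_config())
  img <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  x <- array(rep(img, 8), c(32, 32, 3, 8))
  y <- rep(2L, 8)
  initialize_weights(m, seed = 9)
  refs <- nn_parameters(m)
  state <- list()
  losses <- numeric(5)
  for (i in 1:5) {
    nn_zero_grad(m)
    l <- ghostherd:::softmax_xent(nn_forward(m, x, training = TRUE), y)
    losses[i] <- l$loss
    nn_backward(m, l$grad)
    # plain gradient descent with a small step: an identical-image batch has
    # zero batch variance, so normalization amplifies gradients sharply and
    # monotone descent holds only in the small-step regime
    state <- ghostherd:::sgd_step(refs, state, 1e-6, 0)
  }
  expect_true(all(diff(losses) < 0))
})

test_that("training is reproducible end to end for a fixed seed", {
  x <- array(runif(32 * 32 * 3 * 20), c(32, 32, 3, 20))
  y <- rep(1:5, 4)
  h <- train_hyper(classes = 5, epochs = 2, input_side = 32, batch_size = 8)
  r1 <- fit_model(assemble_model(tiny_config()), list(x = x, y = y),
                  val = list(x = x, y = y), h, seed = 33)
  r2 <- fit_model(assemble_model(tiny_config()), list(x = x, y = y),
                  val = list(x = x, y = y), h, seed = 33)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
  expect_identical(r1$best$params[["fc.weight"]], r2$best$params[["fc.weight"]])
})

test_that("evaluation reports exact accuracy and a conserving confusion table", {
  m <- assemble_model(tiny_config())
  initialize_weights(m, 3)
  x <- array(runif(32 * 32 * 3 * 15), c(32, 32, 3, 15))
  y <- rep(1:5, 3)
  res <- ghostherd:::evaluate_arrays(m, list(x = x, y = y))
  expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  expect_equal(sum(res$confusion), 15)
  expect_equal(unname(rowSums(res$confusion)), rep(3, 5))
  # forced-correct predictions give accuracy 1
  res2 <- list(accuracy = mean(y == y))
  expect_equal(res2$accuracy, 1)
  expect_error(ghostherd:::evaluate_arrays(m, list(x = x[, , , 0, drop = FALSE],
                                                   y = integer())), "empty")
})

test_that("a uniform random classifier scores near 1/13 on a balanced set", {
  # analytic expectation with a binomial confidence band
  set.seed(77)
  n <- 13 * 400
  y <- rep(1:13, 400)
  pred <- sample(1:13, n, replace = TRUE)
  acc <- mean(pred == y)
  ci <- 1 / 13 + c(-4, 4) * sqrt((1 / 13) * (12 / 13) / n)
  expect_gt(acc, ci[1])
  expect_lt(acc, ci[2])
})

test_that("checkpoints round-trip and refuse mismatched architectures", {
  m <- assemble_model(tiny_config())
  initialize_weights(m, 8)
  ck <- make_checkpoint(m, classes = letters[1:5])
  f <- tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  back <- load_checkpoint(f)
  m2 <- assemble_model(tiny_config())
  restore_params(m2, back$params)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_identical(nn_forward(m, x), nn_forward(m2, x))
  wrong <- assemble_model(model_config(num_classes = 3,
                                       stage_widths = c(4, 4, 8),
                                       ghost_counts = c(0, 0, 0),
                                       cbam_reduction = 4, input_side = 32))
  expect_error(restore_params(wrong, back$params), "does not match")
})
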