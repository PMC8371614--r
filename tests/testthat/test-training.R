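test_that("Dice loss matches hand-worked cases and rejects bad input", {
  expect_equal(dice_loss(c(1, 1, 0, 1), c(1, 1, 0, 1)), 0)
  expect_equal(dice_loss(c(1, 0), c(0, 1)), 1, tolerance = 1e-6)
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)), 1 / 3, tolerance = 1e-6)
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)  # both empty: smoothed
  expect_error(dice_loss(c(0.5), c(0.5)), "binary")
  expect_error(dice_loss(c(0.5, 0.5), c(1)), "equal length")
  expect_error(dice_loss(c(1.5, 0), c(1, 0)), "0, 1")
})

test_that("Dice loss is symmetric for binary inputs and monotone toward the truth", {
  set.seed(4)
  for (i in 1:5) {
    p <- rbinom(30, 1, 0.4)
    g <- rbinom(30, 1, 0.4)
    expect_equal(dice_loss(p, g), dice_loss(g, p))
  }
  # moving p linearly toward g never increases the loss
  for (i in 1:5) {
    p <- runif(40)
    g <- rbinom(40, 1, 0.3)
    ts <- seq(0, 1, by = 0.1)
    losses <- vapply(ts, function(t) dice_loss(p + t * (g - p), g), 1)
    expect_true(all(diff(losses) <= 1e-12))
  }
})

test_that("Dice gradient matches finite differences", {
  set.seed(9)
  p <- runif(25)
  g <- rbinom(25, 1, 0.4)
  an <- vesselseg:::dice_loss_grad(p, g)
  eps <- 1e-7
  for (k in c(1, 10, 25)) {
    p2 <- p; p2[k] <- p2[k] + eps
    p1 <- p; p1[k] <- p1[k] - eps
    expect_equal(an[k], (dice_loss(p2, g) - dice_loss(p1, g)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("the L2 objective adds exactly lambda times the squared norm", {
  expect_equal(l2_objective(0.4, c(1, 2), 0), 0.4)
  expect_equal(l2_objective(0.4, numeric(3), 5), 0.4)
  expect_equal(l2_objective(0.1, c(3, 4), 0.1), 0.1 + 2.5)
  expect_equal(l2_objective(0.2, list(a = c(1, 1), b = 2), 0.5),
               0.2 + 0.5 * 6)
  expect_error(l2_objective(0.1, 1, -1), ">= 0")
  # objective >= dice, equality iff the penalty term vanishes
  w <- rnorm(10)
  expect_gt(l2_objective(0.3, w, 1e-3), 0.3)
  expect_equal(l2_objective(0.3, w * 0, 1e-3), 0.3)
})

test_that("training runs, logs history, checkpoints, and learns on easy data", {
  fx <- synth_fixture(64, 3)
  plane <- preprocess_pipeline(fx$image)
  ps <- extract_random_patches(plane, fx$mask, patch_config(16, 120, seed = 2),
                               fov = fx$fov)
  net <- network_config(input_size = c(16, 16, 1), widths = c(4, 8), seed = 1)
  first_last <- sapply(1:3, function(s) {
    m <- fit_vesselnet(ps, val_fraction = 0.15,
                       network = network_config(input_size = c(16, 16, 1),
                                                widths = c(4, 8), seed = s),
                       objective = objective_config(epochs = 5, seed = s,
                                                    batch_size = 25))
    expect_true(m$fitted)
    expect_equal(nrow(m$history), 5)
    expect_true(all(c("train_loss", "val_loss", "train_acc", "val_acc") %in%
                      names(m$history)))
    c(m$history$train_loss[1], m$history$train_loss[5])
  })
  # median over seeds: loss at the final epoch is below epoch 1
  expect_lt(median(first_last[2, ]), median(first_last[1, ]))
})

test_that("strong L2 regularisation shrinks the weight norm", {
  fx <- synth_fixture(64, 3)
  ps <- extract_random_patches(preprocess_pipeline(fx$image), fx$mask,
                               patch_config(16, 60, seed = 2), fov = fx$fov)
  run <- function(lambda) {
    m <- fit_vesselnet(ps, val_fraction = 0.2,
                       network = network_config(input_size = c(16, 16, 1),
                                                widths = c(4, 8), seed = 1),
                       objective = objective_config(lambda_l2 = lambda,
                                                    epochs = 4, seed = 1))
    sqrt(vesselseg:::weight_sq_norm(m$final_params))
  }
  expect_lt(run(1e3), run(0))
})

test_that("with L2 the smoothed validation loss trends downward on the benchmark", {
  fx <- synth_fixture(64, 5)
  ps <- extract_random_patches(preprocess_pipeline(fx$image), fx$mask,
                               patch_config(16, 150, seed = 4), fov = fx$fov)
  m <- fit_vesselnet(ps, val_fraction = 0.2,
                     network = network_config(input_size = c(16, 16, 1),
                                              widths = c(4, 8), seed = 2),
                     objective = objective_config(lambda_l2 = 1e-4,
                                                  epochs = 6, seed = 2))
  v <- m$history$val_loss
  smooth3 <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  smooth3 <- smooth3[!is.na(smooth3)]
  expect_lte(smooth3[length(smooth3)], smooth3[1] + 1e-8)
})

test_that("learning-rate decay halves the rate on the configured schedule", {
  fx <- synth_fixture(64, 3)
  ps <- extract_random_patches(preprocess_pipeline(fx$image), fx$mask,
                               patch_config(16, 30, seed = 2))
  m <- fit_vesselnet(ps, val_fraction = 0.2,
                     network = network_config(input_size = c(16, 16, 1),
                                              widths = c(4, 8), seed = 1),
                     objective = objective_config(epochs = 7, seed = 1,
                                                  learning_step = 3))
  expect_equal(m$history$lr, 0.001 * 0.5^((0:6) %/% 3))
  m2 <- fit_vesselnet(ps, val_fraction = 0.2,
                      network = network_config(input_size = c(16, 16, 1),
                                               widths = c(4, 8), seed = 1),
                      objective = objective_config(epochs = 3, seed = 1,
                                                   lr_decay = FALSE))
  expect_true(all(m2$history$lr == 0.001))
})

test_that("training surfaces configuration errors early", {
  fx <- synth_fixture(64, 3)
  ps <- extract_random_patches(preprocess_pipeline(fx$image), fx$mask,
                               patch_config(16, 10, seed = 1))
  m <- build_model(network_config())  # expects 48x48 input
  expect_error(train_model(m, ps, NULL, objective_config(epochs = 1)),
               "does not match")
  expect_error(objective_config(learning_rate = 0), "positive")
  expect_error(objective_config(batch_size = 0), "batch_size")
})
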