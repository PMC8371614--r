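test_that("unit parameter counts match the closed-form layer arithmetic", {
  expect_identical(conv_unit_params(32, 32), 9248L)
  expect_identical(conv_unit_params(64, 64), 36928L)
  expect_identical(conv_unit_params(128, 128), 147584L)  # 9*128^2 + 128
  expect_identical(conv_unit_params(16, 16), 2320L)
  # BN over 128 channels tracks 4 per-channel quantities
  expect_identical(conv_unit_params(128, 128, bn = TRUE) -
                     conv_unit_params(128, 128), 512L)
})

test_that("the full model hits the published total and the breakdown conserves it", {
  m <- build_model(network_config())
  expect_identical(count_parameters(m), 370817L)
  bd <- count_parameters(m, by_block = TRUE)
  expect_identical(as.integer(sum(bd)), 370817L)
  # parameter count is a pure function of the configuration
  expect_identical(count_parameters(build_model(network_config())),
                   count_parameters(build_model(network_config(seed = 99))))
  expect_identical(count_parameters(structure(list(params = list()),
                                              class = "vesselnet")), 0L)
})

test_that("the plain U-Net variant matches a first-principles parameter total", {
  m <- build_model(network_config(variant = "unet"))
  conv_bn <- function(ci, co) 9 * ci * co + co + 4 * co
  tconv <- function(ci, co) 4 * ci * co + co
  expected <- conv_bn(1, 16) + conv_bn(16, 32) + conv_bn(32, 64) +
    conv_bn(64, 128) +                      # encoder
    conv_bn(128, 128) +                     # bridge
    tconv(128, 64) + conv_bn(64, 64) +
    tconv(64, 32) + conv_bn(32, 32) +
    tconv(32, 16) + conv_bn(16, 16) +       # decoder
    16 + 1                                  # 1x1 head
  expect_identical(count_parameters(m), as.integer(expected))
})

test_that("recurrence shares weights: parameter count is independent of t", {
  counts <- vapply(1:4, function(t)
    count_parameters(build_model(network_config(recurrence_steps = t))), 1L)
  expect_true(all(counts == counts[1]))
})

test_that("one recurrence step reduces to the plain conv+BN+ReLU block", {
  # identical seeds give identical weights; with t = 1 the recurrent variant
  # must match the plain variant exactly
  x <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  cfg_r <- network_config(input_size = c(16, 16, 1), widths = c(4, 8),
                          recurrence_steps = 1, variant = "recurrent",
                          seed = 5)
  cfg_u <- network_config(input_size = c(16, 16, 1), widths = c(4, 8),
                          variant = "unet", seed = 5)
  pr <- vesselseg:::net_forward(build_model(cfg_r)$params, cfg_r, x)$prob
  pu <- vesselseg:::net_forward(build_model(cfg_u)$params, cfg_u, x)$prob
  expect_identical(pr, pu)
})

test_that("SE gates lie in (0,1), preserve zero input, and respect channel symmetry", {
  x <- array(runif(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  w1 <- matrix(rnorm(4 * 2), 4, 2)
  w2 <- matrix(rnorm(2 * 4), 2, 4)
  se <- vesselseg:::se_fwd(x, w1, w2)
  expect_true(all(se$s > 0 & se$s < 1))
  expect_identical(dim(se$y), dim(x))

  zeros <- array(0, dim(x))
  expect_true(all(vesselseg:::se_fwd(zeros, w1, w2)$y == 0))

  # identical channel content + tied weights -> identical gates
  xs <- x
  xs[, , 2, ] <- xs[, , 1, ]
  w1t <- w1; w1t[2, ] <- w1t[1, ]
  w2t <- w2; w2t[, 2] <- w2t[, 1]
  gates <- vesselseg:::se_fwd(xs, w1t, w2t)$s
  expect_equal(gates[1, ], gates[2, ])
})

test_that("residual skips pass the (projected) input through a dead branch", {
  cfg <- tiny_net_config()
  m <- build_model(cfg)
  # kill the conv branch of encoder block 1: BN scale and offset at zero
  m$params[["enc1.bn_gamma"]][] <- 0
  m$params[["enc1.bn_beta"]][] <- 0
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  fw <- vesselseg:::net_forward(m$params, cfg, x)
  blk <- vesselseg:::block_plan(cfg)[[1]]
  proj <- vesselseg:::conv_fwd(x, m$params[["enc1.proj_w"]], numeric(4), 1L)
  proj[proj < 0] <- 0
  expect_equal(fw$caches$enc1$out, proj, tolerance = 1e-12)
})

test_that("gradients flow through the residual skip when the branch saturates", {
  cfg <- tiny_net_config()
  m <- build_model(cfg)
  # saturate the first block's ReLUs: large negative BN offset kills o_t
  P <- m$params
  P[["enc1.bn_beta"]][] <- -50
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  g <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  fw <- vesselseg:::net_forward(P, cfg, x, training = TRUE)
  gp <- vesselseg:::dice_loss_grad(fw$prob, g)
  dim(gp) <- dim(fw$prob)
  grads <- vesselseg:::net_backward(P, cfg, fw$caches, gp)
  # branch conv receives (next to) nothing, yet the projection that carries
  # the skip still gets gradient signal
  expect_gt(sum(abs(grads[["enc1.proj_w"]])), 0)
  # finite-difference agreement on a projection weight through the skip path
  k <- which.max(abs(grads[["enc1.proj_w"]]))
  eps <- 1e-6
  P2 <- P; P2[["enc1.proj_w"]][k] <- P2[["enc1.proj_w"]][k] + eps
  l2 <- dice_loss(vesselseg:::net_forward(P2, cfg, x, TRUE)$prob, g)
  P2[["enc1.proj_w"]][k] <- P2[["enc1.proj_w"]][k] - 2 * eps
  l1 <- dice_loss(vesselseg:::net_forward(P2, cfg, x, TRUE)$prob, g)
  expect_equal((l2 - l1) / (2 * eps), grads[["enc1.proj_w"]][k],
               tolerance = 1e-4)
})

test_that("the assembled network has the documented stage geometry", {
  cfg <- network_config()
  m <- build_model(cfg)
  x <- array(runif(48 * 48 * 2), c(48, 48, 1, 2))
  fw <- vesselseg:::net_forward(m$params, cfg, x)
  expect_identical(dim(fw$caches$enc1$out), c(48L, 48L, 16L, 2L))
  expect_identical(dim(fw$caches$enc2$out), c(24L, 24L, 32L, 2L))
  expect_identical(dim(fw$caches$enc3$out), c(12L, 12L, 64L, 2L))
  expect_identical(dim(fw$caches$enc4$out), c(6L, 6L, 128L, 2L))
  expect_identical(dim(fw$caches$bridge$out), c(6L, 6L, 128L, 2L))
  expect_identical(dim(fw$prob), dim(x))
  # sigmoid head keeps probabilities strictly inside (0, 1), even for zeros
  pz <- vesselseg:::net_forward(m$params, cfg, array(0, c(48, 48, 1, 1)))$prob
  expect_true(all(pz > 0 & pz < 1))

  expect_error(network_config(input_size = c(50, 50, 1)), "divisible")
  expect_error(network_config(recurrence_steps = 0), "recurrence_steps")
  expect_error(network_config(se_reduction = 5), "divide")
  expect_error(network_config(widths = c(16, 8)), "increasing")
})

test_that("analytic gradients agree with finite differences across all blocks", {
  set.seed(11)
  cfg <- tiny_net_config()
  m <- build_model(cfg)
  P <- m$params
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  g <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  fw <- vesselseg:::net_forward(P, cfg, x, training = TRUE)
  gp <- vesselseg:::dice_loss_grad(fw$prob, g)
  dim(gp) <- dim(fw$prob)
  grads <- vesselseg:::net_backward(P, cfg, fw$caches, gp)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (k in sample(length(P[[nm]]), min(2, length(P[[nm]])))) {
      P2 <- P
      P2[[nm]][k] <- P2[[nm]][k] + eps
      l2 <- dice_loss(vesselseg:::net_forward(P2, cfg, x, TRUE)$prob, g)
      P2[[nm]][k] <- P2[[nm]][k] - 2 * eps
      l1 <- dice_loss(vesselseg:::net_forward(P2, cfg, x, TRUE)$prob, g)
      fd <- (l2 - l1) / (2 * eps)
      expect_equal(grads[[nm]][k], fd, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("a single encoder block is translation covariant away from borders", {
  cfg <- tiny_net_config(variant = "unet", t = 1)
  m <- build_model(cfg)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  xs <- x
  xs[2:16, , , ] <- x[1:15, , , ]   # shift down one pixel
  blk <- vesselseg:::block_plan(cfg)[[1]]
  fl <- vesselseg:::variant_flags(cfg$variant)
  o1 <- vesselseg:::block_fwd(m$params, "enc1", x, blk, fl, 1L, FALSE)$out
  o2 <- vesselseg:::block_fwd(m$params, "enc1", xs, blk, fl, 1L, FALSE)$out
  expect_equal(o2[4:15, 3:14, , , drop = FALSE],
               o1[3:14, 3:14, , , drop = FALSE], tolerance = 1e-10)
})

test_that("layer summary mirrors the architecture and checkpoints round-trip", {
  m <- build_model(network_config())
  tab <- layer_table(m)
  expect_identical(attr(tab, "total"), 370817L)
  expect_identical(sum(tab$params), 370817L)
  expect_true(any(grepl("\\(6, 6, 128\\)", tab$output_size)))
  out <- capture.output(summary(m))
  expect_true(any(grepl("370,817", out)))

  d <- file.path(tempdir(), "ckpt")
  save_model(m, d)
  back <- load_model(d)
  x <- array(runif(48 * 48), c(48, 48, 1, 1))
  expect_equal(vesselseg:::net_predict(back, x),
               vesselseg:::net_predict(m, x), tolerance = 1e-15)
  unlink(d, recursive = TRUE)
})
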