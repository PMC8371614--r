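# Layer primitives for the segmentation network. Feature maps are numeric
# arrays dim = c(H, W, C, N); elementwise hot paths are fused C++ kernels and
# every backward pass is checked against finite differences in the tests.

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}
relu_bwd <- function(gy, y) gy * (y > 0)

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

conv_fwd <- function(x, w, b, k) cpp_conv_fwd(x, w, b, k)
conv_bwd <- function(x, w, gy, k) cpp_conv_bwd(x, w, gy, k)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- batch norm + ReLU (fused) --------------------------------------------

# returns activation, the per-channel batch stats actually used, and updated
# running statistics
bnrelu_fwd <- function(s, gamma, beta, rmean, rvar, training) {
  d <- dim(s)
  if (training) {
    m <- d[1] * d[2] * d[4]
    st <- cpp_cn_sums2(s)
    mu <- rowSums(matrix(st[1, ], d[3])) / m
    va <- pmax(rowSums(matrix(st[2, ], d[3])) / m - mu^2, 0)
    rmean <- BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mu
    rvar <- BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * va
  } else {
    mu <- rmean
    va <- rvar
  }
  invsd <- 1 / sqrt(va + BN_EPS)
  a <- gamma * invsd
  o <- cpp_bnrelu_fwd(s, a, beta - mu * a)
  list(o = o, mu = mu, invsd = invsd, rmean = rmean, rvar = rvar)
}

# ---- squeeze-and-excitation gate ------------------------------------------

# w1: C x Ch, w2: Ch x C (both bias-free)
se_fwd <- function(x, w1, w2) {
  d <- dim(x)
  gap <- cpp_cn_sums(x) / (d[1] * d[2])       # C x N
  h <- crossprod(w1, gap)                     # Ch x N
  h[h < 0] <- 0
  s <- 1 / (1 + exp(-crossprod(w2, h)))       # C x N gates in (0,1)
  list(y = cpp_scale_cn(x, s), gap = gap, h = h, s = s)
}

se_bwd <- function(gy, x, w1, w2, cache) {
  d <- dim(x)
  hw <- d[1] * d[2]
  gs <- cpp_dot_cn(gy, x)                     # C x N
  gz2 <- gs * cache$s * (1 - cache$s)
  gw2 <- cache$h %*% t(gz2)                   # Ch x C
  gh <- w2 %*% gz2
  gz1 <- gh * (cache$h > 0)
  gw1 <- cache$gap %*% t(gz1)                 # C x Ch
  ggap <- w1 %*% gz1                          # C x N
  gx <- cpp_add_cn(cpp_scale_cn(gy, cache$s), ggap / hw)
  list(gx = gx, gw1 = gw1, gw2 = gw2)
}

# ---- 2x nearest upsampling (parameter-free alternative to transposed conv) -

nearest_up_fwd <- function(x) {
  d <- dim(x)
  idx <- rep(seq_len(d[1]), each = 2)
  jdx <- rep(seq_len(d[2]), each = 2)
  x[idx, jdx, , , drop = FALSE]
}

nearest_up_bwd <- function(gy) {
  d <- dim(gy)
  g <- gy[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    gy[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    gy[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    gy[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
  dim(g) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  g
}

# ---- Adam optimiser --------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
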