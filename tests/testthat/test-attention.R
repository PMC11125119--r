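rand_fmap <- function(c, h, w, seed = 1) {
  set.seed(seed)
  array(rnorm(c * h * w), dim = c(h, w, c))
}

test_that("channel attention with zero MLP halves the input exactly", {
  x <- rand_fmap(8, 4, 4)
  cfg <- channel_attention_config(8, reduction = 2,
                                  mlp1 = matrix(0, 4, 8),
                                  mlp2 = matrix(0, 8, 4))
  expect_equal(channel_attention(x, cfg), 0.5 * x)
})

test_that("channel attention preserves shape and keeps weights in (0,1)", {
  for (d in list(c(8, 4, 4), c(64, 16, 16))) {
    x <- rand_fmap(d[1], d[2], d[3], seed = d[1])
    cfg <- channel_attention_config(d[1], reduction = min(16, d[1] / 2))
    y <- channel_attention(x, cfg)
    expect_equal(dim(y), dim(x))
    w <- feedscan:::channel_attention_weights(x, cfg)
    expect_true(all(w > 0 & w < 1))
  }
  expect_error(channel_attention_config(8, reduction = 16), "reduction")
})

test_that("channel attention matches scalar hand computation on a 2-channel toy", {
  # 2 channels, 2x2 each; squeeze to width 1 with unit weights
  x <- array(0, dim = c(2, 2, 2))
  x[, , 1] <- matrix(c(1, 2, 3, 4), 2)      # mean 2.5, max 4
  x[, , 2] <- matrix(c(0, 0, 0, 8), 2)      # mean 2,   max 8
  m1 <- matrix(c(1, 1), 1, 2)               # hidden = ch1 + ch2
  m2 <- matrix(c(1, -1), 2, 1)              # out = (hidden, -hidden)
  cfg <- channel_attention_config(2, reduction = 2, mlp1 = m1, mlp2 = m2)
  # avg path: hidden 4.5 -> (4.5, -4.5); max path: hidden 12 -> (12, -12)
  s <- 1 / (1 + exp(-c(16.5, -16.5)))
  y <- channel_attention(x, cfg)
  expect_equal(y[, , 1], x[, , 1] * s[1], tolerance = 1e-12)
  expect_equal(y[, , 2], x[, , 2] * s[2], tolerance = 1e-12)
})

test_that("spatial attention gates with a 7x7-convolved mean/max map", {
  x <- rand_fmap(6, 5, 5)
  zero_conv <- feedscan:::new_conv(2L, 1L, 7L)
  zero_conv$w[] <- 0; zero_conv$b[] <- 0
  expect_equal(spatial_attention(x, zero_conv), 0.5 * x)

  # spatially constant input gives a constant map wherever the 7x7 window
  # sits fully inside (zero padding breaks constancy only at the border)
  const <- array(2, dim = c(16, 16, 3))
  set.seed(12)
  m <- feedscan:::spatial_attention_map(const, feedscan:::new_spatial_attention())
  interior <- m[4:13, 4:13]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-12)

  # 1-channel 3x3 input, kernel that only reads the centre of the mean map
  x1 <- array(c(1, 2, 3, 4, 5, 6, 7, 8, 9), dim = c(3, 3, 1))
  k <- array(0, dim = c(7, 7, 2, 1)); k[4, 4, 1, 1] <- 1
  conv <- feedscan:::new_conv(2L, 1L, 7L)
  conv$w <- conv_weight_matrix(k); conv$b[] <- 0
  y <- spatial_attention(x1, conv)
  expect_equal(y[, , 1], x1[, , 1] / (1 + exp(-x1[, , 1])), tolerance = 1e-12)
})

test_that("cb_conv with identity gating equals the plain double bottleneck", {
  set.seed(8)
  w <- new_cb_conv(16, reduction = 4)
  x <- rand_fmap(16, 6, 6, seed = 2)
  gated_off <- cb_conv_block(x, w, disable_attention = TRUE)
  manual <- feedscan:::bottleneck_fwd(w$bottleneck2,
                                      feedscan:::bottleneck_fwd(w$bottleneck1, x))
  expect_identical(gated_off, manual)
  for (seed in 1:10) {
    y <- cb_conv_block(rand_fmap(16, 6, 6, seed = seed + 10), w)
    expect_true(all(is.finite(y)))
    expect_equal(dim(y), c(6, 6, 16))
  }
})

test_that("cb_conv parameter count matches the closed-form sum", {
  ch <- 256L
  w <- new_cb_conv(ch, reduction = 16)
  bottleneck_params <- function(cin, cmid, cout) {
    cin * cmid + 2 * cmid +        # 1x1 + bn
      9 * cmid * cmid + 2 * cmid + # 3x3 + bn
      cmid * cout + 2 * cout       # 1x1 + bn
  }
  expected <- 2 * bottleneck_params(ch, ch / 4, ch) +
    2 * ch * (ch / 16) +           # shared two-layer MLP
    (7 * 7 * 2 + 1)                # 7x7 conv on the 2-channel pooled map
  expect_equal(feedscan:::params_count(w), expected)
})

test_that("eca kernel size follows the adaptive formula", {
  expect_identical(eca_kernel_size(256, 2, 1), 5L)
  expect_identical(eca_kernel_size(64, 2, 1), 3L)
  expect_identical(eca_kernel_size(2, 2, 1), 1L)
  expect_error(eca_kernel_size(1), "C >= 2")
  ks <- vapply(2:512, eca_kernel_size, integer(1))
  expect_true(all(ks %% 2 == 1))
  expect_true(all(diff(ks) >= 0))
})

test_that("eca block normalizes channel weights and preserves shape", {
  x <- rand_fmap(16, 5, 5, seed = 3)
  set.seed(5)
  w <- new_eca_conv(16)
  cw <- feedscan:::eca_channel_weights(x, w)
  expect_equal(sum(cw), 1, tolerance = 1e-12)
  y <- eca_conv_block(x, w)
  expect_equal(dim(y), dim(x))
  w0 <- w
  w0$conv1$w[] <- 0; w0$conv1$b[] <- 0
  w0$conv3$w[] <- 0; w0$conv3$b[] <- 0
  expect_equal(eca_conv_block(x, w0), 0 * x)
})

test_that("eca channel interaction matches a manual neighbourhood computation", {
  x <- array(0, dim = c(2, 2, 4))
  for (c in 1:4) x[, , c] <- c          # channel means 1..4
  set.seed(9)
  w <- new_eca_conv(4)                  # k = psi(4) = 1... force k = 3
  w$k <- 3L
  w$kernel$w <- c(0.5, 1, 0.25)         # shared kernel variant
  z_manual <- c(0.5 * 0 + 1 * 1 + 0.25 * 2,
                0.5 * 1 + 1 * 2 + 0.25 * 3,
                0.5 * 2 + 1 * 3 + 0.25 * 4,
                0.5 * 3 + 1 * 4 + 0.25 * 0)
  sm <- exp(z_manual - max(z_manual)); sm <- sm / sum(sm)
  expect_equal(feedscan:::eca_channel_weights(x, w), sm, tolerance = 1e-12)
  # per-channel parameter accounting: k * C kernels by default
  wpc <- new_eca_conv(256)
  expect_equal(length(wpc$kernel$w), eca_kernel_size(256) * 256)
  wsh <- new_eca_conv(256, per_channel = FALSE)
  expect_equal(length(wsh$kernel$w), eca_kernel_size(256))
})
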