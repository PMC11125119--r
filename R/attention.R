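#' Channel attention (squeeze-excite over pooled descriptors)
#'
#' Global average-pooled and global max-pooled channel descriptors pass
#' through a shared two-layer squeeze(1/r)-excite MLP; the two outputs are
#' summed and squashed by the logistic function into per-channel weights in
#' (0, 1) that multiply the input map channel-wise. With all-zero MLP
#' weights every channel weight is exactly 0.5.
#'
#' @param x Feature map, `H x W x C` array.
#' @param cfg A [channel_attention_config()] whose channel count matches
#'   `dim(x)[3]`.
#' @return Array of the same shape as `x`.
#' @export
channel_attention <- function(x, cfg) {
  stopifnot(inherits(cfg, "channel_attention_config"))
  if (dim(x)[3] != cfg$channels) stop("channel count mismatch", call. = FALSE)
  scale_channels(x, channel_attention_weights(x, cfg))
}

channel_attention_weights <- function(x, cfg) {
  mlp <- function(v) drop(cfg$mlp2$w %*% relu(cfg$mlp1$w %*% v))
  sigmoid(mlp(gap_channels(x)) + mlp(gmp_channels(x)))
}

#' @rdname channel_attention
#' @param channels Number of channels `C`.
#' @param reduction Squeeze factor `r >= 1`; the hidden width is
#'   `floor(C / r)` (default 16, the convention of the originating
#'   channel-attention design; the source never states it).
#' @param mlp1,mlp2 Optional weight matrices (`hidden x C` and
#'   `C x hidden`) overriding the random initialization.
#' @export
channel_attention_config <- function(channels, reduction = 16,
                                     mlp1 = NULL, mlp2 = NULL) {
  stopifnot(reduction >= 1)
  hidden <- channels %/% reduction
  if (hidden < 1) stop("channel count smaller than reduction", call. = FALSE)
  if (is.null(mlp1)) mlp1 <- matrix(rnorm(hidden * channels, 0, he_sd(channels)),
                                    hidden, channels)
  if (is.null(mlp2)) mlp2 <- matrix(rnorm(channels * hidden, 0, he_sd(hidden)),
                                    channels, hidden)
  structure(list(channels = channels, reduction = reduction,
                 mlp1 = list(type = "linear", w = mlp1, b = NULL),
                 mlp2 = list(type = "linear", w = mlp2, b = NULL)),
            class = "channel_attention_config")
}

#' Spatial attention
#'
#' The channel-wise mean and max maps are stacked into a 2-channel map,
#' convolved with a 7x7 kernel (padding 3), and squashed by the logistic
#' function into a spatial weight map in (0, 1) that multiplies every
#' channel of the input.
#'
#' @param x Feature map, `H x W x C` array.
#' @param conv Optional 7x7 conv layer (2 in-channels, 1 out-channel); a
#'   random one is drawn when omitted. Build custom kernels with
#'   [conv_weight_matrix()].
#' @return Array of the same shape as `x`.
#' @export
spatial_attention <- function(x, conv = NULL) {
  if (is.null(conv)) conv <- new_spatial_attention()
  scale_spatial(x, spatial_attention_map(x, conv))
}

new_spatial_attention <- function() new_conv(2L, 1L, 7L, bias = TRUE)

spatial_attention_map <- function(x, conv) {
  d <- dim(x)
  pooled <- array(0, dim = c(d[1], d[2], 2))
  pooled[, , 1] <- apply(x, c(1, 2), mean)
  pooled[, , 2] <- apply(x, c(1, 2), max)
  sigmoid(conv_fwd(conv, pooled)[, , 1])
}

scale_spatial <- function(x, map) {
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- x[, , c] * map
  out
}

#' Residual attention block for the backbone (CB_Conv)
#'
#' The backbone's attention block: a residual bottleneck, then channel
#' attention, then spatial attention, then a second residual bottleneck.
#' Each bottleneck keeps its identity skip connection, so forcing both
#' attention weight maps to 1 recovers the plain double-bottleneck output
#' exactly.
#'
#' @param x Feature map, `H x W x C` array.
#' @param weights A [new_cb_conv()] weight set for `C` channels.
#' @param disable_attention If `TRUE`, both attention gates are forced to 1
#'   (identity gating), leaving only the two bottlenecks.
#' @return Array of the same shape as `x`.
#' @export
cb_conv_block <- function(x, weights, disable_attention = FALSE) {
  y <- bottleneck_fwd(weights$bottleneck1, x)
  if (!disable_attention) {
    y <- channel_attention(y, weights$channel)
    y <- spatial_attention(y, weights$spatial)
  }
  bottleneck_fwd(weights$bottleneck2, y)
}

#' @rdname cb_conv_block
#' @param channels Channel count `C` (input and output; the bottleneck mid
#'   width is `C / 4`).
#' @param reduction Channel-attention squeeze factor.
#' @export
new_cb_conv <- function(channels, reduction = 16) {
  list(bottleneck1 = new_bottleneck(channels, channels %/% 4L, channels),
       channel = channel_attention_config(channels, reduction),
       spatial = new_spatial_attention(),
       bottleneck2 = new_bottleneck(channels, channels %/% 4L, channels))
}

# Standard residual bottleneck: 1x1 down, 3x3, 1x1 up (+BN each), identity
# or projected skip.
new_bottleneck <- function(cin, cmid, cout, stride = 1L) {
  list(conv1 = new_conv(cin, cmid, 1L, bias = FALSE), bn1 = new_bn(cmid),
       conv2 = new_conv(cmid, cmid, 3L, stride = stride, bias = FALSE),
       bn2 = new_bn(cmid),
       conv3 = new_conv(cmid, cout, 1L, bias = FALSE), bn3 = new_bn(cout),
       down = if (cin != cout || stride != 1L)
         list(conv = new_conv(cin, cout, 1L, stride = stride, bias = FALSE),
              bn = new_bn(cout)) else NULL)
}

bottleneck_fwd <- function(blk, x) {
  y <- relu(bn_fwd(blk$bn1, conv_fwd(blk$conv1, x)))
  y <- relu(bn_fwd(blk$bn2, conv_fwd(blk$conv2, y)))
  y <- bn_fwd(blk$bn3, conv_fwd(blk$conv3, y))
  skip <- if (is.null(blk$down)) x else
    bn_fwd(blk$down$bn, conv_fwd(blk$down$conv, x))
  relu(y + skip)
}

#' Adaptive kernel size for efficient channel attention
#'
#' `k = psi(C)`: with linear-mapping parameters `r` and `b`,
#' `t = floor(|(log2(C) + b) / r|)` and `k` is `t` bumped to the nearest
#' odd integer from below (`t` if odd, else `t + 1`), never below 1. With
#' the defaults `r = 2`, `b = 1`: `C = 256` gives 5 and `C = 64` gives 3.
#'
#' @param channels Channel count `C >= 2`.
#' @param r,b Linear-mapping parameters (defaults 2 and 1, the
#'   originating-method values; the source never states them).
#' @return Odd integer kernel size `k >= 1`.
#' @export
eca_kernel_size <- function(channels, r = 2, b = 1) {
  if (channels < 2) stop("eca_kernel_size requires C >= 2", call. = FALSE)
  stopifnot(r >= 1, b >= 0)
  t <- floor(abs((log2(channels) + b) / r))
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(k, 1))
}

#' Efficient channel attention block (ECA_Conv)
#'
#' The global-average channel descriptor is convolved along the channel
#' axis with an adaptive-size kernel `k` (each channel mixes with its `k`
#' neighbours), the result is normalized into channel weights — SoftMax
#' over channels by default, with a logistic-gate variant — and the
#' reweighted map is passed through parallel 1x1 and 3x3 convolutions
#' whose outputs are summed. Shape is preserved.
#'
#' @param x Feature map, `H x W x C` array.
#' @param weights A [new_eca_conv()] weight set for `C` channels.
#' @return Array of the same shape as `x`.
#' @export
eca_conv_block <- function(x, weights) {
  w <- eca_channel_weights(x, weights)
  z <- scale_channels(x, w)
  conv_fwd(weights$conv1, z) + conv_fwd(weights$conv3, z)
}

eca_channel_weights <- function(x, weights) {
  y <- gap_channels(x)
  C <- length(y); k <- weights$k; half <- (k - 1L) %/% 2L
  ypad <- c(numeric(half), y, numeric(half))
  z <- numeric(C)
  for (i in seq_len(C)) {
    kern <- if (is.matrix(weights$kernel$w)) weights$kernel$w[i, ]
            else weights$kernel$w
    z[i] <- sum(kern * ypad[i:(i + k - 1L)])
  }
  if (weights$gate == "softmax") softmax(z) else sigmoid(z)
}

#' @rdname eca_conv_block
#' @param channels Channel count `C`.
#' @param r,b Kernel-formula parameters, see [eca_kernel_size()].
#' @param per_channel If `TRUE` (default) each channel has its own
#'   interaction kernel — `k * C` added parameters, honouring the stated
#'   parameter count — otherwise one shared kernel of `k` parameters.
#' @param gate `"softmax"` (channel weights summing to 1, as described) or
#'   `"sigmoid"` (the originating method's logistic gate).
#' @export
new_eca_conv <- function(channels, r = 2, b = 1, per_channel = TRUE,
                         gate = c("softmax", "sigmoid")) {
  gate <- match.arg(gate)
  k <- eca_kernel_size(channels, r, b)
  w <- if (per_channel) matrix(rnorm(channels * k, 0, 1 / sqrt(k)), channels, k)
       else rnorm(k, 0, 1 / sqrt(k))
  list(kernel = list(type = "eca_kernel", w = w), k = k, gate = gate,
       conv1 = new_conv(channels, channels, 1L, bias = TRUE),
       conv3 = new_conv(channels, channels, 3L, bias = TRUE))
}
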