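# Parameterized layers for the segmentation model. Each layer is a tagged
# list; forward functions consume H x W x C arrays ("feature maps"). Weight
# matrices use the flat im2col layout of src/ops.cpp; conv_weight_matrix()
# converts from the natural (kh, kw, cin, cout) array so tests can hand-set
# kernels.

he_sd <- function(fan_in) sqrt(2 / fan_in)

new_conv <- function(cin, cout, k, stride = 1L, pad = k %/% 2L, bias = TRUE,
                     init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- he_sd(cin * k * k)
  w <- matrix(rnorm(cout * cin * k * k, 0, init_sd), cout, cin * k * k)
  list(type = "conv", w = w, b = if (bias) numeric(cout) else NULL,
       kh = k, kw = k, stride = as.integer(stride), pad = as.integer(pad),
       cin = cin, cout = cout)
}

#' Build a convolution weight matrix from a kernel array
#'
#' Converts a `(kh, kw, cin, cout)` kernel array into the flat
#' `cout x (cin*kh*kw)` matrix layout the model's convolution primitive
#' uses, so kernels can be specified in their natural shape.
#'
#' @param arr Numeric array of dimension `c(kh, kw, cin, cout)`.
#' @return Weight matrix.
#' @export
conv_weight_matrix <- function(arr) {
  d <- dim(arr)
  stopifnot(length(d) == 4)
  t(matrix(as.vector(arr), d[1] * d[2] * d[3], d[4]))
}

conv_fwd <- function(layer, x) {
  b <- if (is.null(layer$b)) numeric(layer$cout) else layer$b
  y <- cpp_conv2d(x, layer$w, b, layer$kh, layer$kw, layer$stride, layer$pad)
  array(y, dim = dim(y))
}

conv_bwd <- function(layer, x, gout, need_gx = TRUE) {
  cpp_conv2d_bwd(gout, x, layer$w, layer$kh, layer$kw,
                 layer$stride, layer$pad, need_gx)
}

# Batch norm runs with frozen statistics (inference mode) everywhere, the
# detection-finetuning convention; at initialization it is the identity
# affine. gamma/beta are trainable parameters, mean/var are buffers.
new_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       mean = numeric(c), var = rep(1, c))
}

bn_fwd <- function(layer, x) {
  scale <- layer$gamma / sqrt(layer$var + 1e-5)
  shift <- layer$beta - layer$mean * scale
  sweep(sweep(x, 3, scale, `*`), 3, shift, `+`)
}

new_linear <- function(cin, cout, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- he_sd(cin)
  list(type = "linear", w = matrix(rnorm(cout * cin, 0, init_sd), cout, cin),
       b = numeric(cout), cin = cin, cout = cout)
}

linear_fwd <- function(layer, x) drop(layer$w %*% x + layer$b)

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Channel-wise global pools of an H x W x C map.
gap_channels <- function(x) apply(x, 3, mean)
gmp_channels <- function(x) apply(x, 3, max)

scale_channels <- function(x, s) sweep(x, 3, s, `*`)

# --- parameter counting -----------------------------------------------------

layer_param_count <- function(layer) {
  switch(layer$type,
         conv = length(layer$w) + length(layer$b),
         linear = length(layer$w) + length(layer$b),
         bn = length(layer$gamma) + length(layer$beta),
         eca_kernel = length(layer$w),
         stop("unknown layer type: ", layer$type))
}

# Recursively count trainable parameters in a nested list of layers.
params_count <- function(x) {
  if (is.list(x) && !is.null(x$type)) return(layer_param_count(x))
  if (is.list(x)) return(sum(vapply(x, params_count, numeric(1))))
  0
}

# Apply f(layer, path) to every layer in a nested list, returning the
# modified structure (used by the SGD update).
params_map <- function(x, f, path = character(0)) {
  if (is.list(x) && !is.null(x$type)) return(f(x, path))
  if (is.list(x)) {
    for (i in seq_along(x)) {
      nm <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i]
            else as.character(i)
      x[[i]] <- params_map(x[[i]], f, c(path, nm))
    }
  }
  x
}
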