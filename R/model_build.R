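#' Segmentation model configuration
#'
#' Reference configuration of the boundary-refining instance-segmentation
#' model: a ResNet-50 backbone (optionally with mid-stage channel+spatial
#' attention, CB_Conv), a 5-level feature pyramid neck at 256 channels
#' (optionally with an efficient-channel-attention block, ECA_Conv, on the
#' high-level fused map), a region-proposal network and RoI box head with
#' either GIoU or L1 box regression, and a multi-stage mask branch fed by a
#' semantic fusion module over four neck maps, upsampling progressively
#' (14 -> 28 -> 56 -> 112) with halving stage widths.
#'
#' Variants span the ablation lattice: `baseline_refinemask` (no attention,
#' L1 box loss), `refinemask_cb`, `refinemask_eca`, `refinemask_cb_eca`
#' (attention, still L1), and `refinemask_ceg` (both attention blocks plus
#' GIoU box loss).
#'
#' @param variant One of the five tags above.
#' @param fpn_channels Neck width (default 256).
#' @param cbam_reduction Channel-attention squeeze factor for CB_Conv.
#' @param eca_r,eca_b Kernel-formula parameters of ECA_Conv.
#' @param eca_per_channel Per-channel interaction kernels (`k*C` params) or
#'   one shared kernel.
#' @param eca_gate `"softmax"` or `"sigmoid"` channel gate.
#' @param eca_levels Pyramid levels carrying an ECA_Conv block (default
#'   `"p5"`, the high-level semantic map; `c("p2",...,"p6")` for per-level
#'   placement).
#' @param cb_stages Backbone stages (1–4) carrying mid-stage CB attention.
#' @param semantic_convs,instance_convs,stage_channels Mask-branch widths:
#'   semantic-stack depth, instance-stack depth, and per-refinement-stage
#'   channel widths.
#' @param score_threshold,nms_iou Inference thresholds (the source states
#'   none; defaults 0.3 / 0.5).
#' @param loss_weights Named weights of the composite loss.
#' @return Object of class `feedscan_model_config`.
#' @export
model_config <- function(variant = c("refinemask_ceg", "baseline_refinemask",
                                     "refinemask_cb", "refinemask_eca",
                                     "refinemask_cb_eca"),
                         fpn_channels = 256L, cbam_reduction = 16L,
                         eca_r = 2, eca_b = 1, eca_per_channel = TRUE,
                         eca_gate = "softmax", eca_levels = "p5",
                         cb_stages = 1:4,
                         semantic_convs = 6L, instance_convs = 5L,
                         stage_channels = c(128L, 64L, 32L),
                         score_threshold = 0.3, nms_iou = 0.5,
                         loss_weights = c(rpn_cls = 1, rpn_box = 1,
                                          cls = 1, box = 1,
                                          mask = 1, semantic = 0.5)) {
  if (length(variant) > 1) variant <- variant[1]
  allowed <- c("refinemask_ceg", "baseline_refinemask", "refinemask_cb",
               "refinemask_eca", "refinemask_cb_eca")
  if (!variant %in% allowed) {
    stop("invalid variant '", variant, "'; expected one of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  use_cb <- variant %in% c("refinemask_ceg", "refinemask_cb", "refinemask_cb_eca")
  use_eca <- variant %in% c("refinemask_ceg", "refinemask_eca", "refinemask_cb_eca")
  box_loss <- if (variant == "refinemask_ceg") "giou" else "l1"
  structure(list(variant = variant, use_cb = use_cb, use_eca = use_eca,
                 box_loss = box_loss,
                 fpn_channels = as.integer(fpn_channels),
                 cbam_reduction = as.integer(cbam_reduction),
                 eca_r = eca_r, eca_b = eca_b,
                 eca_per_channel = eca_per_channel, eca_gate = eca_gate,
                 eca_levels = eca_levels, cb_stages = as.integer(cb_stages),
                 semantic_convs = as.integer(semantic_convs),
                 instance_convs = as.integer(instance_convs),
                 stage_channels = as.integer(stage_channels),
                 n_classes = 2L, anchor_ratios = c(0.5, 1, 2),
                 box_roi = 7L, mask_roi = 14L, fc_dim = 1024L,
                 score_threshold = score_threshold, nms_iou = nms_iou,
                 loss_weights = loss_weights),
            class = "feedscan_model_config")
}

resnet50_stages <- function() {
  list(list(blocks = 3L, cmid = 64L, cout = 256L, stride = 1L),
       list(blocks = 4L, cmid = 128L, cout = 512L, stride = 2L),
       list(blocks = 6L, cmid = 256L, cout = 1024L, stride = 2L),
       list(blocks = 3L, cmid = 512L, cout = 2048L, stride = 2L))
}

#' Build the segmentation model
#'
#' Allocates and deterministically initializes all weights of the
#' configured variant. The same config and seed always produce identical
#' weights.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `feedscan_model`.
#' @export
build_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "feedscan_model_config"))
  fc <- config$fpn_channels
  local_seed(seed, {
    stages <- resnet50_stages()
    backbone <- list(stem_conv = new_conv(3L, 64L, 7L, stride = 2L, bias = FALSE),
                     stem_bn = new_bn(64L), layers = list(), cb = list())
    cin <- 64L
    for (s in seq_along(stages)) {
      st <- stages[[s]]
      blocks <- list()
      for (b in seq_len(st$blocks)) {
        blocks[[b]] <- new_bottleneck(if (b == 1L) cin else st$cout, st$cmid,
                                      st$cout,
                                      stride = if (b == 1L) st$stride else 1L)
      }
      backbone$layers[[s]] <- blocks
      cin <- st$cout
      if (config$use_cb && s %in% config$cb_stages) {
        backbone$cb[[s]] <- list(
          channel = channel_attention_config(st$cout, config$cbam_reduction),
          spatial = new_spatial_attention())
      } else backbone$cb[s] <- list(NULL)
    }

    couts <- vapply(stages, function(s) s$cout, integer(1))
    neck <- list(lateral = lapply(couts, function(cc) new_conv(cc, fc, 1L)),
                 output = lapply(1:4, function(i) new_conv(fc, fc, 3L)),
                 eca = list())
    if (config$use_eca) {
      for (lv in config$eca_levels) {
        neck$eca[[lv]] <- new_eca_conv(fc, config$eca_r, config$eca_b,
                                       config$eca_per_channel, config$eca_gate)
      }
    }

    # prediction layers start near zero, the usual detector initialization
    n_anchor <- length(config$anchor_ratios)
    rpn <- list(conv = new_conv(fc, fc, 3L),
                cls = new_conv(fc, n_anchor, 1L, init_sd = 0.01),
                reg = new_conv(fc, 4L * n_anchor, 1L, init_sd = 0.01))

    roi_dim <- fc * config$box_roi^2
    box <- list(fc1 = new_linear(roi_dim, config$fc_dim),
                fc2 = new_linear(config$fc_dim, config$fc_dim),
                cls = new_linear(config$fc_dim, config$n_classes + 1L,
                                 init_sd = 0.01),
                reg = new_linear(config$fc_dim, 4L * config$n_classes,
                                 init_sd = 0.001))

    mask <- list(
      lateral = lapply(1:4, function(i) new_conv(fc, fc, 1L)),
      sem_stack = lapply(seq_len(config$semantic_convs),
                         function(i) new_conv(fc, fc, 3L)),
      sem_logits = new_conv(fc, config$n_classes, 1L, init_sd = 0.01),
      inst_stack = lapply(seq_len(config$instance_convs),
                          function(i) new_conv(fc, fc, 3L)),
      inst_logits = new_conv(fc, config$n_classes, 1L, init_sd = 0.01),
      stages = list())
    prev <- fc
    for (k in seq_along(config$stage_channels)) {
      ck <- config$stage_channels[k]
      mask$stages[[k]] <- list(fuse = new_conv(prev + fc, ck, 1L),
                               conv = new_conv(ck, ck, 3L),
                               logits = new_conv(ck, config$n_classes, 1L, init_sd = 0.01))
      prev <- ck
    }

    structure(list(config = config,
                   params = list(backbone = backbone, neck = neck,
                                 rpn = rpn, box = box, mask = mask)),
              class = "feedscan_model")
  })
}

#' @export
print.feedscan_model <- function(x, ...) {
  cat(sprintf("<feedscan_model '%s': %.2f M parameters>\n",
              x$config$variant, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar (conv and linear weights and biases, batch
#' norm scale/shift, attention MLPs and kernels); batch-norm running
#' statistics are buffers and are not counted.
#'
#' @param model A [build_model()] result.
#' @param units `"M"` (millions, default) or `"raw"`.
#' @return Scalar count.
#' @export
count_parameters <- function(model, units = c("M", "raw")) {
  units <- match.arg(units)
  n <- params_count(model$params)
  if (units == "M") n / 1e6 else n
}

#' @rdname count_parameters
#' @return `parameter_breakdown()`: named numeric of raw per-module counts
#'   (`backbone`, `neck`, `rpn`, `box`, `mask`), summing to the total.
#' @export
parameter_breakdown <- function(model) {
  vapply(model$params, params_count, numeric(1))
}

# --- backbone + neck forward ------------------------------------------------

backbone_stage_fwd <- function(blocks, cb, x) {
  mid <- max(1L, length(blocks) %/% 2L)
  for (b in seq_along(blocks)) {
    x <- bottleneck_fwd(blocks[[b]], x)
    if (b == mid && !is.null(cb)) {
      x <- channel_attention(x, cb$channel)
      x <- spatial_attention(x, cb$spatial)
    }
  }
  x
}

#' Backbone + neck forward pass
#'
#' Runs the ResNet-50 stages (with mid-stage attention when configured) and
#' the feature pyramid (lateral 1x1, top-down nearest upsampling and
#' summation, 3x3 output convs, max-pooled extra level), yielding five maps
#' at strides 4, 8, 16, 32, 64 relative to the input, all at the neck
#' width. Input sizes are padded internally to multiples of 64.
#'
#' @param model A [build_model()] result.
#' @param image `H x W x 3` array with values in 0–255.
#' @return Named list `p2`–`p6` of feature maps; each carries a `"stage"`
#'   attribute with its stride.
#' @export
forward_features <- function(model, image) {
  x <- normalize_image(image)
  p <- model$params
  x <- relu(bn_fwd(p$backbone$stem_bn, conv_fwd(p$backbone$stem_conv, x)))
  x <- as_fmap(cpp_maxpool2d(x, 3L, 2L, 1L))
  cs <- vector("list", 4L)
  for (s in 1:4) {
    x <- backbone_stage_fwd(p$backbone$layers[[s]], p$backbone$cb[[s]], x)
    cs[[s]] <- x
  }
  # top-down pathway
  lat <- lapply(1:4, function(i) conv_fwd(p$neck$lateral[[i]], cs[[i]]))
  fused <- vector("list", 4L)
  fused[[4]] <- lat[[4]]
  for (i in 3:1) {
    fused[[i]] <- lat[[i]] + as_fmap(cpp_upsample2x(fused[[i + 1]]))
  }
  out <- lapply(1:4, function(i) conv_fwd(p$neck$output[[i]], fused[[i]]))
  names(out) <- c("p2", "p3", "p4", "p5")
  for (lv in names(p$neck$eca)) out[[lv]] <- eca_conv_block(out[[lv]], p$neck$eca[[lv]])
  out$p6 <- as_fmap(cpp_maxpool2d(out$p5, 1L, 2L, 0L))
  strides <- c(p2 = 4L, p3 = 8L, p4 = 16L, p5 = 32L, p6 = 64L)
  for (nm in names(out)) attr(out[[nm]], "stage") <- strides[[nm]]
  out
}

as_fmap <- function(x) array(x, dim = dim(x))

normalize_image <- function(image) {
  img <- as_image_array(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  ph <- ceiling(h / 64) * 64; pw <- ceiling(w / 64) * 64
  out <- array(0, dim = c(ph, pw, 3))
  out[seq_len(h), seq_len(w), ] <- img / 127.5 - 1
  out
}
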