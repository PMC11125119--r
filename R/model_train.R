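# Toy trainer: optimizes the head networks (RPN, box head, semantic head,
# mask branch) with analytic backprop and SGD while the backbone and neck
# stay frozen, so per-image pyramid features are computed once and cached.
# This is the transfer-learning regime detection models are routinely
# fine-tuned in, scaled to desk-size problems; full-network training is a
# config preset, not part of the desk scope.

#' Build an in-memory dataset from synthetic scenes
#'
#' @param scenes List of [make_scene()] results.
#' @return A [dataset_index()] whose records hold in-memory images.
#' @export
scene_dataset <- function(scenes) {
  dataset_index(lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    list(image = s$image, height = dim(s$image)[1], width = dim(s$image)[2],
         annotations = s$truth$annotations)
  }))
}

record_image <- function(rec) {
  if (is.character(rec$image)) {
    img <- png::readPNG(rec$image)
    round(img[, , 1:3] * 255)
  } else rec$image
}

#' Toy training loop
#'
#' Runs SGD on the composite loss (proposal classification + box
#' regression, RoI classification + box regression with the configured
#' GIoU or L1 box loss, per-stage mask loss, semantic-segmentation loss)
#' over a small dataset, cycling the images one per step. Head networks
#' are trained; backbone and neck features are cached frozen. Seeded and
#' reproducible; raises if the loss turns non-finite.
#'
#' @param model A `feedscan_model`.
#' @param dataset A [dataset_index()] with in-memory images (see
#'   [scene_dataset()]).
#' @param steps Number of SGD steps.
#' @param seed Integer seed (sampling of anchors/proposals).
#' @param lr Learning rate (0 freezes everything: constant loss trace).
#' @param momentum SGD momentum.
#' @param clip_norm Global gradient-norm clip (numeric, `Inf` to disable).
#' @return List with `model` (updated weights) and `trace`, a data frame of
#'   per-step loss components.
#' @export
train_toy <- function(model, dataset, steps, seed = 1, lr = 3e-4,
                      momentum = 0.9, clip_norm = 5) {
  stopifnot(inherits(model, "feedscan_model"), inherits(dataset, "dataset_index"))
  recs <- dataset$records
  if (!length(recs)) stop("empty dataset", call. = FALSE)
  local_seed(seed, {
    caches <- lapply(recs, function(rec) {
      img <- record_image(rec)
      feats <- forward_features(model, img)
      anns <- rec$annotations
      boxes <- t(vapply(anns, function(a) a$bbox, numeric(4)))
      classes <- vapply(anns, function(a)
        match(a$category, feedscan_categories()), integer(1))
      masks <- lapply(anns, function(a) a$mask)
      list(feats = feats, boxes = boxes, classes = classes, masks = masks,
           h = dim(img)[1], w = dim(img)[2])
    })
    vel <- list()
    trace <- vector("list", steps)
    for (step in seq_len(steps)) {
      idx <- (step - 1L) %% length(caches) + 1L
      ca <- caches[[idx]]
      # anchor/proposal sampling is a deterministic function of (seed, image),
      # so revisiting an image at fixed weights reproduces its loss exactly
      set.seed(seed + idx * 131L)
      lg <- composite_loss_and_grads(model, ca)
      if (!is.finite(lg$losses[["total"]])) {
        stop("training diverged: non-finite loss at step ", step, call. = FALSE)
      }
      if (lr > 0) {
        gn <- sqrt(grad_sq_norm(lg$grads))
        if (is.finite(clip_norm) && gn > clip_norm) {
          lg$grads <- scale_grads(lg$grads, clip_norm / gn)
        }
        upd <- sgd_update(model$params[c("rpn", "box", "mask")], lg$grads,
                          vel, lr, momentum)
        model$params[c("rpn", "box", "mask")] <- upd$params
        vel <- upd$vel
      }
      trace[[step]] <- c(step = step, lg$losses)
    }
    list(model = model, trace = as.data.frame(do.call(rbind, trace)))
  })
}

# Loss weights are folded into the output-side gradients before the single
# backward pass through each head.
composite_loss_and_grads <- function(model, ca) {
  lw <- model$config$loss_weights
  rpn <- rpn_loss_and_grads(model, ca, lw_cls = lw[["rpn_cls"]],
                            lw_box = lw[["rpn_box"]])
  roi <- roi_loss_and_grads(model, ca, lw_cls = lw[["cls"]],
                            lw_box = lw[["box"]])
  sem <- semantic_loss_and_grads(model, ca)
  msk <- mask_loss_and_grads(model, ca, sem$sem_feat)
  losses <- c(rpn_cls = rpn$cls_loss, rpn_box = rpn$box_loss,
              cls = roi$cls_loss, box = roi$box_loss,
              mask = msk$loss, semantic = sem$loss)
  total <- sum(losses * lw[names(losses)])
  grads <- list(
    rpn = rpn$grads, box = roi$grads,
    mask = scale_grads(sem$grads, lw[["semantic"]]) |>
      add_grads(scale_grads(msk$grads, lw[["mask"]])))
  list(losses = c(total = total, losses), grads = grads)
}

# --- gradient structure helpers ---------------------------------------------

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in union(names(a), names(b))) {
    out[[nm]] <- add_grads(a[[nm]], b[[nm]])
  }
  out
}

scale_grads <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.numeric(g)) return(g * s)
  lapply(g, scale_grads, s = s)
}

grad_sq_norm <- function(g) {
  if (is.null(g)) return(0)
  if (is.numeric(g)) return(sum(g^2))
  sum(vapply(g, grad_sq_norm, numeric(1)))
}

conv_grad_entry <- function(layer, r) {
  g <- list(w = r$gw)
  if (!is.null(layer$b)) g$b <- as.vector(r$gb)
  g
}

# params and grads are parallel nested lists; layers are updated on their
# w/b entries with momentum-SGD.
sgd_update <- function(params, grads, vel, lr, momentum) {
  walk <- function(p, g, v) {
    if (is.null(g)) return(list(p = p, v = v))
    if (is.list(p) && !is.null(p$type)) {
      for (nm in intersect(names(g), c("w", "b"))) {
        vv <- if (!is.null(v[[nm]])) v[[nm]] else 0
        vv <- momentum * vv + g[[nm]]
        p[[nm]] <- p[[nm]] - lr * vv
        v[[nm]] <- vv
      }
      return(list(p = p, v = v))
    }
    if (is.list(p)) {
      if (is.null(v)) v <- list()
      for (nm in names(g)) {
        if (is.null(p[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        p[[nm]] <- r$p; v[[nm]] <- r$v
      }
    }
    list(p = p, v = v)
  }
  r <- walk(params, grads, vel)
  list(params = r$p, vel = r$v)
}

bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# --- RPN loss ---------------------------------------------------------------

rpn_loss_and_grads <- function(model, ca, n_pos_max = 16L, n_neg_max = 32L,
                               lw_cls = 1, lw_box = 1) {
  cfg <- model$config
  p <- model$params$rpn
  use_giou <- cfg$box_loss == "giou"
  cls_loss <- 0; box_loss <- 0
  gcls_total <- NULL
  n_levels <- 0L
  for (nm in names(ca$feats)) {
    feat <- ca$feats[[nm]]
    stride <- attr(feat, "stage")
    fwd <- rpn_forward_level(p, feat)
    hf <- dim(feat)[1]; wf <- dim(feat)[2]
    anc <- all_level_anchors(hf, wf, stride, cfg$anchor_ratios)
    n_anc <- nrow(anc$boxes)
    ious <- matrix(0, n_anc, nrow(ca$boxes))
    for (g in seq_len(nrow(ca$boxes))) {
      ious[, g] <- vapply(seq_len(n_anc), function(i)
        iou(anc$boxes[i, ], ca$boxes[g, ]), numeric(1))
    }
    max_iou <- apply(ious, 1, max)
    best_for_gt <- apply(ious, 2, which.max)
    pos <- unique(c(which(max_iou >= 0.5), best_for_gt))
    neg <- which(max_iou < 0.3)
    if (length(pos) > n_pos_max) pos <- sample(pos, n_pos_max)
    if (length(neg) > n_neg_max) neg <- sample(neg, n_neg_max)
    sampled <- c(pos, neg)
    labels <- c(rep(1, length(pos)), rep(0, length(neg)))

    gcls <- array(0, dim = dim(fwd$cls))
    greg <- array(0, dim = dim(fwd$reg))
    n_s <- length(sampled)
    for (ii in seq_along(sampled)) {
      i <- sampled[ii]
      z <- fwd$cls[anc$h[i], anc$w[i], anc$a[i]]
      y <- labels[ii]
      cls_loss <- cls_loss + (max(z, 0) - z * y + log1p(exp(-abs(z)))) / n_s
      gcls[anc$h[i], anc$w[i], anc$a[i]] <- (sigmoid(z) - y) / n_s
    }
    if (length(pos)) {
      for (i in pos) {
        gt <- ca$boxes[which.max(ious[i, ]), ]
        slots <- (4 * (anc$a[i] - 1) + 1):(4 * anc$a[i])
        delta <- fwd$reg[anc$h[i], anc$w[i], slots]
        if (use_giou) {
          dec <- decode_box(anc$boxes[i, ], delta)
          box_loss <- box_loss + giou_loss(dec, gt) / length(pos)
          gb <- giou_loss_grad(dec, gt) / length(pos)
          greg[anc$h[i], anc$w[i], slots] <-
            decode_box_grad(anc$boxes[i, ], delta, gb)
        } else {
          tgt <- encode_box(anc$boxes[i, ], gt)
          box_loss <- box_loss + sum(abs(delta - tgt)) / length(pos)
          greg[anc$h[i], anc$w[i], slots] <- sign(delta - tgt) / length(pos)
        }
      }
    }
    rc <- conv_bwd(p$cls, fwd$t, gcls * lw_cls, need_gx = TRUE)
    rr <- conv_bwd(p$reg, fwd$t, greg * lw_box, need_gx = TRUE)
    gt_in <- (as_fmap(rc$gx) + as_fmap(rr$gx)) * (fwd$t > 0)
    rt <- conv_bwd(p$conv, feat, gt_in, need_gx = FALSE)
    gcls_total <- add_grads(gcls_total,
                            list(conv = conv_grad_entry(p$conv, rt),
                                 cls = conv_grad_entry(p$cls, rc),
                                 reg = conv_grad_entry(p$reg, rr)))
    n_levels <- n_levels + 1L
  }
  list(cls_loss = cls_loss / n_levels, box_loss = box_loss / n_levels,
       grads = scale_grads(gcls_total, 1 / n_levels))
}

# --- RoI head loss ----------------------------------------------------------

roi_loss_and_grads <- function(model, ca, n_jitter = 12L, n_bg = 12L,
                               lw_cls = 1, lw_box = 1) {
  cfg <- model$config
  p <- model$params$box
  n_gt <- nrow(ca$boxes)
  props <- ca$boxes
  labels <- ca$classes
  match_gt <- seq_len(n_gt)
  for (g in seq_len(n_gt)) {
    for (j in seq_len(n_jitter)) {
      b <- jitter_box(ca$boxes[g, ], ca$h, ca$w)
      props <- rbind(props, b)
      overlap <- iou(b, ca$boxes[g, ])
      labels <- c(labels, if (overlap >= 0.5) ca$classes[g] else cfg$n_classes + 1L)
      match_gt <- c(match_gt, if (overlap >= 0.5) g else NA_integer_)
    }
  }
  tries <- 0L
  while (sum(is.na(match_gt) | labels > cfg$n_classes) < n_bg && tries < 80L) {
    tries <- tries + 1L
    b <- random_box(ca$h, ca$w)
    if (max(vapply(seq_len(n_gt), function(g) iou(b, ca$boxes[g, ]),
                   numeric(1))) < 0.3) {
      props <- rbind(props, b)
      labels <- c(labels, cfg$n_classes + 1L)
      match_gt <- c(match_gt, NA_integer_)
    }
  }
  n <- nrow(props)
  X <- t(vapply(seq_len(n), function(i)
    as.vector(roi_features(ca$feats, props[i, ], cfg$box_roi)),
    numeric(cfg$fpn_channels * cfg$box_roi^2)))
  fwd <- box_head_forward(p, X)

  probs <- t(apply(fwd$cls, 1, softmax))
  onehot <- matrix(0, n, cfg$n_classes + 1L)
  onehot[cbind(seq_len(n), labels)] <- 1
  cls_loss <- -mean(log(pmax(probs[cbind(seq_len(n), labels)], 1e-12)))
  Gcls <- (probs - onehot) / n

  Greg <- matrix(0, n, 4L * cfg$n_classes)
  box_loss <- 0
  pos <- which(!is.na(match_gt) & labels <= cfg$n_classes)
  use_giou <- cfg$box_loss == "giou"
  for (i in pos) {
    gt <- ca$boxes[match_gt[i], ]
    slots <- (4 * (labels[i] - 1) + 1):(4 * labels[i])
    delta <- fwd$reg[i, slots]
    if (use_giou) {
      dec <- decode_box(props[i, ], delta)
      box_loss <- box_loss + giou_loss(dec, gt) / length(pos)
      gb <- giou_loss_grad(dec, gt) / length(pos)
      Greg[i, slots] <- decode_box_grad(props[i, ], delta, gb)
    } else {
      tgt <- encode_box(props[i, ], gt)
      box_loss <- box_loss + sum(abs(delta - tgt)) / length(pos)
      Greg[i, slots] <- sign(delta - tgt) / length(pos)
    }
  }

  Gc <- Gcls * lw_cls; Gr <- Greg * lw_box
  gh2 <- Gc %*% p$cls$w + Gr %*% p$reg$w
  g <- list(cls = list(w = t(Gc) %*% fwd$h2, b = colSums(Gc)),
            reg = list(w = t(Gr) %*% fwd$h2, b = colSums(Gr)))
  gh2 <- gh2 * (fwd$h2 > 0)
  g$fc2 <- list(w = t(gh2) %*% fwd$h1, b = colSums(gh2))
  gh1 <- (gh2 %*% p$fc2$w) * (fwd$h1 > 0)
  g$fc1 <- list(w = t(gh1) %*% X, b = colSums(gh1))
  list(cls_loss = cls_loss, box_loss = box_loss, grads = g)
}

jitter_box <- function(b, h, w) {
  bw <- b[3] - b[1]; bh <- b[4] - b[2]
  s <- runif(1, 0.9, 1.1)
  dx <- runif(1, -0.15, 0.15) * bw; dy <- runif(1, -0.15, 0.15) * bh
  cx <- (b[1] + b[3]) / 2 + dx; cy <- (b[2] + b[4]) / 2 + dy
  clip_box(c(cx - s * bw / 2, cy - s * bh / 2, cx + s * bw / 2,
             cy + s * bh / 2), h, w)
}

random_box <- function(h, w) {
  bw <- runif(1, 8, w / 2); bh <- runif(1, 8, h / 2)
  x1 <- runif(1, 0, w - bw); y1 <- runif(1, 0, h - bh)
  c(x1, y1, x1 + bw, y1 + bh)
}

# --- semantic head loss -----------------------------------------------------

semantic_loss_and_grads <- function(model, ca) {
  mk <- model$params$mask
  sem <- semantic_forward(mk, ca$feats)
  d <- dim(sem$logits)
  target <- array(0, dim = d)
  for (cls in 1:2) {
    idx <- which(ca$classes == cls)
    if (!length(idx)) next
    un <- Reduce(`|`, ca$masks[idx])
    # embed at the padded canvas size the features were computed on
    padded <- matrix(FALSE, d[1] * 4L, d[2] * 4L)
    padded[seq_len(nrow(un)), seq_len(ncol(un))] <- un
    target[, , cls] <- downsample_mask(padded, d[1], d[2])
  }
  z <- sem$logits
  loss <- bce_with_logits(z, target)
  gz <- (sigmoid(z) - target) / length(z)

  r_log <- conv_bwd(mk$sem_logits, sem$feat, gz, need_gx = TRUE)
  grads <- list(sem_logits = conv_grad_entry(mk$sem_logits, r_log),
                sem_stack = vector("list", length(mk$sem_stack)),
                lateral = vector("list", 4L))
  g <- as_fmap(r_log$gx)
  for (j in rev(seq_along(mk$sem_stack))) {
    out_j <- if (j == length(mk$sem_stack)) sem$feat else sem$stack_in[[j + 1]]
    g <- g * (out_j > 0)
    r <- conv_bwd(mk$sem_stack[[j]], sem$stack_in[[j]], g, need_gx = TRUE)
    grads$sem_stack[[j]] <- conv_grad_entry(mk$sem_stack[[j]], r)
    g <- as_fmap(r$gx)
  }
  for (i in 1:4) {
    gi <- g
    if (i > 1) for (k in seq_len(i - 1)) gi <- as_fmap(cpp_downsum2x(gi))
    r <- conv_bwd(mk$lateral[[i]], sem$lat_in[[i]], gi, need_gx = FALSE)
    grads$lateral[[i]] <- conv_grad_entry(mk$lateral[[i]], r)
  }
  list(loss = loss, grads = grads, sem_feat = sem$feat)
}

downsample_mask <- function(mask, h, w) {
  src_r <- resize_index(h, nrow(mask)); src_c <- resize_index(w, ncol(mask))
  (mask[src_r, src_c, drop = FALSE]) * 1
}

# --- mask branch loss -------------------------------------------------------

mask_loss_and_grads <- function(model, ca, sem_feat) {
  mk <- model$params$mask
  n_gt <- nrow(ca$boxes)
  total <- 0; grads <- NULL
  for (g in seq_len(n_gt)) {
    box <- ca$boxes[g, ]
    mb <- mask_branch_forward(mk, ca$feats, sem_feat, box)
    n_stage <- length(mb$logits)
    cls <- ca$classes[g]
    glog <- vector("list", n_stage)
    for (k in seq_len(n_stage)) {
      z <- mb$logits[[k]][, , cls]
      tgt <- crop_mask_to_box(ca$masks[[g]], box, dim(z)[1])
      total <- total + bce_with_logits(z, tgt) / (n_stage * n_gt)
      gz <- array(0, dim = dim(mb$logits[[k]]))
      gz[, , cls] <- (sigmoid(z) - tgt) / (length(z) * n_stage * n_gt)
      glog[[k]] <- gz
    }
    grads <- add_grads(grads, mask_branch_backward(mk, mb, glog))
  }
  list(loss = total, grads = grads)
}

crop_mask_to_box <- function(mask, box, res) {
  ys <- box[2] + (seq_len(res) - 0.5) * (box[4] - box[2]) / res
  xs <- box[1] + (seq_len(res) - 0.5) * (box[3] - box[1]) / res
  rr <- pmin(pmax(floor(ys) + 1L, 1L), nrow(mask))
  cc <- pmin(pmax(floor(xs) + 1L, 1L), ncol(mask))
  (mask[rr, cc, drop = FALSE]) * 1
}

mask_branch_backward <- function(mk, mb, glog) {
  K <- length(mk$stages)
  grads <- list(stages = vector("list", K),
                inst_stack = vector("list", length(mk$inst_stack)))
  gf <- NULL
  for (k in rev(seq_len(K))) {
    st <- mk$stages[[k]]; cache <- mb$stages[[k]]
    r_log <- conv_bwd(st$logits, cache$f, glog[[k + 1]], need_gx = TRUE)
    gfk <- as_fmap(r_log$gx)
    if (!is.null(gf)) gfk <- gfk + gf
    gfk <- gfk * (cache$f > 0)
    r_conv <- conv_bwd(st$conv, cache$g, gfk, need_gx = TRUE)
    gg <- as_fmap(r_conv$gx) * (cache$g > 0)
    r_fuse <- conv_bwd(st$fuse, cache$cat_in, gg, need_gx = TRUE)
    grads$stages[[k]] <- list(fuse = conv_grad_entry(st$fuse, r_fuse),
                              conv = conv_grad_entry(st$conv, r_conv),
                              logits = conv_grad_entry(st$logits, r_log))
    gcat <- as_fmap(r_fuse$gx)
    gfin <- gcat[, , seq_len(cache$n_up), drop = FALSE]
    gf <- as_fmap(cpp_downsum2x(gfin))
  }
  r_ilog <- conv_bwd(mk$inst_logits, mb$inst_feat, glog[[1]], need_gx = TRUE)
  grads$inst_logits <- conv_grad_entry(mk$inst_logits, r_ilog)
  gx <- as_fmap(r_ilog$gx)
  if (!is.null(gf)) gx <- gx + gf
  for (j in rev(seq_along(mk$inst_stack))) {
    out_j <- if (j == length(mk$inst_stack)) mb$inst_feat else mb$stack_in[[j + 1]]
    gx <- gx * (out_j > 0)
    r <- conv_bwd(mk$inst_stack[[j]], mb$stack_in[[j]], gx,
                  need_gx = j > 1L)
    grads$inst_stack[[j]] <- conv_grad_entry(mk$inst_stack[[j]], r)
    if (j > 1L) gx <- as_fmap(r$gx)
  }
  grads
}
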