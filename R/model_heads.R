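# Head networks: region proposal network, RoI box head, semantic fusion
# module and multi-stage mask branch. Forward functions cache the
# intermediates the toy trainer's analytic backward passes need.

# --- anchors and box coding -------------------------------------------------

# Anchor base size is 4x the level stride, with aspect ratios h/w from the
# config; centres sit at pixel centres of the level grid.
level_anchor_box <- function(h_idx, w_idx, a_idx, stride, ratios) {
  base <- 4 * stride
  ratio <- ratios[a_idx]
  aw <- base / sqrt(ratio); ah <- base * sqrt(ratio)
  cx <- (w_idx - 0.5) * stride; cy <- (h_idx - 0.5) * stride
  c(cx - aw / 2, cy - ah / 2, cx + aw / 2, cy + ah / 2)
}

all_level_anchors <- function(hf, wf, stride, ratios) {
  grid <- expand.grid(h = seq_len(hf), w = seq_len(wf), a = seq_along(ratios))
  boxes <- t(mapply(level_anchor_box, grid$h, grid$w, grid$a,
                    MoreArgs = list(stride = stride, ratios = ratios)))
  list(boxes = boxes, h = grid$h, w = grid$w, a = grid$a)
}

# (dx, dy, dw, dh) parameterization relative to a reference box; dw/dh are
# clamped at +/-4 for numeric safety.
decode_box <- function(ref, delta) {
  rw <- max(ref[3] - ref[1], 1e-3); rh <- max(ref[4] - ref[2], 1e-3)
  cx <- (ref[1] + ref[3]) / 2 + delta[1] * rw
  cy <- (ref[2] + ref[4]) / 2 + delta[2] * rh
  w <- rw * exp(min(max(delta[3], -4), 4))
  h <- rh * exp(min(max(delta[4], -4), 4))
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

encode_box <- function(ref, box) {
  rw <- max(ref[3] - ref[1], 1e-3); rh <- max(ref[4] - ref[2], 1e-3)
  bw <- max(box[3] - box[1], 1e-3); bh <- max(box[4] - box[2], 1e-3)
  c(((box[1] + box[3]) / 2 - (ref[1] + ref[3]) / 2) / rw,
    ((box[2] + box[4]) / 2 - (ref[2] + ref[4]) / 2) / rh,
    log(bw / rw), log(bh / rh))
}

# Chain rule through decode_box: given dL/d(decoded box), return dL/d(delta).
decode_box_grad <- function(ref, delta, gbox) {
  rw <- max(ref[3] - ref[1], 1e-3); rh <- max(ref[4] - ref[2], 1e-3)
  dw <- min(max(delta[3], -4), 4); dh <- min(max(delta[4], -4), 4)
  w <- rw * exp(dw); h <- rh * exp(dh)
  g <- numeric(4)
  g[1] <- rw * (gbox[1] + gbox[3])
  g[2] <- rh * (gbox[2] + gbox[4])
  if (delta[3] > -4 && delta[3] < 4) g[3] <- (w / 2) * (gbox[3] - gbox[1])
  if (delta[4] > -4 && delta[4] < 4) g[4] <- (h / 2) * (gbox[4] - gbox[2])
  g
}

clip_box <- function(box, h, w) {
  c(min(max(box[1], 0), w), min(max(box[2], 0), h),
    min(max(box[3], 0), w), min(max(box[4], 0), h))
}

# FPN level for an RoI (the standard area heuristic), clamped to p2..p5.
roi_level <- function(box) {
  scale <- sqrt(max(box[3] - box[1], 1) * max(box[4] - box[2], 1))
  k <- floor(4 + log2(scale / 224))
  paste0("p", min(max(k, 2), 5))
}

roi_features <- function(feats, box, out_size) {
  lv <- roi_level(box)
  stride <- attr(feats[[lv]], "stage")
  as_fmap(cpp_roi_align(feats[[lv]], matrix(box, 1), out_size, out_size,
                        1 / stride)[[1]])
}

# --- RPN --------------------------------------------------------------------

rpn_forward_level <- function(rpn, feat) {
  pre <- conv_fwd(rpn$conv, feat)
  t <- relu(pre)
  list(t = t, cls = conv_fwd(rpn$cls, t), reg = conv_fwd(rpn$reg, t))
}

# --- RoI box head -----------------------------------------------------------

# X: n x (fc*roi^2) matrix of flattened RoI features (column-major cube order).
box_head_forward <- function(box, X) {
  h1 <- pmax(X %*% t(box$fc1$w) + rep(box$fc1$b, each = nrow(X)), 0)
  h2 <- pmax(h1 %*% t(box$fc2$w) + rep(box$fc2$b, each = nrow(X)), 0)
  list(h1 = h1, h2 = h2,
       cls = h2 %*% t(box$cls$w) + rep(box$cls$b, each = nrow(X)),
       reg = h2 %*% t(box$reg$w) + rep(box$reg$b, each = nrow(X)))
}

# --- semantic fusion module -------------------------------------------------

# Fuses the four neck maps (p2..p5 upsampled to p2 size and summed through
# 1x1 laterals) and runs the semantic conv stack. Caches every conv input.
semantic_forward <- function(mask, feats) {
  lv <- c("p2", "p3", "p4", "p5")
  lat_in <- lapply(lv, function(nm) feats[[nm]])
  lat_out <- lapply(1:4, function(i) conv_fwd(mask$lateral[[i]], lat_in[[i]]))
  for (i in 2:4) {
    up <- lat_out[[i]]
    for (k in seq_len(i - 1)) up <- as_fmap(cpp_upsample2x(up))
    lat_out[[i]] <- up
  }
  fused <- Reduce(`+`, lat_out)
  xs <- list(); x <- fused
  for (j in seq_along(mask$sem_stack)) {
    xs[[j]] <- x
    x <- relu(conv_fwd(mask$sem_stack[[j]], x))
  }
  list(lat_in = lat_in, fused = fused, stack_in = xs, feat = x,
       logits = conv_fwd(mask$sem_logits, x))
}

# --- mask branch ------------------------------------------------------------

# Multi-stage instance mask head: initial conv stack on the 14x14 RoI, then
# refinement stages that upsample x2, fuse with the RoI-aligned semantic
# feature (treated as constant input) and predict progressively larger
# masks. Returns logits at every stage plus the caches for backward.
mask_branch_forward <- function(mask, feats, sem_feat, box) {
  x14 <- roi_features(feats, box, 14L)
  xs <- list(); x <- x14
  for (j in seq_along(mask$inst_stack)) {
    xs[[j]] <- x
    x <- relu(conv_fwd(mask$inst_stack[[j]], x))
  }
  logits <- list(conv_fwd(mask$inst_logits, x))
  stages <- list()
  f <- x
  res <- 14L
  for (k in seq_along(mask$stages)) {
    st <- mask$stages[[k]]
    res <- res * 2L
    fin <- as_fmap(cpp_upsample2x(f))
    sem_roi <- as_fmap(cpp_roi_align(sem_feat, matrix(box, 1), res, res,
                                     1 / 4)[[1]])
    cat_in <- abind3(fin, sem_roi)
    g <- relu(conv_fwd(st$fuse, cat_in))
    f <- relu(conv_fwd(st$conv, g))
    logits[[k + 1]] <- conv_fwd(st$logits, f)
    stages[[k]] <- list(cat_in = cat_in, g = g, f = f, n_up = dim(fin)[3])
  }
  list(x14 = x14, stack_in = xs, inst_feat = x, stages = stages,
       logits = logits)
}

abind3 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}
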