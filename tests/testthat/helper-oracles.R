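# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, direct formula evaluation,
# and an explicit threshold sweep for average precision.

# Eq-style double-loop MSE over rows, columns and channels.
mse_loop_oracle <- function(a, b) {
  d <- dim(a)
  acc <- 0
  for (k in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- acc + (a[i, j, k] - b[i, j, k])^2
      }
    }
  }
  acc / prod(d)
}

# Pixel-enumeration IoU of two boxes on a fine integer subgrid.
box_iou_pixel_oracle <- function(a, b, res = 1) {
  xs <- seq(min(a[1], b[1]), max(a[3], b[3]) - res / 2, by = res) + res / 2
  ys <- seq(min(a[2], b[2]), max(a[4], b[4]) - res / 2, by = res) + res / 2
  in_box <- function(box, x, y) x >= box[1] & x < box[3] & y >= box[2] & y < box[4]
  g <- expand.grid(x = xs, y = ys)
  na <- sum(in_box(a, g$x, g$y)); nb <- sum(in_box(b, g$x, g$y))
  ni <- sum(in_box(a, g$x, g$y) & in_box(b, g$x, g$y))
  ni / (na + nb - ni)
}

# Greedy per-category matching re-implemented independently for the sweep.
oracle_match <- function(preds, truths, thr, mode) {
  pair_overlap <- function(p, g) {
    if (mode == "box") {
      ix <- min(p$bbox[3], g$bbox[3]) - max(p$bbox[1], g$bbox[1])
      iy <- min(p$bbox[4], g$bbox[4]) - max(p$bbox[2], g$bbox[2])
      inter <- if (ix > 0 && iy > 0) ix * iy else 0
      ap <- (p$bbox[3] - p$bbox[1]) * (p$bbox[4] - p$bbox[2])
      ag <- (g$bbox[3] - g$bbox[1]) * (g$bbox[4] - g$bbox[2])
      inter / (ap + ag - inter)
    } else {
      sum(p$mask & g$mask) / sum(p$mask | g$mask)
    }
  }
  ord <- order(vapply(preds, function(p) p$score, numeric(1)), decreasing = TRUE)
  used <- rep(FALSE, length(truths))
  tp <- 0
  for (i in ord) {
    ovs <- vapply(seq_along(truths), function(j) {
      if (used[j] || truths[[j]]$category != preds[[i]]$category) return(-1)
      pair_overlap(preds[[i]], truths[[j]])
    }, numeric(1))
    j <- which.max(ovs)
    if (length(j) && ovs[j] >= thr) { used[j] <- TRUE; tp <- tp + 1 }
  }
  c(tp = tp, fp = length(preds) - tp)
}

# Explicit threshold-sweep AP for one category: PR point per unique score,
# right-max envelope, all-point area. Assumes distinct scores.
ap_sweep_oracle <- function(preds, truths, thr, mode, category) {
  preds <- Filter(function(p) p$category == category, preds)
  truths <- Filter(function(g) g$category == category, truths)
  n_gt <- length(truths)
  if (!length(preds)) return(0)
  scores <- sort(unique(vapply(preds, function(p) p$score, numeric(1))),
                 decreasing = TRUE)
  pr <- t(vapply(scores, function(s) {
    sub <- Filter(function(p) p$score >= s, preds)
    m <- oracle_match(sub, truths, thr, mode)
    c(p = m[["tp"]] / max(m[["tp"]] + m[["fp"]], 1), r = m[["tp"]] / n_gt)
  }, numeric(2)))
  env <- rev(cummax(rev(pr[, "p"])))
  r_prev <- c(0, pr[-nrow(pr), "r"])
  sum((pr[, "r"] - r_prev) * env)
}

# Finite-difference gradient of a scalar function of a numeric vector.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
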