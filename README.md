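# feedscan

Recognition of dairy-cow feeding behaviour at the feed fence from
instance-segmentation masks.

On large dairy farms, feed is spread along a feeding alley and cows reach
through a restriction fence to eat. How long each cow spends feeding during
the peak period after spreading is a practical welfare and feed-efficiency
indicator, but contact sensors are invasive and plain object detection is
too coarse to tell "head near feed" from "jaw in the feed pile". `feedscan`
implements a camera-only pipeline built around a boundary-refining
instance-segmentation model:

1. **Frame sampling** — redundancy in fixed-camera footage is quantified
   with MSE and PSNR over frame pairs at increasing gaps,
   `MSE = (1/MN) Σᵢⱼ (I(i,j) − K(i,j))²` and
   `PSNR = 10·log₁₀(MAX_I²/MSE)`, and frames are extracted at a fixed
   stride (default 600 frames for 20 fps footage).
2. **Dataset preparation** — COCO-dialect annotations over two categories
   (`head`, `feed trough`), a deterministic 8:1:1 train/val/test split, and
   mosaic + horizontal-flip augmentation.
3. **Segmentation model** — a RefineMask-style architecture: ResNet-50
   backbone with channel+spatial attention blocks (CB_Conv) in its residual
   stages, a five-level FPN neck with an efficient-channel-attention block
   (ECA_Conv, adaptive kernel `k = ψ(C)`) on the high-level fused map, a
   region-proposal network and RoI head whose box regression minimizes the
   GIoU loss `L = 1 − GIoU`, `GIoU = IoU − (A_c − U)/A_c`, and a
   multi-stage mask branch fused with a semantic head over four neck maps.
   The baseline variant (no attention, L1 box loss) counts 48.40 M
   trainable parameters and the full variant 49.76 M under the reference
   configuration.
4. **Evaluation** — precision/recall, per-category average precision (area
   under the right-max-interpolated PR curve) and mAP for boxes and masks.
5. **Behaviour recognition** — per frame, each detected head is assigned to
   the fence strip holding the majority of its mask; the fence is *feeding*
   when the head's jaw region (lowest third of the head mask) overlaps the
   feed-pile mask in that fence by at least τ pixels (default 20). Flags
   accumulate to per-fence feeding times, `time = frames × stride / fps`,
   scored against reference times with the mean absolute error
   `MAE = (1/n) Σ |ŷᵢ − yᵢ|`.

Because the farm dataset behind the original study is private, the package
ships a synthetic barn-scene generator (band-shaped irregular feed pile,
elliptical heads, fence strips, day/dim/night regimes) that produces
pixel-accurate ground truth for every stage, including feeding clips with
known per-fence schedules and perturbed detection sets with oracle-known
average precision.

## Worked example

```r
library(feedscan)

cfg <- scene_config(canvas_size = c(96, 128), n_fences = 4, n_heads = 3, seed = 7)
scene <- make_scene(cfg)
scene$truth$feeding_state
#>     1     2     3     4
#> FALSE  TRUE FALSE  TRUE

## evaluation on a perturbed detection set (1 px jitter, 2 false positives,
## one missed instance -- the miss is the single feed trough, so its AP is 0)
dets <- make_detection_set(scene$truth, jitter_px = 1, n_false_positives = 2,
                           n_misses = 1, seed = 11)
mean_ap(dets, scene$truth$annotations, 0.5, "mask")
#> [1] 50

## a 2-second clip with a known feeding schedule, recognized from truth masks
clip <- make_feeding_clip(cfg, n_frames = 40, fps = 20,
                          schedule = list("1" = rbind(c(0, 30)),
                                          "3" = rbind(c(10, 20))))
states <- lapply(clip$truth$frame_annotations, frame_feeding_state,
                 layout = clip$truth$fence_layout)
accumulate_timeline(states, fps = 20)
#> <feeding_timeline: 40 frames x 4 fences @ 20 fps, stride 1>
#>   fence feeding_frames feeding_time_s
#> 1     1             30            1.5
#> 2     2              0            0.0
#> 3     3             10            0.5
#> 4     4              0            0.0
```

Fence 1 was scheduled to feed for frames 0–29 (1.5 s at 20 fps) and fence 3
for frames 10–19 (0.5 s); the mask-overlap logic recovers both exactly, so
`mae()` against the schedule is 0.

Model-side entry points: `build_model()` / `count_parameters()` for the
architecture, `forward_features()` for the five-level pyramid,
`train_toy()` for a seeded head-finetuning loop on synthetic scenes, and
`predict()` for thresholded, NMS-suppressed instances with full-resolution
masks. A thin CLI (`exec/feedscan`) wraps the synthesizer, frame sampler,
evaluator and behaviour pipeline for shell use.

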