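# Shared fixtures: everything is generated in code, nothing read from disk.

# tiny network that exercises every code path cheaply
tiny_net_config <- function(variant = "serr", t = 2L, seed = 3L)
  network_config(input_size = c(8L, 8L, 1L), widths = c(4L, 8L),
                 recurrence_steps = t, se_reduction = 4L, variant = variant,
                 seed = seed)

# small synthetic image triplet, memoised per (size, seed)
.synth_cache <- new.env(parent = emptyenv())
synth_fixture <- function(size = 96L, seed = 1L) {
  key <- paste0(size, "_", seed)
  if (is.null(.synth_cache[[key]]))
    .synth_cache[[key]] <- generate_fundus(
      synth_config(image_size = c(size, size), seed = seed))
  .synth_cache[[key]]
}

# deterministic RGB test image with distinct channels
rgb_fixture <- function(H = 48L, W = 48L) {
  base <- outer(seq_len(H), seq_len(W), function(i, j) (i + 2 * j) %% 200)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- base
  px[, , 2] <- (base + 30) %% 256
  px[, , 3] <- (255 - base)
  fundus_image(px, source_id = "fixture")
}

# O(n^2) pairwise-concordance AUC oracle (ties count one half)
auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force per-pixel confusion tally
confusion_oracle <- function(pred, gt, fov = NULL) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (!is.null(fov) && fov[i] == 0) next
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# exhaustive per-class IoU tally
miou_oracle <- function(pred, gt) {
  ious <- c()
  for (cls in c(0, 1)) {
    inter <- sum(pred == cls & gt == cls)
    union <- sum(pred == cls | gt == cls)
    if (union > 0) ious <- c(ious, inter / union)
  }
  mean(ious)
}

gray_plane_from <- function(v) gray_plane(v, "raw")
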