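# One-stage anchor-based lung-box detector: a reduced residual backbone,
# shared class/box convolutional heads, focal loss for anchor
# classification, smooth-L1 for box regression, greedy NMS at decode time.
# The CPU desk profile uses a single pyramid level at stride 16; the anchor
# and loss settings follow the standard one-stage defaults (alpha 0.25,
# gamma 2, assignment thresholds 0.5/0.4).

#' Detector configuration
#'
#' @param img_size square input resolution (desk profile 128; full 512).
#' @param stride feature stride of the detection level (16).
#' @param base_scale anchor base size = `base_scale * stride`.
#' @param scales,ratios anchor scale multipliers and aspect ratios
#'   (3 x 3 = 9 anchors per cell).
#' @param channels backbone widths: stem then three residual stages.
#' @param head_channels width of the class/box subnets.
#' @param focal_alpha,focal_gamma focal-loss parameters.
#' @param pos_iou,neg_iou anchor assignment thresholds.
#' @param score_threshold,nms_iou decode-time filtering.
#' @param reg_weight weight of the box-regression loss relative to the
#'   focal classification term.
#' @param lr,lr_decay,patience,epochs,batch_size training schedule
#'   (defaults: Adam 1e-4, plateau decay 0.1 after 3 stale evaluations,
#'   200 epochs, batch 1).
#' @param seed weight-init seed.
#' @export
detector_config <- function(img_size = 128, stride = 16, base_scale = 4,
                            scales = 2^(c(0, 1, 2) / 3), ratios = c(0.5, 1, 2),
                            channels = c(16, 32, 48, 64), head_channels = 64,
                            focal_alpha = 0.25, focal_gamma = 2,
                            pos_iou = 0.5, neg_iou = 0.4,
                            score_threshold = 0.05, nms_iou = 0.5,
                            reg_weight = 2,
                            lr = 1e-4, lr_decay = 0.1, patience = 3,
                            epochs = 200, batch_size = 1, seed = 1) {
  if (nms_iou <= 0 || nms_iou >= 1) stopf("nms_iou must be in (0,1)")
  if (!(neg_iou <= pos_iou)) stopf("need neg_iou <= pos_iou")
  list(img_size = img_size, stride = stride, base_scale = base_scale,
       scales = scales, ratios = ratios, channels = channels,
       head_channels = head_channels, focal_alpha = focal_alpha,
       focal_gamma = focal_gamma, pos_iou = pos_iou, neg_iou = neg_iou,
       score_threshold = score_threshold, nms_iou = nms_iou,
       reg_weight = reg_weight, lr = lr,
       lr_decay = lr_decay, patience = patience, epochs = epochs,
       batch_size = batch_size, seed = seed)
}

#' Focal loss for binary anchor classification
#'
#' `FL = -alpha_t (1 - p_t)^gamma log(p_t)` with `p_t = p` for positives and
#' `1 - p` for negatives. Probabilities are clamped to
#' `[eps, 1 - eps]` (eps = 1e-7).
#'
#' @param pred_prob predicted probabilities.
#' @param target 0/1 targets.
#' @param alpha,gamma focal parameters.
#' @return vector of per-anchor losses (non-negative).
#' @export
focal_loss <- function(pred_prob, target, alpha = 0.25, gamma = 2) {
  eps <- 1e-7
  p <- pmin(pmax(pred_prob, eps), 1 - eps)
  pt <- ifelse(target == 1, p, 1 - p)
  at <- ifelse(target == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

# d(FL)/d(logit) with p = sigmoid(logit); vectorized.
focal_loss_grad_logit <- function(p, target, alpha, gamma) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(target == 1, p, 1 - p)
  at <- ifelse(target == 1, alpha, 1 - alpha)
  dFL_dpt <- -at * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
  dpt_dp <- ifelse(target == 1, 1, -1)
  dFL_dpt * dpt_dp * p * (1 - p)
}

# Anchor grid for a single feature level; returns a matrix with columns
# (top, bottom, left, right) in image pixels, rows ordered (cell_row,
# cell_col, anchor) with anchor fastest.
make_anchors <- function(config) {
  g <- config$img_size / config$stride
  base <- config$base_scale * config$stride
  hw <- expand.grid(scale = config$scales, ratio = config$ratios)
  # area = (base*scale)^2, h/w = ratio
  h <- base * hw$scale * sqrt(hw$ratio)
  w <- base * hw$scale / sqrt(hw$ratio)
  out <- matrix(0, g * g * nrow(hw), 4)
  k <- 1
  for (i in seq_len(g)) {
    cy <- (i - 0.5) * config$stride
    for (j in seq_len(g)) {
      cx <- (j - 0.5) * config$stride
      for (a in seq_len(nrow(hw))) {
        out[k, ] <- c(cy - h[a] / 2, cy + h[a] / 2, cx - w[a] / 2, cx + w[a] / 2)
        k <- k + 1
      }
    }
  }
  colnames(out) <- c("top", "bottom", "left", "right")
  out
}

anchor_iou <- function(anchors, box) {
  ih <- pmax(0, pmin(anchors[, "bottom"], box$bottom) - pmax(anchors[, "top"], box$top))
  iw <- pmax(0, pmin(anchors[, "right"], box$right) - pmax(anchors[, "left"], box$left))
  inter <- ih * iw
  aa <- (anchors[, "bottom"] - anchors[, "top"]) * (anchors[, "right"] - anchors[, "left"])
  inter / (aa + box_area(box) - inter)
}

#' Assign anchors to a ground-truth box
#'
#' Anchors with IoU >= `pos_iou` are positive, <= `neg_iou` negative, the
#' rest ignored; the best-IoU anchor is always positive so every target has
#' at least one match. Regression targets are center/size offsets
#' `(dy/ah, dx/aw, log(h/ah), log(w/aw))`.
#'
#' @param anchors matrix from `make_anchors()`.
#' @param truth_box a [lung_box()].
#' @param pos_iou,neg_iou assignment thresholds.
#' @return list `cls` (1 positive / 0 negative / NA ignored) and `reg`
#'   (N x 4 targets, rows valid for positives).
#' @export
assign_anchors <- function(anchors, truth_box, pos_iou = 0.5, neg_iou = 0.4) {
  ious <- anchor_iou(anchors, truth_box)
  cls <- rep(NA_real_, nrow(anchors))
  cls[ious <= neg_iou] <- 0
  cls[ious >= pos_iou] <- 1
  cls[which.max(ious)] <- 1
  ah <- anchors[, "bottom"] - anchors[, "top"]
  aw <- anchors[, "right"] - anchors[, "left"]
  acy <- (anchors[, "top"] + anchors[, "bottom"]) / 2
  acx <- (anchors[, "left"] + anchors[, "right"]) / 2
  bh <- truth_box$bottom - truth_box$top
  bw <- truth_box$right - truth_box$left
  bcy <- (truth_box$top + truth_box$bottom) / 2
  bcx <- (truth_box$left + truth_box$right) / 2
  reg <- cbind((bcy - acy) / ah, (bcx - acx) / aw, log(bh / ah), log(bw / aw))
  list(cls = cls, reg = reg, ious = ious)
}

decode_boxes <- function(anchors, offsets, img_size) {
  ah <- anchors[, "bottom"] - anchors[, "top"]
  aw <- anchors[, "right"] - anchors[, "left"]
  acy <- (anchors[, "top"] + anchors[, "bottom"]) / 2
  acx <- (anchors[, "left"] + anchors[, "right"]) / 2
  cy <- acy + offsets[, 1] * ah
  cx <- acx + offsets[, 2] * aw
  h <- ah * exp(pmin(offsets[, 3], 4))
  w <- aw * exp(pmin(offsets[, 4], 4))
  cbind(top = pmax(0, cy - h / 2), bottom = pmin(img_size, cy + h / 2),
        left = pmax(0, cx - w / 2), right = pmin(img_size, cx + w / 2))
}

#' Decode raw detector outputs and run greedy NMS
#'
#' @param scores per-anchor probabilities.
#' @param offsets N x 4 regression offsets.
#' @param anchors anchor matrix.
#' @param config [detector_config()] (score threshold, NMS IoU, image size).
#' @return list of detections `list(box, score)` in descending score order;
#'   empty list if nothing clears the threshold.
#' @export
decode_and_nms <- function(scores, offsets, anchors, config) {
  keep <- which(scores >= config$score_threshold)
  if (length(keep) == 0) return(list())
  boxes <- decode_boxes(anchors[keep, , drop = FALSE],
                        offsets[keep, , drop = FALSE], config$img_size)
  scr <- scores[keep]
  ord <- order(scr, decreasing = TRUE)
  boxes <- boxes[ord, , drop = FALSE]; scr <- scr[ord]
  valid <- boxes[, "bottom"] > boxes[, "top"] & boxes[, "right"] > boxes[, "left"]
  boxes <- boxes[valid, , drop = FALSE]; scr <- scr[valid]
  sel <- integer(0)
  alive <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (!alive[i]) next
    sel <- c(sel, i)
    if (i < nrow(boxes)) {
      bi <- lung_box(boxes[i, 1], boxes[i, 2], boxes[i, 3], boxes[i, 4])
      rest <- which(alive & seq_len(nrow(boxes)) > i)
      for (j in rest) {
        bj <- lung_box(boxes[j, 1], boxes[j, 2], boxes[j, 3], boxes[j, 4])
        if (iou(bi, bj) >= config$nms_iou) alive[j] <- FALSE
      }
    }
  }
  lapply(sel, function(i)
    list(box = lung_box(boxes[i, 1], boxes[i, 2], boxes[i, 3], boxes[i, 4]),
         score = scr[i]))
}

# --- network ---------------------------------------------------------------

res_stage <- function(in_c, out_c) {
  list(ca = nn_conv(in_c, out_c, k = 3, stride = 2), aa = nn_lrelu(),
       cb = nn_conv(out_c, out_c, k = 3, stride = 1),
       sc = nn_conv(in_c, out_c, k = 1, stride = 2, pad = 0), ao = nn_lrelu())
}

res_stage_fwd <- function(st, x) st$ao$fwd(st$cb$fwd(st$aa$fwd(st$ca$fwd(x))) + st$sc$fwd(x))

res_stage_bwd <- function(st, dy) {
  d <- st$ao$bwd(dy)
  st$sc$bwd(d) + st$ca$bwd(st$aa$bwd(st$cb$bwd(d)))
}

#' Build the lung-box detector network
#'
#' @param config a [detector_config()].
#' @return `detector_net` with `$forward(img)` returning per-anchor scores
#'   and offsets.
#' @export
build_detector <- function(config = detector_config()) {
  A <- length(config$scales) * length(config$ratios)
  ch <- config$channels; hc <- config$head_channels
  n_stages <- length(ch) - 1
  if (2^(1 + n_stages) != config$stride)
    stopf("channels length %d implies stride %d, config says %d",
          length(ch), 2^(1 + n_stages), config$stride)
  layers <- with_seed(config$seed, {
    L <- list(stem = nn_conv(1, ch[1], k = 3, stride = 2), stema = nn_lrelu())
    for (s in seq_len(n_stages))
      L[[paste0("s", s)]] <- res_stage(ch[s], ch[s + 1])
    L$ch1 <- nn_conv(ch[n_stages + 1], hc, k = 3); L$cha <- nn_lrelu()
    L$cls <- nn_conv(hc, A, k = 3)
    L$bh1 <- nn_conv(ch[n_stages + 1], hc, k = 3); L$bha <- nn_lrelu()
    L$box <- nn_conv(hc, 4 * A, k = 3)
    L$cls$b <- rep(-log((1 - 0.01) / 0.01), A)  # rare-positive prior
    L
  })
  flat <- c(layers[c("stem", "stema")],
            do.call(c, lapply(seq_len(n_stages), function(s) layers[[paste0("s", s)]])),
            layers[c("ch1", "cha", "cls", "bh1", "bha", "box")])
  net <- list(kind = "detector", config = config, layers = flat,
              anchors = make_anchors(config))
  L <- layers
  net$forward <- function(img) {
    x <- array(unclass_img(img), c(nrow(img), ncol(img), 1))
    f <- L$stema$fwd(L$stem$fwd(x))
    for (s in seq_len(n_stages)) f <- res_stage_fwd(L[[paste0("s", s)]], f)
    cl <- L$cls$fwd(L$cha$fwd(L$ch1$fwd(f)))
    bx <- L$box$fwd(L$bha$fwd(L$bh1$fwd(f)))
    list(cls = cl, box = bx)
  }
  net$backward <- function(dcls, dbox) {
    df <- L$ch1$bwd(L$cha$bwd(L$cls$bwd(dcls))) +
          L$bh1$bwd(L$bha$bwd(L$box$bwd(dbox)))
    for (s in rev(seq_len(n_stages))) df <- res_stage_bwd(L[[paste0("s", s)]], df)
    invisible(L$stem$bwd(L$stema$bwd(df)))
  }
  # map head cubes <-> flat per-anchor vectors (anchor order of make_anchors)
  net$flatten_heads <- function(out) {
    g <- dim(out$cls)[1]; A <- dim(out$cls)[3]
    n <- g * g * A
    scores_logit <- numeric(n); offs <- matrix(0, n, 4)
    k <- 1
    for (i in seq_len(g)) for (j in seq_len(g)) for (a in seq_len(A)) {
      scores_logit[k] <- out$cls[i, j, a]
      offs[k, ] <- out$box[i, j, ((a - 1) * 4 + 1):(a * 4)]
      k <- k + 1
    }
    list(logits = scores_logit, offsets = offs)
  }
  net$unflatten_grads <- function(dlogits, doffs, g, A) {
    dcls <- array(0, c(g, g, A)); dbox <- array(0, c(g, g, 4 * A))
    k <- 1
    for (i in seq_len(g)) for (j in seq_len(g)) for (a in seq_len(A)) {
      dcls[i, j, a] <- dlogits[k]
      dbox[i, j, ((a - 1) * 4 + 1):(a * 4)] <- doffs[k, ]
      k <- k + 1
    }
    list(dcls = dcls, dbox = dbox)
  }
  class(net) <- "detector_net"
  net
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
smooth_l1_grad <- function(x) pmax(pmin(x, 1), -1)

# loss + gradient cubes for one image; returns loss and pushes grads.
detector_step <- function(net, img, truth_box) {
  cfg <- net$config
  out <- net$forward(img)
  fl <- net$flatten_heads(out)
  p <- sigmoid(fl$logits)
  asg <- assign_anchors(net$anchors, truth_box, cfg$pos_iou, cfg$neg_iou)
  use <- !is.na(asg$cls)
  npos <- max(1, sum(asg$cls == 1, na.rm = TRUE))
  cls_loss <- sum(focal_loss(p[use], asg$cls[use], cfg$focal_alpha, cfg$focal_gamma))
  dlog <- numeric(length(p))
  dlog[use] <- focal_loss_grad_logit(p[use], asg$cls[use],
                                     cfg$focal_alpha, cfg$focal_gamma) / npos
  pos <- which(!is.na(asg$cls) & asg$cls == 1)
  doffs <- matrix(0, length(p), 4)
  reg_loss <- 0
  if (length(pos) > 0) {
    diffm <- fl$offsets[pos, , drop = FALSE] - asg$reg[pos, , drop = FALSE]
    reg_loss <- cfg$reg_weight * sum(smooth_l1(diffm))
    doffs[pos, ] <- cfg$reg_weight * smooth_l1_grad(diffm) / npos
  }
  g <- dim(out$cls)[1]; A <- dim(out$cls)[3]
  gr <- net$unflatten_grads(dlog, doffs, g, A)
  net$backward(gr$dcls, gr$dbox)
  (cls_loss + reg_loss) / npos
}

#' Train the lung-box detector
#'
#' Focal + smooth-L1 loss, Adam (lr from config), plateau scheduler
#' (decay `lr_decay` after `patience` stale epochs). Deterministic under the
#' config seed.
#'
#' @param dataset list of `list(image, box)`; images at
#'   `config$img_size`, boxes as [lung_box()] at that scale.
#' @param config a [detector_config()].
#' @param epochs override of `config$epochs`.
#' @param verbose print per-epoch loss.
#' @return trained `detector_net` with `$history`.
#' @export
train_detector <- function(dataset, config = detector_config(), epochs = NULL,
                           verbose = FALSE) {
  if (length(dataset) == 0) stopf("empty dataset")
  epochs <- epochs %||% config$epochs
  net <- build_detector(config)
  opt <- nn_adam(net$layers, lr = config$lr)
  sched <- plateau_scheduler(opt, patience = config$patience, factor = config$lr_decay)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(config$seed * 1000 + ep, sample(length(dataset)))
    losses <- numeric(0)
    i <- 1
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1, length(ord))]
      for (j in idx)
        losses <- c(losses, detector_step(net, dataset[[j]]$image, dataset[[j]]$box))
      opt$step()
      i <- i + config$batch_size
    }
    history[ep] <- mean(losses)
    sched$step(history[ep])
    if (verbose) message(sprintf("epoch %d loss %.4f lr %.2g", ep, history[ep], opt$lr))
  }
  net$history <- history
  net$optimizer_lr <- opt$lr
  net
}

#' Detect the lung box in an image
#'
#' Resizes to the detector's input resolution, runs NMS and takes the
#' highest-scoring detection. With `box_voting` (the default) the returned
#' box is the score-weighted average of all candidate boxes that overlap the
#' top detection (IoU >= `nms_iou`) and score at least half as much, which
#' averages out per-anchor regression noise. The box is mapped back to the
#' input resolution.
#'
#' @param img grayscale image.
#' @param net trained `detector_net`.
#' @param box_voting average overlapping high-score candidates (default
#'   TRUE).
#' @return a [lung_box()] at the input resolution.
#' @export
detect_lung <- function(img, net, box_voting = TRUE) {
  cfg <- net$config
  work <- resize_to(to_unit(img), c(cfg$img_size, cfg$img_size))
  out <- net$forward(work)
  fl <- net$flatten_heads(out)
  p <- sigmoid(fl$logits)
  det <- decode_and_nms(p, fl$offsets, net$anchors, cfg)
  if (length(det) == 0)
    stopf("no detection above score threshold %.2f; lower score_threshold",
          cfg$score_threshold)
  top <- det[[1]]
  if (box_voting) {
    sel <- which(p >= max(0.5 * top$score, cfg$score_threshold))
    boxes <- decode_boxes(net$anchors[sel, , drop = FALSE],
                          fl$offsets[sel, , drop = FALSE], cfg$img_size)
    ok <- vapply(seq_len(nrow(boxes)), function(i) {
      b <- lung_box(boxes[i, 1], boxes[i, 2], boxes[i, 3], boxes[i, 4])
      iou(b, top$box) >= cfg$nms_iou
    }, logical(1))
    w <- p[sel][ok] / sum(p[sel][ok])
    b <- colSums(boxes[ok, , drop = FALSE] * w)
    top$box <- lung_box(b["top"], b["bottom"], b["left"], b["right"])
  }
  box_rescale(top$box, from = cfg$img_size, to = dim(img))
}
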