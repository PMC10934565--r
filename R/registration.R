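# Deformable registration of the working (pre) crop onto the reference
# (post) crop. Displacement fields use the pull-back convention: the warped
# image samples the input at p + field(p), with bilinear interpolation and
# replicate-edge border handling. Two engines are provided: gradient ascent
# on a similarity metric over a dense field (classical), and a small U-Net
# that predicts the field in one pass (learned).

#' Warp an image through a displacement field
#'
#' `out(p) = img(p + field(p))`, bilinear, replicate border. A zero field is
#' the identity; a constant integer field is an exact array shift in the
#' interior.
#'
#' @param img image matrix.
#' @param field list with `drow` and `dcol` matrices (pixels), same grid.
#' @export
warp_image <- function(img, field) {
  if (!all(dim(img) == dim(field$drow)) || !all(dim(img) == dim(field$dcol)))
    stopf("field grid does not match image")
  gray_image(cpp_warp_bilinear(unclass_img(img) + 0.0, field$drow, field$dcol),
             img_depth(img))
}

zero_field <- function(nr, nc) list(drow = matrix(0, nr, nc), dcol = matrix(0, nr, nc))

#' Mean local normalized cross-correlation
#'
#' Mean over pixels of the signed squared correlation within a
#' `(2 radius + 1)^2` window (ANTs-style neighborhood correlation); windows
#' with zero variance in either image are skipped.
#'
#' @param a,b images of equal size.
#' @param radius window radius in pixels (default 4).
#' @return scalar in \[-1, 1\].
#' @export
local_ncc <- function(a, b, radius = 4) {
  if (!all(dim(a) == dim(b))) stopf("shape mismatch")
  cpp_local_ncc(unclass_img(a) + 0.0, unclass_img(b) + 0.0, radius, FALSE)$value
}

#' Joint-histogram mutual information (bits)
#'
#' `H(A) + H(B) - H(A,B)` from a joint intensity histogram of unit-range
#' images.
#'
#' @param a,b unit-range images of equal size.
#' @param bins histogram bins per axis (default 32).
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (!all(dim(a) == dim(b))) stopf("shape mismatch")
  cpp_mutual_information(unclass_img(to_unit(a)), unclass_img(to_unit(b)),
                         as.integer(bins), FALSE)$mi
}

registration_metrics <- function(working, reference) {
  c(psnr = psnr(gray_image(clamp01(working), "unit"), gray_image(clamp01(reference), "unit")),
    ssim = ssim(gray_image(clamp01(working), "unit"), gray_image(clamp01(reference), "unit")),
    ncc = ncc(working, reference))
}

#' Classical registration configuration
#'
#' @param metric similarity to ascend: `"local_ncc"` (default) or
#'   `"mutual_information"`. The two are never combined.
#' @param radius local-NCC window radius.
#' @param bins MI histogram bins.
#' @param step maximum per-iteration displacement update in pixels.
#' @param iterations gradient-ascent iterations per level.
#' @param smooth_sigma Gaussian smoothing of the field after each update, px.
#' @param levels multi-resolution factors, coarse to fine; `c(4, 1)` runs a
#'   quarter-scale pass to capture large shifts, then refines at full scale.
#' @param presmooth Gaussian blur applied to both images before
#'   registration, px.
#' @export
classical_register_config <- function(metric = c("local_ncc", "mutual_information"),
                                      radius = 4, bins = 32, step = 0.25,
                                      iterations = 100, smooth_sigma = 2,
                                      levels = c(4, 1), presmooth = 1) {
  list(metric = match.arg(metric), radius = radius, bins = bins, step = step,
       iterations = iterations, smooth_sigma = smooth_sigma, levels = levels,
       presmooth = presmooth)
}

metric_value_grad <- function(warped, reference, cfg) {
  if (cfg$metric == "local_ncc") {
    r <- cpp_local_ncc(warped, reference, cfg$radius, TRUE)
    list(value = r$value, grad = r$grad_a)
  } else {
    r <- cpp_mutual_information(clamp01(warped), clamp01(reference), cfg$bins, TRUE)
    list(value = r$mi, grad = r$grad_a)
  }
}

#' Classical displacement-field registration
#'
#' Dense-field gradient ascent on the chosen similarity metric: the field
#' starts at zero, each iteration moves every pixel along the metric
#' gradient (normalized so the largest update is `step` pixels) and the
#' field is Gaussian-smoothed to stay regular. The best-metric field over
#' the run is returned. Optionally runs coarse-to-fine.
#'
#' @param working moving image (unit range), typically histogram-matched.
#' @param reference fixed image (unit range).
#' @param config a [classical_register_config()].
#' @return `registration_result`: `field`, `warped`, `metrics` (before/
#'   after), `metric_trace`, `iterations`.
#' @export
classical_register <- function(working, reference,
                               config = classical_register_config()) {
  if (!all(dim(working) == dim(reference))) stopf("shape mismatch")
  w0 <- unclass_img(to_unit(working)); r0 <- unclass_img(to_unit(reference))
  nr <- nrow(w0); nc <- ncol(w0)
  before <- registration_metrics(w0, r0)
  field <- NULL
  trace <- numeric(0)
  for (lev in config$levels) {
    sr <- max(1L, as.integer(round(nr / lev))); sc <- max(1L, as.integer(round(nc / lev)))
    wl <- if (lev > 1) cpp_resize_bilinear(w0, sr, sc) else w0
    rl <- if (lev > 1) cpp_resize_bilinear(r0, sr, sc) else r0
    if (config$presmooth > 0) {
      wl <- cpp_gaussian_blur(wl, config$presmooth)
      rl <- cpp_gaussian_blur(rl, config$presmooth)
    }
    if (is.null(field)) {
      field <- zero_field(sr, sc)
    } else {
      scale_r <- sr / nrow(field$drow); scale_c <- sc / ncol(field$dcol)
      field <- list(drow = cpp_resize_bilinear(field$drow, sr, sc) * scale_r,
                    dcol = cpp_resize_bilinear(field$dcol, sr, sc) * scale_c)
    }
    best <- list(value = -Inf, field = field)
    for (it in seq_len(config$iterations)) {
      wg <- cpp_warp_with_grad(wl, field$drow, field$dcol)
      mg <- metric_value_grad(wg$warped, rl, config)
      trace <- c(trace, mg$value)
      if (mg$value > best$value) best <- list(value = mg$value, field = field)
      grow <- mg$grad * wg$grad_row
      gcol <- mg$grad * wg$grad_col
      gmax <- max(sqrt(grow^2 + gcol^2))
      if (gmax <= 0) break
      field$drow <- cpp_gaussian_blur(field$drow + config$step * grow / gmax,
                                      config$smooth_sigma)
      field$dcol <- cpp_gaussian_blur(field$dcol + config$step * gcol / gmax,
                                      config$smooth_sigma)
    }
    # evaluate the final field too
    wg <- cpp_warp_with_grad(wl, field$drow, field$dcol)
    mg <- metric_value_grad(wg$warped, rl, config)
    if (mg$value > best$value) best <- list(value = mg$value, field = field)
    field <- best$field
  }
  lev_last <- config$levels[length(config$levels)]
  if (lev_last > 1) {
    field <- list(drow = cpp_resize_bilinear(field$drow, nr, nc) * lev_last,
                  dcol = cpp_resize_bilinear(field$dcol, nr, nc) * lev_last)
  }
  warped <- cpp_warp_bilinear(w0, field$drow, field$dcol)
  structure(list(field = field, warped = gray_image(warped, "unit"),
                 metrics = list(before = before,
                                after = registration_metrics(warped, r0)),
                 metric_trace = trace, iterations = length(trace),
                 method = "classical"),
            class = "registration_result")
}

# ---- learned registration (U-Net) -----------------------------------------

#' Build the registration U-Net
#'
#' Encoder of stride-2 convolutions halving the resolution four times (to
#' 1/16 of the input), decoder of convolutions + nearest-neighbour
#' upsampling with skip concatenations, Leaky ReLU activations throughout,
#' and a zero-initialized final layer emitting a 2-channel displacement
#' field -- so an untrained network is the identity transform.
#'
#' @param enc,dec encoder/decoder channel widths (length 4 each).
#' @param seed RNG seed for weight initialization.
#' @return a `voxelmorph_net` object with `$predict(moving, fixed)`.
#' @export
voxelmorph_net <- function(enc = c(16, 32, 32, 32), dec = c(32, 32, 32, 16),
                           seed = 1) {
  net <- with_seed(seed, {
    L <- list(
      e1 = nn_conv(2, enc[1], k = 3, stride = 2), a1 = nn_lrelu(),
      e2 = nn_conv(enc[1], enc[2], k = 3, stride = 2), a2 = nn_lrelu(),
      e3 = nn_conv(enc[2], enc[3], k = 3, stride = 2), a3 = nn_lrelu(),
      e4 = nn_conv(enc[3], enc[4], k = 3, stride = 2), a4 = nn_lrelu(),
      d1 = nn_conv(enc[4], dec[1], k = 3), da1 = nn_lrelu(), u1 = nn_upsample2(),
      d2 = nn_conv(dec[1] + enc[3], dec[2], k = 3), da2 = nn_lrelu(), u2 = nn_upsample2(),
      d3 = nn_conv(dec[2] + enc[2], dec[3], k = 3), da3 = nn_lrelu(), u3 = nn_upsample2(),
      d4 = nn_conv(dec[3] + enc[1], dec[4], k = 3), da4 = nn_lrelu(), u4 = nn_upsample2(),
      f1 = nn_conv(dec[4] + 2, 16, k = 3), fa1 = nn_lrelu(),
      flow = nn_conv(16, 2, k = 3, init = "zero"))
    L
  })
  obj <- list(kind = "voxelmorph", config = list(enc = enc, dec = dec), layers = net)
  obj$forward <- function(moving, fixed) {
    L <- net
    x <- array(c(moving, fixed), c(nrow(moving), ncol(moving), 2))
    if (any(dim(moving) %% 16 != 0)) stopf("input size must be divisible by 16")
    h1 <- L$a1$fwd(L$e1$fwd(x))
    h2 <- L$a2$fwd(L$e2$fwd(h1))
    h3 <- L$a3$fwd(L$e3$fwd(h2))
    h4 <- L$a4$fwd(L$e4$fwd(h3))
    y <- L$u1$fwd(L$da1$fwd(L$d1$fwd(h4)))
    y <- concat_c(y, h3)
    y <- L$u2$fwd(L$da2$fwd(L$d2$fwd(y)))
    y <- concat_c(y, h2)
    y <- L$u3$fwd(L$da3$fwd(L$d3$fwd(y)))
    y <- concat_c(y, h1)
    y <- L$u4$fwd(L$da4$fwd(L$d4$fwd(y)))
    y <- concat_c(y, x)
    y <- L$fa1$fwd(L$f1$fwd(y))
    flow <- L$flow$fwd(y)
    list(field = list(drow = flow[, , 1], dcol = flow[, , 2]),
         split = list(c1 = dim(h3)[3], c2 = dim(h2)[3], c3 = dim(h1)[3]))
  }
  obj$predict <- function(moving, fixed) obj$forward(moving, fixed)$field
  class(obj) <- "voxelmorph_net"
  obj
}

concat_c <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}
# split channels: first (total - keep_last) channels in $a, last keep_last in $b
split_c <- function(x, keep_last) {
  n <- dim(x)[3]
  list(a = x[, , seq_len(n - keep_last), drop = FALSE],
       b = x[, , (n - keep_last + 1):n, drop = FALSE])
}

# Full backward pass through the U-Net given dL/dfield.
vm_backward <- function(net, dfield) {
  L <- net$layers
  dflow <- array(c(dfield$drow, dfield$dcol),
                 c(nrow(dfield$drow), ncol(dfield$drow), 2))
  dy <- L$f1$bwd(L$fa1$bwd(L$flow$bwd(dflow)))
  sp <- split_c(dy, 2)                         # drop grad into the raw input
  dy <- L$d4$bwd(L$da4$bwd(L$u4$bwd(sp$a)))
  sp <- split_c(dy, nrow(L$e1$W))              # skip from h1
  dh1_skip <- sp$b
  dy <- L$d3$bwd(L$da3$bwd(L$u3$bwd(sp$a)))
  sp <- split_c(dy, nrow(L$e2$W))              # skip from h2
  dh2_skip <- sp$b
  dy <- L$d2$bwd(L$da2$bwd(L$u2$bwd(sp$a)))
  sp <- split_c(dy, nrow(L$e3$W))              # skip from h3
  dh3_skip <- sp$b
  dh4 <- L$d1$bwd(L$da1$bwd(L$u1$bwd(sp$a)))
  dh3 <- dh3_skip + L$e4$bwd(L$a4$bwd(dh4))
  dh2 <- dh2_skip + L$e3$bwd(L$a3$bwd(dh3))
  dh1 <- dh1_skip + L$e2$bwd(L$a2$bwd(dh2))
  invisible(L$e1$bwd(L$a1$bwd(dh1)))
}

# Smoothness penalty lambda * mean of squared forward differences of both
# field components; returns value and gradient.
smoothness_penalty <- function(field, lambda) {
  val <- 0
  grads <- list()
  for (nm in c("drow", "dcol")) {
    u <- field[[nm]]
    dr <- u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE]
    dc <- u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE]
    npx <- length(u)
    val <- val + (sum(dr^2) + sum(dc^2)) / npx
    g <- matrix(0, nrow(u), ncol(u))
    g[-nrow(u), ] <- g[-nrow(u), ] - 2 * dr / npx
    g[-1, ] <- g[-1, ] + 2 * dr / npx
    g[, -ncol(u)] <- g[, -ncol(u)] - 2 * dc / npx
    g[, -1] <- g[, -1] + 2 * dc / npx
    grads[[nm]] <- g
  }
  list(value = lambda * val, grad = lapply(grads, function(g) lambda * g))
}

# Unsupervised loss for one pair: -similarity + lambda * smoothness.
vm_loss_and_grads <- function(net, moving, fixed, lambda, sim = "local_ncc",
                              radius = 4) {
  fw <- net$forward(moving, fixed)
  field <- fw$field
  wg <- cpp_warp_with_grad(moving, field$drow, field$dcol)
  if (sim == "local_ncc") {
    m <- cpp_local_ncc(wg$warped, fixed, radius, TRUE)
    sim_val <- m$value
    dwarped <- -m$grad_a
  } else {
    d <- wg$warped - fixed
    sim_val <- -mean(d^2)
    dwarped <- 2 * d / length(d)
  }
  sp <- smoothness_penalty(field, lambda)
  loss <- -sim_val + sp$value
  dfield <- list(drow = dwarped * wg$grad_row + sp$grad$drow,
                 dcol = dwarped * wg$grad_col + sp$grad$dcol)
  vm_backward(net, dfield)
  list(loss = loss, similarity = sim_val, field = field)
}

#' Train the registration U-Net
#'
#' Unsupervised training: minimizes `-similarity(warp(moving, field), fixed)
#' + lambda * mean(|grad field|^2)` with Adam.
#'
#' @param pairs list of `list(moving, fixed)` unit-range matrices.
#' @param net a [voxelmorph_net()]; built fresh if `NULL`.
#' @param epochs,batch_size,lr Adam schedule (defaults 400 / 8 / 1e-4).
#' @param lambda smoothness weight (default 0.01).
#' @param sim `"local_ncc"` or `"mse"`.
#' @param radius local-NCC window radius.
#' @param seed RNG seed (weight init and shuffling).
#' @param verbose print per-epoch loss.
#' @return the trained net, with `$history` (mean loss per epoch).
#' @export
train_voxelmorph <- function(pairs, net = NULL, epochs = 400, batch_size = 8,
                             lr = 1e-4, lambda = 0.01, sim = "local_ncc",
                             radius = 4, seed = 1, verbose = FALSE) {
  if (length(pairs) == 0) stopf("empty training set")
  if (is.null(net)) net <- voxelmorph_net(seed = seed)
  opt <- nn_adam(net$layers, lr = lr)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed * 10000 + ep, sample(length(pairs)))
    losses <- numeric(0)
    i <- 1
    while (i <= length(ord)) {
      idx <- ord[i:min(i + batch_size - 1, length(ord))]
      for (j in idx) {
        r <- vm_loss_and_grads(net, pairs[[j]]$moving, pairs[[j]]$fixed,
                               lambda, sim, radius)
        losses <- c(losses, r$loss)
      }
      opt$step()
      i <- i + batch_size
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d loss %.5f", ep, history[ep]))
  }
  net$history <- history
  net
}

#' Register a pre/post pair
#'
#' Histogram-matches the working (pre) crop to the reference (post) crop,
#' then runs the chosen registration engine and reports PSNR/SSIM/NCC before
#' and after.
#'
#' @param working,reference unit-range crops of equal size.
#' @param method `"classical"` or `"learned"`.
#' @param config [classical_register_config()] for the classical engine.
#' @param net trained [voxelmorph_net()] for the learned engine.
#' @return a `registration_result`.
#' @export
register_pair <- function(working, reference, method = c("classical", "learned"),
                          config = classical_register_config(), net = NULL) {
  method <- match.arg(method)
  matched <- unclass_img(to_unit(histogram_match(to_unit(working), to_unit(reference))))
  ref <- unclass_img(to_unit(reference))
  if (method == "classical") {
    res <- classical_register(matched, ref, config)
  } else {
    if (is.null(net)) stopf("learned registration requires a trained net")
    field <- net$predict(matched, ref)
    warped <- cpp_warp_bilinear(matched, field$drow, field$dcol)
    res <- structure(list(field = field, warped = gray_image(warped, "unit"),
                          metrics = list(before = registration_metrics(matched, ref),
                                         after = registration_metrics(warped, ref)),
                          iterations = 0, method = "learned"),
                     class = "registration_result")
  }
  res$working_matched <- gray_image(matched, "unit")
  res
}

#' @export
print.registration_result <- function(x, ...) {
  b <- x$metrics$before; a <- x$metrics$after
  cat(sprintf("<registration_result %s: PSNR %.2f->%.2f dB, SSIM %.4f->%.4f, NCC %.4f->%.4f>\n",
              x$method, b["psnr"], a["psnr"], b["ssim"], a["ssim"],
              b["ncc"], a["ncc"]))
  invisible(x)
}
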