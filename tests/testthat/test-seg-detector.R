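test_that("focal loss closed forms and properties", {
  # near-perfect positive prediction -> loss near zero
  expect_lt(focal_loss(1 - 1e-6, 1), 1e-10)
  # gamma = 0, alpha = 0.5 reduces to half the binary cross-entropy
  p <- c(0.2, 0.6, 0.9); t <- c(1, 0, 1)
  bce <- -(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(focal_loss(p, t, alpha = 0.5, gamma = 0), 0.5 * bce,
               tolerance = 1e-9)
  # printed example: target 1, p 0.9, alpha 0.25, gamma 2
  expect_equal(focal_loss(0.9, 1, 0.25, 2), 0.25 * 0.1^2 * (-log(0.9)),
               tolerance = 1e-12)
  expect_equal(focal_loss(0.9, 1, 0.25, 2), 2.634e-4, tolerance = 1e-3)
  # non-negative, decreasing in p_t for positives
  ps <- seq(0.05, 0.95, by = 0.05)
  fl <- focal_loss(ps, rep(1, length(ps)))
  expect_true(all(fl >= 0))
  expect_true(all(diff(fl) < 0))
})

test_that("anchor assignment thresholds and regression targets", {
  anchors <- rbind(c(10, 50, 10, 50),    # identical to truth
                   c(100, 120, 100, 120),  # disjoint
                   c(10, 50, 14.5, 54.5))  # partial overlap
  colnames(anchors) <- c("top", "bottom", "left", "right")
  truth <- lung_box(10, 50, 10, 50)
  asg <- assign_anchors(anchors, truth, pos_iou = 0.5, neg_iou = 0.4)
  expect_equal(asg$cls[1], 1)
  expect_equal(asg$reg[1, ], rep(0, 4), ignore_attr = TRUE)
  expect_equal(asg$cls[2], 0)
  # anchor 3: overlap width 35.5/44.5 -> IoU 35.5*40 / (1600*2 - 35.5*40)
  i3 <- (35.5 * 40) / (1600 * 2 - 35.5 * 40)
  expect_equal(asg$ious[3], i3)
  expect_gt(i3, 0.5)
  expect_equal(asg$cls[3], 1)
  # best anchor is always positive even with strict thresholds
  asg2 <- assign_anchors(anchors, truth, pos_iou = 1, neg_iou = 0)
  expect_equal(asg2$cls[1], 1)
})

test_that("decode + NMS keeps the right survivors", {
  cfg <- detector_config(img_size = 128, score_threshold = 0.1, nms_iou = 0.5)
  anchors <- rbind(c(10, 50, 10, 50), c(10, 50, 10, 50), c(80, 120, 80, 120))
  colnames(anchors) <- c("top", "bottom", "left", "right")
  zero_off <- matrix(0, 3, 4)
  # duplicate boxes: one survivor with the higher score
  det <- decode_and_nms(c(0.9, 0.8, 0.05), zero_off, anchors, cfg)
  expect_length(det, 1)
  expect_equal(det[[1]]$score, 0.9)
  # disjoint boxes both survive, in descending score order
  det2 <- decode_and_nms(c(0.6, 0.05, 0.9), zero_off, anchors, cfg)
  expect_length(det2, 2)
  expect_equal(det2[[1]]$score, 0.9)
  expect_lt(iou(det2[[1]]$box, det2[[2]]$box), cfg$nms_iou)
  # A suppresses B but not C
  anchors3 <- rbind(c(10, 50, 10, 50), c(12, 52, 12, 52), c(40, 80, 40, 80))
  colnames(anchors3) <- c("top", "bottom", "left", "right")
  det3 <- decode_and_nms(c(0.9, 0.8, 0.7), matrix(0, 3, 4), anchors3, cfg)
  expect_length(det3, 2)
  expect_equal(vapply(det3, `[[`, 0, "score"), c(0.9, 0.7))
  # nothing above threshold -> empty list
  expect_length(decode_and_nms(c(0.01, 0.02, 0.03), zero_off, anchors, cfg), 0)
})

test_that("plateau scheduler decays the learning rate after patience stale epochs", {
  opt <- new.env(); opt$lr <- 1e-4
  s <- ld$plateau_scheduler(opt, patience = 3, factor = 0.1)
  s$step(1.0)               # best
  for (i in 1:3) s$step(1.0)  # three non-improving evaluations
  expect_equal(opt$lr, 1e-5, tolerance = 1e-12)
})

test_that("one optimizer step on a small batch decreases the detector loss", {
  cfg <- detector_config(img_size = 64, channels = c(4, 8, 8), stride = 8,
                         base_scale = 5, scales = c(0.8, 1, 1.25),
                         head_channels = 8, seed = 11)
  net <- build_detector(cfg)
  sp <- ld$with_seed(300, ld$random_pair_spec(64, 0, 300))
  ph <- generate_phantom(sp)
  opt <- ld$nn_adam(net$layers, lr = 1e-4)
  l0 <- ld$detector_step(net, ph$image, ph$truth$lung_box)
  opt$step()
  l1 <- ld$detector_step(net, ph$image, ph$truth$lung_box)
  expect_lt(l1, l0)
  # detection on pure noise with an absurd threshold errors with guidance
  cfg2 <- cfg; cfg2$score_threshold <- 0.999
  net$config <- cfg2
  noise <- gray_image(matrix(ld$with_seed(1, runif(64 * 64)), 64), "unit")
  expect_error(detect_lung(noise, net), "score_threshold")
})

test_that("detector model state round-trips through the raw container", {
  cfg <- detector_config(img_size = 64, channels = c(4, 8, 8), stride = 8,
                         head_channels = 8, seed = 12)
  net <- build_detector(cfg)
  f <- tempfile(fileext = ".bin")
  save_model(net, f)
  net2 <- build_detector(detector_config(img_size = 64, channels = c(4, 8, 8),
                                         stride = 8, head_channels = 8,
                                         seed = 99))
  load_model(net2, f)
  img <- gray_image(matrix(ld$with_seed(2, runif(64 * 64)), 64), "unit")
  o1 <- net$forward(img); o2 <- net2$forward(img)
  expect_identical(o1$cls, o2$cls)
  expect_identical(o1$box, o2$box)
  unlink(c(f, paste0(f, ".json")))
})
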