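# End-to-end orchestration: dataset simulation to disk, displacement-field
# containers, pipeline configuration and the segment -> crop -> match ->
# register -> compare -> classify chain.

#' Write a displacement field as a raw float container with JSON sidecar
#'
#' Little-endian float32, row-displacement plane first then
#' column-displacement plane, column-major within each plane; the sidecar
#' (`<path>.json`) records shape and ordering.
#'
#' @param field list `(drow, dcol)`.
#' @param path output path (conventionally `.f32`).
#' @export
write_field <- function(field, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(field$drow), con, size = 4, endian = "little")
  writeBin(as.numeric(field$dcol), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(format = "lungdiff-field-v1", shape = dim(field$drow),
         order = c("row-displacement", "column-displacement"),
         storage = "float32 little-endian, column-major per plane"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  drow <- matrix(readBin(con, "double", n, size = 4, endian = "little"), meta$shape[1])
  dcol <- matrix(readBin(con, "double", n, size = 4, endian = "little"), meta$shape[1])
  list(drow = drow, dcol = dcol)
}

#' Simulate a phantom pair dataset on disk
#'
#' Writes `n_pairs` pre/post PNG pairs plus ground truth: one displacement
#' field container per pair, one boxes CSV (post-geometry truth boxes, one
#' row per image) and one labels CSV (12 binary columns per pair). Pair
#' specs vary lung geometry and lesions under the given seed; a fraction of
#' pairs receives a new lesion in the post image (labelled "Nodule").
#'
#' @param out_dir output directory (created).
#' @param n_pairs number of pairs.
#' @param image_size square size in px (default 256).
#' @param lesion_prob probability a pair gains a new post-image lesion.
#' @param seed master seed; the dataset is byte-identical under re-run.
#' @param write_masks also write lung-mask PNGs under `masks/`.
#' @return invisibly, a data.frame manifest.
#' @export
simulate_dataset <- function(out_dir, n_pairs, image_size = 256,
                             lesion_prob = 0.5, seed = 1, write_masks = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_masks) dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  boxes <- NULL; labels <- NULL; manifest <- NULL
  for (i in seq_len(n_pairs)) {
    sp <- with_seed(seed * 100000 + i, random_pair_spec(image_size, lesion_prob,
                                                        seed * 100000 + i))
    pair <- generate_pair(sp)
    pre_id <- sprintf("pair%03d_pre", i)
    post_id <- sprintf("pair%03d_post", i)
    write_gray_png(pair$pre, file.path(out_dir, paste0(pre_id, ".png")))
    write_gray_png(pair$post, file.path(out_dir, paste0(post_id, ".png")))
    write_field(pair$truth$true_field, file.path(out_dir, sprintf("pair%03d_field.f32", i)))
    if (write_masks)
      write_gray_png(gray_image(pair$truth$lung_mask + 0.0, "unit"),
                     file.path(out_dir, "masks", paste0(post_id, "_lungmask.png")))
    bx <- pair$truth$lung_box
    bxp <- pair$truth$lung_box_pre
    boxes <- rbind(boxes,
                   data.frame(image_id = post_id, top = bx$top, bottom = bx$bottom,
                              left = bx$left, right = bx$right),
                   data.frame(image_id = pre_id, top = bxp$top, bottom = bxp$bottom,
                              left = bxp$left, right = bxp$right))
    lab <- as.data.frame(as.list(pair$truth$labels))
    labels <- rbind(labels, cbind(data.frame(image_id = post_id), lab))
    manifest <- rbind(manifest, data.frame(pair = i, pre = pre_id, post = post_id))
  }
  write.csv(boxes, file.path(out_dir, "boxes.csv"), row.names = FALSE)
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

# A randomized phantom-pair spec emulating between-visit variation: jittered
# lung geometry, baseline lesions in both images, optional new post lesion,
# smooth deformation, small shift, gain/offset drift.
random_pair_spec <- function(image_size, lesion_prob, seed) {
  sc <- image_size / 512
  jit <- function(x, s) x + runif(length(x), -s, s)
  lungs <- list(
    list(center = jit(c(0.52, 0.32), 0.02), semi = jit(c(0.30, 0.155), 0.015),
         intensity = 0.30),
    list(center = jit(c(0.52, 0.68), 0.02), semi = jit(c(0.30, 0.155), 0.015),
         intensity = 0.30))
  new_lesions <- list()
  if (runif(1) < lesion_prob) {
    lung <- lungs[[sample(2, 1)]]
    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.6
    ctr <- lung$center + rad * c(lung$semi[1] * cos(ang), lung$semi[2] * sin(ang))
    new_lesions <- list(list(center = ctr, radius = max(4, 14 * sc),
                             delta = runif(1, 0.18, 0.30)))
  }
  phantom_spec(image_size = image_size, lung_params = lungs,
               lesion_list = list(), new_lesions = new_lesions,
               noise_sigma = 0.01,
               deformation = list(spacing = max(16, 64 * sc), max_mag = 6 * sc),
               global_shift = round(runif(2, -4, 4) * sc),
               gain = runif(1, 0.95, 1.05), offset = runif(1, -0.03, 0.03),
               seed = seed)
}

#' Pipeline configuration
#'
#' One place for every stage parameter; serializes to JSON and back
#' round-trip stable.
#'
#' @param crop_size working resolution for registration/comparison crops.
#' @param seg_method `"classical"` or `"detector"`.
#' @param seg_model path to a trained detector (required for
#'   `"detector"`).
#' @param register_method `"classical"` or `"learned"`.
#' @param register_model path to trained registration net weights.
#' @param compare_mode `"linear"`, `"nonlinear-1"` or `"nonlinear-2"`.
#' @param blend heat-map overlay opacity.
#' @param classifier_model optional trained classifier weights; the
#'   classification stage is skipped when absent.
#' @param seed master seed.
#' @param classical,register_classical stage parameter groups.
#' @export
pipeline_config <- function(crop_size = 512, seg_method = "classical",
                            seg_model = NULL, register_method = "classical",
                            register_model = NULL,
                            compare_mode = "linear", blend = 0.5,
                            classifier_model = NULL, seed = 1,
                            classical = classical_config(),
                            register_classical = classical_register_config()) {
  list(crop_size = crop_size, seg_method = seg_method, seg_model = seg_model,
       register_method = register_method, register_model = register_model,
       compare_mode = compare_mode, blend = blend,
       classifier_model = classifier_model, seed = seed,
       classical = classical, register_classical = register_classical)
}

#' @rdname pipeline_config
#' @param config configuration list.
#' @param path JSON file path.
#' @export
config_save <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
config_load <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # merge onto defaults, then drop unset (NULL) fields so that repeated
  # save/load cycles are stable
  out <- modifyList(pipeline_config(), cfg)
  out[!vapply(out, is.null, logical(1))]
}

crop_box <- function(img, box) {
  unclass_img(img)[(box$top + 1):box$bottom, (box$left + 1):box$right, drop = FALSE]
}

#' Run the full comparison pipeline on one pre/post pair
#'
#' Stages: lung segmentation of both images, crop + resize to the working
#' resolution, histogram matching of the pre crop, deformable registration,
#' difference-map computation and heat-map rendering, and (when a classifier
#' is supplied) multi-label disease prediction. Every intermediate artifact
#' is written to `out_dir`, and the JSON report carries per-stage timings,
#' registration metrics before/after and the clipped-pixel fraction.
#'
#' @param pre_path,post_path paths to the PNG images (or matrices).
#' @param out_dir artifact directory.
#' @param config a [pipeline_config()].
#' @param classifier optional in-memory trained classifier (overrides
#'   `config$classifier_model`).
#' @param register_net optional in-memory registration net.
#' @return report list (also written to `report.json`).
#' @export
run_pipeline <- function(pre_path, post_path, out_dir,
                         config = pipeline_config(), classifier = NULL,
                         register_net = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    t_all[[name]] <<- round(tic() - t0, 3)
    r
  }
  pre <- if (is.character(pre_path)) read_gray_png(pre_path) else to_unit(pre_path)
  post <- if (is.character(post_path)) read_gray_png(post_path) else to_unit(post_path)

  seg <- stage("segment", {
    if (config$seg_method == "classical") {
      list(pre = segment_classical(pre, config$classical)$box,
           post = segment_classical(post, config$classical)$box)
    } else {
      if (is.null(config$seg_model)) stopf("detector model path missing")
      dcfg <- detector_config()
      dnet <- build_detector(dcfg)
      load_model(dnet, config$seg_model)
      list(pre = detect_lung(pre, dnet), post = detect_lung(post, dnet))
    }
  })
  boxes_csv <- file.path(out_dir, "boxes.csv")
  write.csv(data.frame(image_id = c("pre", "post"),
                       top = c(seg$pre$top, seg$post$top),
                       bottom = c(seg$pre$bottom, seg$post$bottom),
                       left = c(seg$pre$left, seg$post$left),
                       right = c(seg$pre$right, seg$post$right)),
            boxes_csv, row.names = FALSE)

  crops <- stage("crop", {
    cs <- c(config$crop_size, config$crop_size)
    list(pre = resize_to(gray_image(crop_box(pre, seg$pre), "unit"), cs),
         post = resize_to(gray_image(crop_box(post, seg$post), "unit"), cs))
  })

  reg <- stage("register", {
    if (config$register_method == "classical") {
      register_pair(crops$pre, crops$post, "classical", config$register_classical)
    } else {
      net <- register_net
      if (is.null(net)) {
        if (is.null(config$register_model)) stopf("registration model missing")
        net <- voxelmorph_net()
        load_model(net, config$register_model)
      }
      register_pair(crops$pre, crops$post, "learned", net = net)
    }
  })
  write_gray_png(reg$warped, file.path(out_dir, "warped.png"))
  write_field(reg$field, file.path(out_dir, "field.f32"))

  cmp <- stage("compare", {
    dm <- difference_map(unclass_img(reg$warped), unclass_img(crops$post),
                         config$compare_mode)
    hl <- highlight(crops$post, dm$D_star)
    overlay <- render_heatmap(dm$D_star, crops$post, config$blend)
    write_gray_png(gray_image(dm$D_star, "unit"), file.path(out_dir, "diff.png"))
    write_gray_png(gray_image(hl$imgnew, "unit"), file.path(out_dir, "imgnew.png"))
    png::writePNG(overlay, file.path(out_dir, "overlay.png"))
    list(dm = dm, highlight = hl)
  })

  preds <- NULL
  if (!is.null(classifier) || !is.null(config$classifier_model)) {
    preds <- stage("classify", {
      net <- classifier
      if (is.null(net)) {
        net <- build_single_input(classifier_config())
        load_model(net, config$classifier_model)
      }
      sz <- net$config$input_size
      post_in <- resize_to(crops$post, c(sz, sz))
      pr <- if (net$kind == "classifier_dual") {
        diff_in <- resize_to(gray_image(cmp$dm$D_star, "unit"), c(sz, sz))
        net$predict(post_in, diff_in)
      } else net$predict(post_in)
      names(pr) <- DISEASE_CLASSES
      write.csv(data.frame(image_id = "post", t(pr)),
                file.path(out_dir, "predictions.csv"), row.names = FALSE)
      pr
    })
  }

  report <- list(
    boxes = list(pre = unclass(seg$pre)[1:4], post = unclass(seg$post)[1:4]),
    registration = reg$metrics,
    clip_frac = cmp$highlight$clip_frac,
    compare_mode = config$compare_mode,
    predictions = as.list(preds),
    timings_s = t_all)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
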