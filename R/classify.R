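# Multi-label thoracic-disease classification. Two architectures share a
# densely-connected convolutional trunk (4 dense blocks, 3 transition
# layers, final 1x1 reduction to 16 channels, global average pooling, a
# 12-way sigmoid head):
#   single-input -- classifies one image (post image or a difference image);
#   dual-input   -- adds a second path that turns the difference image into
#                   per-channel weights w and rescales the stem features by
#                   (1 + w) ("operation block") before the shared trunk.
# Loss is per-class binary cross-entropy (multi-label; no softmax coupling).

# Densely connected block: each internal layer convolves the concatenation
# of everything before it and appends `growth` channels.
nn_dense_block <- function(in_c, growth, n_layers) {
  e <- new.env(parent = emptyenv())
  e$type <- "block"
  e$convs <- lapply(seq_len(n_layers), function(i)
    nn_conv(in_c + (i - 1) * growth, growth, k = 3))
  e$acts <- lapply(seq_len(n_layers), function(i) nn_lrelu())
  e$param_layers <- e$convs
  e$out_c <- in_c + n_layers * growth
  e$fwd <- function(x) {
    feats <- list(x)
    for (i in seq_along(e$convs)) {
      inp <- Reduce(concat_c, feats)
      feats[[i + 1]] <- e$acts[[i]]$fwd(e$convs[[i]]$fwd(inp))
    }
    e$n_in <- dim(x)[3]
    Reduce(concat_c, feats)
  }
  e$bwd <- function(dy) {
    growth_c <- as.integer((dim(dy)[3] - e$n_in) / length(e$convs))
    # split incoming grad into segments [x, o1, ..., oL]
    segs <- list()
    start <- 1
    widths <- c(e$n_in, rep(growth_c, length(e$convs)))
    for (w in widths) {
      segs[[length(segs) + 1]] <- dy[, , start:(start + w - 1), drop = FALSE]
      start <- start + w
    }
    for (i in rev(seq_along(e$convs))) {
      dinp <- e$convs[[i]]$bwd(e$acts[[i]]$bwd(segs[[i + 1]]))
      # dinp covers segments 1..i; accumulate
      start <- 1
      for (s in seq_len(i)) {
        w <- widths[s]
        segs[[s]] <- segs[[s]] + dinp[, , start:(start + w - 1), drop = FALSE]
        start <- start + w
      }
    }
    segs[[1]]
  }
  e
}

#' Classifier configuration
#'
#' @param input_size square input resolution (full profile 512; desk tests
#'   use 64).
#' @param stem_channels channels after the stem convolution.
#' @param growth dense-block growth rate.
#' @param block_layers layers in each of the 4 dense blocks.
#' @param n_classes number of disease labels (12).
#' @param lr,lr_decay,patience,epochs,batch_size training schedule
#'   (defaults: Adam 1e-4, plateau 0.1/3, 40 epochs, batch 2).
#' @param seed weight-init seed.
#' @export
classifier_config <- function(input_size = 64, stem_channels = 8, growth = 6,
                              block_layers = c(2, 2, 2, 2), n_classes = 12,
                              lr = 1e-4, lr_decay = 0.1, patience = 3,
                              epochs = 40, batch_size = 2, seed = 1) {
  list(input_size = input_size, stem_channels = stem_channels, growth = growth,
       block_layers = block_layers, n_classes = n_classes, lr = lr,
       lr_decay = lr_decay, patience = patience, epochs = epochs,
       batch_size = batch_size, seed = seed)
}

#' Channel-weighting fusion ("operation block")
#'
#' Multiplies each channel of the primary feature maps by `1 + w[c]`, where
#' `w` comes from the secondary input path. With `w = 0` the block is the
#' identity and the dual network collapses to single-input behavior.
#'
#' @param F1 feature array `(H, W, C)`.
#' @param w numeric weight vector of length C.
#' @return rescaled feature array.
#' @export
operation_block <- function(F1, w) {
  if (dim(F1)[3] != length(w)) stopf("channel mismatch: %d maps, %d weights",
                                     dim(F1)[3], length(w))
  out <- F1
  for (c in seq_along(w)) out[, , c] <- F1[, , c] * (1 + w[c])
  out
}

build_trunk <- function(cfg) {
  c0 <- cfg$stem_channels
  trunk <- list()
  cc <- c0
  for (b in 1:4) {
    blk <- nn_dense_block(cc, cfg$growth, cfg$block_layers[b])
    cc <- blk$out_c
    trunk[[paste0("block", b)]] <- blk
    if (b < 4) {
      cc2 <- max(4, floor(cc / 2))
      trunk[[paste0("trans", b)]] <- nn_conv(cc, cc2, k = 1, pad = 0)
      trunk[[paste0("transa", b)]] <- nn_lrelu()
      trunk[[paste0("transp", b)]] <- nn_avgpool2()
      cc <- cc2
    }
  }
  # final 1x1 reduction so the last block presents 16 channels to the GAP
  trunk$reduce <- nn_conv(cc, 16, k = 1, pad = 0)
  trunk$reducea <- nn_lrelu()
  trunk$gap <- nn_gap()
  trunk$fc <- nn_dense(16, cfg$n_classes)
  trunk
}

trunk_fwd <- function(tr, x) {
  for (b in 1:4) {
    x <- tr[[paste0("block", b)]]$fwd(x)
    if (b < 4) {
      x <- tr[[paste0("transp", b)]]$fwd(tr[[paste0("transa", b)]]$fwd(
        tr[[paste0("trans", b)]]$fwd(x)))
    }
  }
  v <- tr$gap$fwd(tr$reducea$fwd(tr$reduce$fwd(x)))
  tr$fc$fwd(v)
}

trunk_bwd <- function(tr, dlogits) {
  dv <- tr$fc$bwd(dlogits)
  dx <- tr$reduce$bwd(tr$reducea$bwd(tr$gap$bwd(dv)))
  for (b in 4:1) {
    if (b < 4) {
      dx <- tr[[paste0("trans", b)]]$bwd(tr[[paste0("transa", b)]]$bwd(
        tr[[paste0("transp", b)]]$bwd(dx)))
    }
    dx <- tr[[paste0("block", b)]]$bwd(dx)
  }
  dx
}

#' Build the single-input classifier
#'
#' Stem convolution + max-pool, four dense blocks with three transition
#' layers, 1x1 reduction to a 16-channel final block, global average pooling
#' to a 16-vector and a fully connected sigmoid head with one output per
#' disease class.
#'
#' @param config a [classifier_config()].
#' @return `classifier_net` with `$forward(img)` (logits) and
#'   `$predict(img)` (probabilities).
#' @export
build_single_input <- function(config = classifier_config()) {
  L <- with_seed(config$seed, {
    c(list(stem = nn_conv(1, config$stem_channels, k = 3), stema = nn_lrelu(),
           stemp = nn_maxpool2()),
      build_trunk(config))
  })
  net <- list(kind = "classifier_single", config = config, layers = L)
  net$forward <- function(img) {
    x <- array(unclass_img(img), c(nrow(img), ncol(img), 1))
    f <- L$stemp$fwd(L$stema$fwd(L$stem$fwd(x)))
    trunk_fwd(L, f)
  }
  net$backward <- function(dlogits) {
    df <- trunk_bwd(L, dlogits)
    invisible(L$stem$bwd(L$stema$bwd(L$stemp$bwd(df))))
  }
  net$predict <- function(img) sigmoid(net$forward(img))
  class(net) <- "classifier_net"
  net
}

#' Build the dual-input classifier
#'
#' The primary (post-image) path reuses the single-input stem; the secondary
#' (difference-image) path applies two convolutions, a max-pool and global
#' average pooling to produce one weight per stem channel, which rescales
#' the primary stem features via the [operation_block()] before the shared
#' trunk. With `weight_init = "zero"` the final weight layer starts at zero,
#' so the network reproduces the single-input forward pass exactly when its
#' trunk/stem weights are shared (the collapse-to-single property); the
#' default random init is used for training.
#'
#' @param config a [classifier_config()].
#' @param share_from optional single-input net whose stem/trunk weights are
#'   copied (shared initialization).
#' @param weight_init init of the final secondary-path convolution.
#' @return `classifier_net` whose `$forward(img1, img2)` takes both inputs.
#' @export
build_dual_input <- function(config = classifier_config(), share_from = NULL,
                             weight_init = c("he", "zero")) {
  weight_init <- match.arg(weight_init)
  L <- with_seed(config$seed, {
    c(list(stem = nn_conv(1, config$stem_channels, k = 3), stema = nn_lrelu(),
           stemp = nn_maxpool2(),
           w1 = nn_conv(1, config$stem_channels, k = 3), wa1 = nn_lrelu(),
           w2 = nn_conv(config$stem_channels, config$stem_channels, k = 3,
                        init = weight_init),
           wp = nn_maxpool2(), wgap = nn_gap()),
      build_trunk(config))
  })
  if (!is.null(share_from)) {
    src <- share_from$layers
    for (nm in names(src)) {
      if (nm %in% names(L) && has_params(src[[nm]])) {
        L[[nm]]$W <- src[[nm]]$W
        L[[nm]]$b <- src[[nm]]$b
      } else if (nm %in% names(L) && !is.null(src[[nm]]$type) &&
                 src[[nm]]$type == "block") {
        for (i in seq_along(src[[nm]]$convs)) {
          L[[nm]]$convs[[i]]$W <- src[[nm]]$convs[[i]]$W
          L[[nm]]$convs[[i]]$b <- src[[nm]]$convs[[i]]$b
        }
      }
    }
  }
  net <- list(kind = "classifier_dual", config = config, layers = L)
  st <- new.env(parent = emptyenv())   # fusion cache
  net$forward <- function(img1, img2) {
    x1 <- array(unclass_img(img1), c(nrow(img1), ncol(img1), 1))
    x2 <- array(unclass_img(img2), c(nrow(img2), ncol(img2), 1))
    F1 <- L$stemp$fwd(L$stema$fwd(L$stem$fwd(x1)))
    w <- L$wgap$fwd(L$wp$fwd(L$w2$fwd(L$wa1$fwd(L$w1$fwd(x2)))))
    st$F1 <- F1; st$w <- w
    fused <- operation_block(F1, w)
    trunk_fwd(L, fused)
  }
  net$backward <- function(dlogits) {
    dfused <- trunk_bwd(L, dlogits)
    C <- length(st$w)
    dF1 <- dfused
    dw <- numeric(C)
    for (c in seq_len(C)) {
      dF1[, , c] <- dfused[, , c] * (1 + st$w[c])
      dw[c] <- sum(dfused[, , c] * st$F1[, , c])
    }
    L$w1$bwd(L$wa1$bwd(L$w2$bwd(L$wp$bwd(L$wgap$bwd(dw)))))
    invisible(L$stem$bwd(L$stema$bwd(L$stemp$bwd(dF1))))
  }
  net$predict <- function(img1, img2) sigmoid(net$forward(img1, img2))
  class(net) <- "classifier_net"
  net
}

classifier_forward <- function(net, inputs) {
  if (net$kind == "classifier_single") net$forward(inputs[[1]])
  else net$forward(inputs[[1]], inputs[[2]])
}

#' Train a classifier
#'
#' Per-class binary cross-entropy summed over the label vector, Adam with
#' plateau learning-rate decay. Deterministic under the config seed.
#'
#' @param dataset list of `list(inputs = list(img) or list(img1, img2),
#'   labels = 0/1 vector)`.
#' @param net a built classifier; built fresh from `config` if `NULL`.
#' @param config a [classifier_config()] (used when `net` is NULL).
#' @param epochs override of the config epoch count.
#' @param verbose print per-epoch loss.
#' @return the trained net with `$history`.
#' @export
train_classifier <- function(dataset, net = NULL, config = classifier_config(),
                             epochs = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stopf("empty dataset")
  if (is.null(net)) {
    n_inputs <- length(dataset[[1]]$inputs)
    net <- if (n_inputs == 2) build_dual_input(config) else build_single_input(config)
  }
  cfg <- net$config
  epochs <- epochs %||% cfg$epochs
  opt <- nn_adam(net$layers, lr = cfg$lr)
  sched <- plateau_scheduler(opt, patience = cfg$patience, factor = cfg$lr_decay)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(cfg$seed * 100 + ep, sample(length(dataset)))
    losses <- numeric(0)
    i <- 1
    while (i <= length(ord)) {
      idx <- ord[i:min(i + cfg$batch_size - 1, length(ord))]
      for (j in idx) {
        logits <- classifier_forward(net, dataset[[j]]$inputs)
        r <- bce_with_logits(logits, dataset[[j]]$labels)
        losses <- c(losses, r$loss)
        net$backward(r$grad)
      }
      opt$step()
      i <- i + cfg$batch_size
    }
    history[ep] <- mean(losses)
    sched$step(history[ep])
    if (verbose) message(sprintf("epoch %d loss %.4f lr %.2g", ep, history[ep], opt$lr))
  }
  net$history <- history
  net
}

#' Per-class and macro-average ROC AUC of a classifier on a dataset
#'
#' Classes for which the dataset contains a single label value get `NA` AUC
#' (with a warning) and are excluded from the macro mean.
#'
#' @param net trained classifier.
#' @param dataset as in [train_classifier()].
#' @return list `per_class` (named AUCs) and `macro` (mean over defined
#'   classes).
#' @export
evaluate_auc <- function(net, dataset) {
  scores <- t(vapply(dataset, function(d)
    sigmoid(classifier_forward(net, d$inputs)), numeric(net$config$n_classes)))
  labels <- t(vapply(dataset, function(d) as.numeric(d$labels),
                     numeric(net$config$n_classes)))
  per <- vapply(seq_len(ncol(scores)), function(c) {
    if (length(unique(labels[, c])) < 2) {
      warning(sprintf("class %d has a single label value; AUC undefined", c))
      return(NA_real_)
    }
    auc_score(scores[, c], labels[, c])
  }, numeric(1))
  nm <- if (ncol(scores) == length(DISEASE_CLASSES)) DISEASE_CLASSES
        else paste0("class", seq_len(ncol(scores)))
  names(per) <- nm
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}
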