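# Minimal CPU neural-network framework: layers are mutable environments with
# fwd()/bwd() closures; convolution/pooling run in compiled code. Feature
# maps are (H, W, C) arrays. Gradients accumulate into each layer's dW/db
# until the optimizer consumes them. This is deliberately small: the
# networks in this package are desk-scale and hand-wired.

nn_conv <- function(in_c, out_c, k = 3, stride = 1, pad = (k - 1) %/% 2,
                    init = c("he", "zero")) {
  init <- match.arg(init)
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- k; e$stride <- stride; e$pad <- pad
  sd0 <- sqrt(2 / (in_c * k * k))
  e$W <- if (init == "zero") matrix(0, out_c, in_c * k * k)
         else matrix(rnorm(out_c * in_c * k * k, 0, sd0), out_c)
  e$b <- numeric(out_c)
  e$dW <- e$W * 0; e$db <- e$b * 0
  e$fwd <- function(x) {
    e$x <- x
    cpp_conv_fwd(x, e$W, e$b, e$k, e$stride, e$pad)
  }
  e$bwd <- function(dy) {
    g <- cpp_conv_bwd(e$x, e$W, dy, e$k, e$stride, e$pad)
    e$dW <- e$dW + g$dW
    e$db <- e$db + as.numeric(g$db)
    g$dx
  }
  e
}

nn_dense <- function(in_n, out_n, init = c("he", "zero")) {
  init <- match.arg(init)
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$W <- if (init == "zero") matrix(0, out_n, in_n)
         else matrix(rnorm(out_n * in_n, 0, sqrt(2 / in_n)), out_n)
  e$b <- numeric(out_n)
  e$dW <- e$W * 0; e$db <- e$b * 0
  e$fwd <- function(x) {            # x: numeric vector
    e$x <- x
    as.numeric(e$W %*% x + e$b)
  }
  e$bwd <- function(dy) {
    e$dW <- e$dW + outer(dy, e$x)
    e$db <- e$db + dy
    as.numeric(crossprod(e$W, dy))
  }
  e
}

nn_lrelu <- function(alpha = 0.2) {
  e <- new.env(parent = emptyenv())
  e$type <- "lrelu"
  e$fwd <- function(x) {
    e$mask <- x > 0
    x * ifelse(e$mask, 1, alpha)
  }
  e$bwd <- function(dy) dy * ifelse(e$mask, 1, alpha)
  e
}

nn_maxpool2 <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"
  e$fwd <- function(x) {
    e$hw <- dim(x)[1:2]
    r <- cpp_maxpool2_fwd(x)
    e$arg <- r$arg
    r$y
  }
  e$bwd <- function(dy) cpp_maxpool2_bwd(dy, e$arg, e$hw[1], e$hw[2])
  e
}

nn_avgpool2 <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "avgpool"
  e$fwd <- function(x) { e$hw <- dim(x)[1:2]; cpp_avgpool2_fwd(x) }
  e$bwd <- function(dy) cpp_avgpool2_bwd(dy, e$hw[1], e$hw[2])
  e
}

nn_upsample2 <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "upsample"
  e$fwd <- function(x) cpp_upsample2_fwd(x)
  e$bwd <- function(dy) cpp_upsample2_bwd(dy)
  e
}

# Global average pooling: (H, W, C) -> length-C vector.
nn_gap <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "gap"
  e$fwd <- function(x) {
    e$d <- dim(x)
    apply(x, 3, mean)
  }
  e$bwd <- function(dy) {
    d <- e$d
    g <- array(0, d)
    for (c in seq_len(d[3])) g[, , c] <- dy[c] / (d[1] * d[2])
    g
  }
  e
}

# Run a list of layers as a chain.
seq_fwd <- function(layers, x) {
  for (l in layers) x <- l$fwd(x)
  x
}
seq_bwd <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$bwd(dy)
  dy
}

has_params <- function(l) !is.null(l$type) && l$type %in% c("conv", "dense")

# flatten composite layers (type "block") into their parameterized children
collect_params <- function(layers) {
  out <- list()
  for (l in layers) {
    if (is.null(l$type)) next
    if (has_params(l)) out <- c(out, list(l))
    else if (l$type == "block") out <- c(out, l$param_layers)
  }
  out
}

zero_grads <- function(layers) {
  for (l in collect_params(layers)) { l$dW <- l$dW * 0; l$db <- l$db * 0 }
  invisible(NULL)
}

# Adam with in-place updates; lr is mutable (plateau scheduler adjusts it).
nn_adam <- function(layers, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$t <- 0
  opt$layers <- collect_params(layers)
  for (l in opt$layers) { l$mW <- l$W * 0; l$vW <- l$W * 0; l$mb <- l$b * 0; l$vb <- l$b * 0 }
  opt$step <- function() {
    opt$t <- opt$t + 1
    bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
    for (l in opt$layers) {
      l$mW <- beta1 * l$mW + (1 - beta1) * l$dW
      l$vW <- beta2 * l$vW + (1 - beta2) * l$dW^2
      l$W <- l$W - opt$lr * (l$mW / bc1) / (sqrt(l$vW / bc2) + eps)
      l$mb <- beta1 * l$mb + (1 - beta1) * l$db
      l$vb <- beta2 * l$vb + (1 - beta2) * l$db^2
      l$b <- l$b - opt$lr * (l$mb / bc1) / (sqrt(l$vb / bc2) + eps)
      l$dW <- l$dW * 0; l$db <- l$db * 0
    }
    invisible(NULL)
  }
  opt
}

# Reduce-on-plateau: after `patience` consecutive non-improving evaluations,
# multiply the optimizer lr by `factor`.
plateau_scheduler <- function(opt, patience = 3, factor = 0.1, min_delta = 1e-8) {
  s <- new.env(parent = emptyenv())
  s$best <- Inf; s$bad <- 0
  s$step <- function(metric) {
    if (metric < s$best - min_delta) {
      s$best <- metric; s$bad <- 0
    } else {
      s$bad <- s$bad + 1
      if (s$bad >= patience) {
        opt$lr <- opt$lr * factor
        s$bad <- 0
      }
    }
    opt$lr
  }
  s
}

# --- serialization: flat double vector + JSON sidecar ----------------------

#' Save model weights
#'
#' Writes all conv/dense parameters of a network as a flat little-endian
#' float64 container with a JSON sidecar describing each tensor's shape.
#'
#' @param net a network object with a `layers` list.
#' @param path output path; the sidecar is written to `paste0(path, ".json")`.
#' @export
save_model <- function(net, path) {
  pl <- collect_params(net$layers)
  meta <- list()
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(pl)) {
    l <- pl[[i]]
    writeBin(as.numeric(l$W), con, size = 8, endian = "little")
    writeBin(as.numeric(l$b), con, size = 8, endian = "little")
    meta[[i]] <- list(W = dim(l$W), b = length(l$b))
  }
  jsonlite::write_json(list(format = "lungdiff-weights-v1", kind = net$kind %||% "net",
                            config = net$config %||% list(), tensors = meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load model weights into an existing network of identical topology
#'
#' @param net network built with the same configuration.
#' @param path container written by [save_model()].
#' @export
load_model <- function(net, path) {
  pl <- collect_params(net$layers)
  con <- file(path, "rb")
  on.exit(close(con))
  for (l in pl) {
    w <- readBin(con, "double", n = length(l$W), size = 8, endian = "little")
    l$W <- matrix(w, nrow(l$W))
    l$b <- readBin(con, "double", n = length(l$b), size = 8, endian = "little")
  }
  invisible(net)
}

# Stable sigmoid / BCE helpers.
sigmoid <- function(x) 1 / (1 + exp(-x))

bce_with_logits <- function(logits, targets) {
  # loss and gradient wrt logits, summed over entries
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -sum(targets * log(p + eps) + (1 - targets) * log(1 - p + eps))
  list(loss = loss, grad = p - targets)
}
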