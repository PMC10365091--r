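# Minimal layer framework with hand-derived gradients. Layers are plain
# lists; a "sequential" is a list of layers run in order. Arrays are
# [H, W, C, N]. Convolution and bilinear resampling run through the
# compiled kernels; batch norm and ReLU are vectorized R.

layer_conv <- function(in_ch, out_ch, k = 3, stride = 1, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  # He-normal fan-in initialization
  w <- array(rnorm(k * k * in_ch * out_ch, sd = sqrt(2 / (k * k * in_ch))),
             dim = c(k, k, in_ch, out_ch))
  list(type = "conv", w = w, b = numeric(out_ch),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       rm = numeric(ch), rv = rep(1, ch), momentum = momentum, eps = eps)
}

layer_relu <- function() list(type = "relu")

layer_bilinear <- function(out_h, out_w = out_h) {
  list(type = "bilinear", out = c(as.integer(out_h), as.integer(out_w)))
}

layer_residual <- function(body, shortcut = NULL) {
  list(type = "residual", body = body, shortcut = shortcut)
}

layer_fw <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      list(out = conv2d_fw(x, layer$w, layer$b, layer$stride, layer$pad),
           cache = list(x = x), layer = layer)
    },
    bn = {
      if (train) {
        r <- bn_fw_cpp(x, layer$gamma, layer$beta, NULL, NULL, layer$eps)
        d <- dim(x)
        m <- d[1] * d[2] * d[4]
        layer$rm <- (1 - layer$momentum) * layer$rm + layer$momentum * r$mu
        # unbiased running variance
        layer$rv <- (1 - layer$momentum) * layer$rv +
          layer$momentum * r$var * m / max(m - 1, 1)
      } else {
        r <- bn_fw_cpp(x, layer$gamma, layer$beta, layer$rm, layer$rv,
                       layer$eps)
      }
      list(out = r$out, cache = list(xhat = r$xhat, inv_std = r$inv_std,
                                     train = train), layer = layer)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    bilinear = {
      d <- dim(x)
      out <- if (d[1] == layer$out[1] && d[2] == layer$out[2]) x else
        bilinear_fw(x, layer$out[1], layer$out[2])
      list(out = out, cache = list(in_dim = d), layer = layer)
    },
    residual = {
      body <- seq_fw(layer$body, x, train)
      if (is.null(layer$shortcut)) {
        sc_out <- x; sc <- NULL
      } else {
        sc <- seq_fw(layer$shortcut, x, train)
        sc_out <- sc$out
      }
      layer$body <- body$layers
      if (!is.null(sc)) layer$shortcut <- sc$layers
      list(out = body$out + sc_out,
           cache = list(body = body$cache,
                        shortcut = if (!is.null(sc)) sc$cache),
           layer = layer)
    },
    stop("unknown layer type ", layer$type))
}

layer_bw <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      g <- conv2d_bw(cache$x, layer$w, dout, layer$stride, layer$pad,
                     !isTRUE(layer$input_layer))
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    bn = {
      r <- bn_bw_cpp(cache$xhat, dout, layer$gamma, cache$inv_std,
                     isTRUE(cache$train))
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    bilinear = {
      d <- cache$in_dim
      dx <- if (d[1] == dim(dout)[1] && d[2] == dim(dout)[2]) dout else
        bilinear_bw(dout, d[1], d[2])
      list(dx = dx, grads = NULL)
    },
    residual = {
      body <- seq_bw(layer$body, cache$body, dout)
      if (is.null(layer$shortcut)) {
        dx <- body$dx + dout
        sg <- NULL
      } else {
        sc <- seq_bw(layer$shortcut, cache$shortcut, dout)
        dx <- body$dx + sc$dx
        sg <- sc$grads
      }
      list(dx = dx, grads = list(body = body$grads, shortcut = sg))
    })
}

seq_fw <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fw(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, cache = caches, layers = layers)
}

seq_bw <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bw(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)   # keep NULL placeholders in position
  }
  list(dx = dout, grads = grads)
}

#' Encoder/decoder configuration
#'
#' The encoder is a convolutional trunk whose stage outputs are resampled
#' to the classification grid and (when `multi_resolution`) concatenated
#' before a final classification block of two convolutions separated by
#' batch normalization and ReLU -- replacing the global pooling + linear
#' head of an ordinary classifier so that one logit is produced per grid
#' cell per class. The decoder is three blocks of bilinear x2 upsampling,
#' convolution and batch normalization, mapping the pre-classification
#' features to per-class logit maps at `input_size / 2`.
#'
#' @param backbone `"tiny"` (strided conv blocks; the test-scale default,
#'   under 500k parameters) or `"resnet50_shaped"` (bottleneck residual
#'   stages with standard widths, for full-scale runs).
#' @param input_size square working resolution (default 512).
#' @param grid_size classification grid (default 32; must divide
#'   `input_size`).
#' @param n_classes number of labels (default 10).
#' @param multi_resolution tap every stage output into the classification
#'   block (otherwise only the last stage is used).
#' @param stage_channels per-stage output channels for the tiny backbone.
#' @param head_channels width of the first classification-block conv.
#' @param decoder_channels widths of the first two decoder blocks.
#' @return an `encoder_config`.
#' @export
encoder_config <- function(backbone = c("tiny", "resnet50_shaped"),
                           input_size = 512, grid_size = 32, n_classes = 10,
                           multi_resolution = TRUE, stage_channels = NULL,
                           head_channels = NULL, decoder_channels = NULL) {
  backbone <- match.arg(backbone)
  if (input_size %% grid_size != 0) {
    stop_user("encoder_config: grid_size must divide input_size")
  }
  if (backbone == "tiny") {
    n_stages <- as.integer(round(log2(input_size / grid_size)))
    if (2^n_stages * grid_size != input_size) {
      stop_user("encoder_config: input_size / grid_size must be a power of 2",
                " for the tiny backbone")
    }
    defaults <- c(8, 16, 24, 32, 48, 64)
    stage_channels <- stage_channels %||% defaults[seq_len(n_stages)]
    if (length(stage_channels) != n_stages) {
      stop_user("encoder_config: need ", n_stages, " stage channels")
    }
    head_channels <- head_channels %||% 40
    decoder_channels <- decoder_channels %||% c(20, 20)
  } else {
    stage_channels <- stage_channels %||% c(256, 512, 1024, 2048)
    head_channels <- head_channels %||% 512
    decoder_channels <- decoder_channels %||% c(64, 64)
  }
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 grid_size = as.integer(grid_size),
                 n_classes = as.integer(n_classes),
                 multi_resolution = isTRUE(multi_resolution),
                 stage_channels = stage_channels,
                 head_channels = head_channels,
                 decoder_channels = decoder_channels,
                 decoder_size = as.integer(grid_size * 8)),
            class = "encoder_config")
}

bottleneck_unit <- function(in_ch, mid_ch, out_ch, stride) {
  body <- list(layer_conv(in_ch, mid_ch, k = 1, stride = 1),
               layer_bn(mid_ch), layer_relu(),
               layer_conv(mid_ch, mid_ch, k = 3, stride = stride),
               layer_bn(mid_ch), layer_relu(),
               layer_conv(mid_ch, out_ch, k = 1, stride = 1),
               layer_bn(out_ch))
  shortcut <- if (in_ch != out_ch || stride != 1) {
    list(layer_conv(in_ch, out_ch, k = 1, stride = stride),
         layer_bn(out_ch))
  }
  list(layer_residual(body, shortcut), layer_relu())
}

#' Build a model from a configuration
#'
#' Initialization is seed-controlled through R's RNG: call `set.seed()`
#' (or use [with_seed()]-style wrappers) before building for reproducible
#' weights.
#' @param config an [encoder_config()].
#' @return a `gazemil_model` list with `config`, `stages`, `head`,
#'   `classifier`, `decoder`.
#' @export
build_model <- function(config) {
  K <- config$n_classes
  if (config$backbone == "tiny") {
    stages <- list()
    in_ch <- 1L
    for (s in seq_along(config$stage_channels)) {
      ch <- config$stage_channels[s]
      stages[[s]] <- list(layer_conv(in_ch, ch, k = 3, stride = 2),
                          layer_bn(ch), layer_relu())
      in_ch <- ch
    }
    # input gradient of the very first conv is never consumed
    stages[[1]][[1]]$input_layer <- TRUE
    stage_out <- config$stage_channels
  } else {
    stem1 <- layer_conv(1L, 64L, k = 7, stride = 2, pad = 3L)
    stem1$input_layer <- TRUE
    stem <- list(stem1,
                 layer_bn(64L), layer_relu(),
                 layer_conv(64L, 64L, k = 3, stride = 2),
                 layer_bn(64L), layer_relu())
    units <- c(3L, 4L, 6L, 3L)
    widths <- config$stage_channels
    mids <- widths %/% 4L
    strides <- c(1L, 2L, 2L, 2L)
    stages <- list()
    in_ch <- 64L
    for (s in 1:4) {
      st <- if (s == 1) stem else list()
      for (u in seq_len(units[s])) {
        st <- c(st, bottleneck_unit(in_ch, mids[s], widths[s],
                                    if (u == 1) strides[s] else 1L))
        in_ch <- widths[s]
      }
      stages[[s]] <- st
    }
    stage_out <- widths
  }
  tap_ch <- if (config$multi_resolution) stage_out else
    stage_out[length(stage_out)]
  hc <- config$head_channels
  head <- list(layer_conv(sum(tap_ch), hc, k = 3, stride = 1),
               layer_bn(hc), layer_relu())
  classifier <- list(layer_conv(hc, K, k = 1, stride = 1))
  # negative-prior bias: a soft-OR over hundreds of cells saturates toward
  # "present" when cells start at sigma = 0.5; start cells near-negative
  classifier[[1]]$b <- rep(-3, K)
  dc <- config$decoder_channels
  g <- config$grid_size
  decoder <- list(
    layer_bilinear(2 * g), layer_conv(hc, dc[1]), layer_bn(dc[1]),
    layer_relu(),
    layer_bilinear(4 * g), layer_conv(dc[1], dc[2]), layer_bn(dc[2]),
    layer_relu(),
    layer_bilinear(8 * g), layer_conv(dc[2], K), layer_bn(K))
  structure(list(config = config, stages = stages, head = head,
                 classifier = classifier, decoder = decoder,
                 tap_channels = tap_ch),
            class = "gazemil_model")
}

#' Encoder + decoder forward pass
#'
#' @param model a `gazemil_model`.
#' @param x input images: `[H, W, 1, N]` array (or `H x W` matrix for one
#'   image) at the configured input size.
#' @param train use batch statistics and keep caches for [model_backward()].
#' @param with_decoder also run the decoder.
#' @return list with `grid_logits` `[g, g, K, N]`, `spatial_activation`
#'   (sigmoid of grid logits), `decoder_logits` `[8g, 8g, K, N]` (when
#'   requested), and `model` (running statistics updated when training).
#'   With `train = TRUE` the cache needed by [model_backward()] is
#'   attached.
#' @export
model_forward <- function(model, x, train = FALSE, with_decoder = TRUE) {
  cfg <- model$config
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop_user("model_forward: input must be ", cfg$input_size, "x",
              cfg$input_size, " (letterbox first)")
  }
  g <- cfg$grid_size
  taps <- vector("list", length(model$stages))
  stage_caches <- vector("list", length(model$stages))
  cur <- x
  for (s in seq_along(model$stages)) {
    r <- seq_fw(model$stages[[s]], cur, train)
    cur <- r$out
    model$stages[[s]] <- r$layers
    stage_caches[[s]] <- r$cache
    taps[[s]] <- r$out
  }
  use <- if (cfg$multi_resolution) seq_along(taps) else length(taps)
  tap_dims <- lapply(taps[use], dim)
  resized <- lapply(taps[use], function(t) {
    if (dim(t)[1] == g && dim(t)[2] == g) t else bilinear_fw(t, g, g)
  })
  concat <- if (length(resized) == 1) resized[[1]] else cat_channels(resized)
  hr <- seq_fw(model$head, concat, train)
  model$head <- hr$layers
  cr <- seq_fw(model$classifier, hr$out, train)
  model$classifier <- cr$layers
  out <- list(grid_logits = cr$out, spatial_activation = sigmoid(cr$out))
  if (with_decoder) {
    dr <- seq_fw(model$decoder, hr$out, train)
    model$decoder <- dr$layers
    out$decoder_logits <- dr$out
    if (train) out$cache_decoder <- dr$cache
  }
  if (train) {
    out$cache <- list(stages = stage_caches, head = hr$cache,
                      classifier = cr$cache, tap_dims = tap_dims,
                      use = use)
  }
  out$model <- model
  out
}

#' Backward pass through the full model
#'
#' @param model model returned in `model_forward(...)$model`.
#' @param fwd the full [model_forward()] result (train mode).
#' @param d_grid gradient of the loss w.r.t. the grid logits.
#' @param d_decoder gradient w.r.t. the decoder logits (or `NULL`).
#' @return nested gradient structure aligned with the model's layers.
#' @export
model_backward <- function(model, fwd, d_grid, d_decoder = NULL) {
  cfg <- model$config
  cb <- seq_bw(model$classifier, fwd$cache$classifier, d_grid)
  dfeat <- cb$dx
  dec_grads <- NULL
  if (!is.null(d_decoder)) {
    db <- seq_bw(model$decoder, fwd$cache_decoder, d_decoder)
    dfeat <- dfeat + db$dx
    dec_grads <- db$grads
  }
  hb <- seq_bw(model$head, fwd$cache$head, dfeat)
  use <- fwd$cache$use
  chans <- vapply(fwd$cache$tap_dims, function(d) d[3], numeric(1))
  dtaps_resized <- if (length(use) == 1) list(hb$dx) else
    split_channels(hb$dx, chans)
  dtap <- vector("list", length(model$stages))
  for (i in seq_along(use)) {
    s <- use[i]
    td <- fwd$cache$tap_dims[[i]]
    dtap[[s]] <- if (td[1] == dim(dtaps_resized[[i]])[1] &&
                       td[2] == dim(dtaps_resized[[i]])[2]) {
      dtaps_resized[[i]]
    } else {
      bilinear_bw(dtaps_resized[[i]], td[1], td[2])
    }
  }
  stage_grads <- vector("list", length(model$stages))
  dcur <- NULL
  for (s in rev(seq_along(model$stages))) {
    dout <- dtap[[s]] %||% 0
    if (!is.null(dcur)) dout <- dout + dcur
    sb <- seq_bw(model$stages[[s]], fwd$cache$stages[[s]], dout)
    stage_grads[[s]] <- sb$grads
    dcur <- sb$dx
  }
  list(stages = stage_grads, head = hb$grads, classifier = cb$grads,
       decoder = dec_grads)
}

#' Run the encoder alone
#'
#' Evaluation-mode forward pass through the trunk, multi-resolution taps
#' and classification block, exposing the pre-classification feature maps
#' alongside the grid logits.
#' @inheritParams model_forward
#' @return list with `features` (`[g, g, head_channels, N]`),
#'   `grid_logits` and `spatial_activation`.
#' @export
encode <- function(model, x) {
  cfg <- model$config
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop_user("encode: input must be ", cfg$input_size, "x",
              cfg$input_size, " (letterbox first)")
  }
  g <- cfg$grid_size
  taps <- vector("list", length(model$stages))
  cur <- x
  for (s in seq_along(model$stages)) {
    cur <- seq_fw(model$stages[[s]], cur, train = FALSE)$out
    taps[[s]] <- cur
  }
  use <- if (cfg$multi_resolution) seq_along(taps) else length(taps)
  resized <- lapply(taps[use], function(t) {
    if (dim(t)[1] == g && dim(t)[2] == g) t else bilinear_fw(t, g, g)
  })
  concat <- if (length(resized) == 1) resized[[1]] else cat_channels(resized)
  features <- seq_fw(model$head, concat, train = FALSE)$out
  logits <- seq_fw(model$classifier, features, train = FALSE)$out
  list(features = features, grid_logits = logits,
       spatial_activation = sigmoid(logits))
}

#' Run the decoder alone
#'
#' Maps encoder features at grid resolution to per-class logit maps at
#' eight times the grid resolution (three bilinear x2 blocks).
#' @param model a `gazemil_model`.
#' @param features feature array from [encode()].
#' @return `[8g, 8g, n_classes, N]` logit array.
#' @export
decode <- function(model, features) {
  d <- dim(features)
  g <- model$config$grid_size
  if (d[1] != g || d[2] != g ||
        d[3] != dim(model$decoder[[2]]$w)[3]) {
    stop_user("decode: features do not match the decoder configuration")
  }
  seq_fw(model$decoder, features, train = FALSE)$out
}

# ---- parameter flattening -------------------------------------------------

collect_params <- function(layers, path, out) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    p <- paste0(path, ".", i)
    if (is.null(l)) next
    if (identical(l$type, "conv")) {
      out[[paste0(p, ".w")]] <- l$w
      out[[paste0(p, ".b")]] <- l$b
    } else if (identical(l$type, "bn")) {
      out[[paste0(p, ".gamma")]] <- l$gamma
      out[[paste0(p, ".beta")]] <- l$beta
    } else if (identical(l$type, "residual")) {
      out <- collect_params(l$body, paste0(p, ".body"), out)
      if (!is.null(l$shortcut)) {
        out <- collect_params(l$shortcut, paste0(p, ".shortcut"), out)
      }
    }
  }
  out
}

collect_grads <- function(grads, path, out) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    p <- paste0(path, ".", i)
    if (is.null(g)) next
    if (!is.null(g$w)) {
      out[[paste0(p, ".w")]] <- g$w
      out[[paste0(p, ".b")]] <- g$b
    } else if (!is.null(g$gamma)) {
      out[[paste0(p, ".gamma")]] <- g$gamma
      out[[paste0(p, ".beta")]] <- g$beta
    } else if (!is.null(g$body)) {
      out <- collect_grads(g$body, paste0(p, ".body"), out)
      if (!is.null(g$shortcut)) {
        out <- collect_grads(g$shortcut, paste0(p, ".shortcut"), out)
      }
    }
  }
  out
}

#' Flatten model parameters into a named list of numeric arrays
#' @param model a `gazemil_model`.
#' @return named list (conv weights/biases, batch-norm scale/shift).
#' @export
model_params <- function(model) {
  out <- list()
  for (s in seq_along(model$stages)) {
    out <- collect_params(model$stages[[s]], paste0("stage", s), out)
  }
  out <- collect_params(model$head, "head", out)
  out <- collect_params(model$classifier, "classifier", out)
  out <- collect_params(model$decoder, "decoder", out)
  out
}

#' @rdname model_params
#' @param grads output of [model_backward()].
#' @export
model_grads <- function(model, grads) {
  out <- list()
  for (s in seq_along(grads$stages)) {
    out <- collect_grads(grads$stages[[s]], paste0("stage", s), out)
  }
  out <- collect_grads(grads$head, "head", out)
  out <- collect_grads(grads$classifier, "classifier", out)
  if (!is.null(grads$decoder)) {
    out <- collect_grads(grads$decoder, "decoder", out)
  }
  out
}

assign_params <- function(layers, path, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    p <- paste0(path, ".", i)
    if (is.null(l)) next
    if (identical(l$type, "conv")) {
      if (!is.null(params[[paste0(p, ".w")]])) {
        layers[[i]]$w <- array(params[[paste0(p, ".w")]], dim = dim(l$w))
        layers[[i]]$b <- as.numeric(params[[paste0(p, ".b")]])
      }
    } else if (identical(l$type, "bn")) {
      if (!is.null(params[[paste0(p, ".gamma")]])) {
        layers[[i]]$gamma <- as.numeric(params[[paste0(p, ".gamma")]])
        layers[[i]]$beta <- as.numeric(params[[paste0(p, ".beta")]])
      }
    } else if (identical(l$type, "residual")) {
      layers[[i]]$body <- assign_params(l$body, paste0(p, ".body"), params)
      if (!is.null(l$shortcut)) {
        layers[[i]]$shortcut <- assign_params(l$shortcut,
                                              paste0(p, ".shortcut"), params)
      }
    }
  }
  layers
}

#' @rdname model_params
#' @param params named list as returned by [model_params()].
#' @export
set_model_params <- function(model, params) {
  for (s in seq_along(model$stages)) {
    model$stages[[s]] <- assign_params(model$stages[[s]],
                                       paste0("stage", s), params)
  }
  model$head <- assign_params(model$head, "head", params)
  model$classifier <- assign_params(model$classifier, "classifier", params)
  model$decoder <- assign_params(model$decoder, "decoder", params)
  model
}

#' Total trainable parameter count
#' @param model a `gazemil_model`.
#' @export
n_params <- function(model) {
  sum(vapply(model_params(model), length, numeric(1)))
}

# ---- optimizer ------------------------------------------------------------

#' AMSGrad optimizer
#'
#' Adaptive-moment optimizer with the AMSGrad maximum on the second-moment
#' estimate and decoupled-style L2 weight decay added to the gradient
#' (matching the common Adam/AMSGrad implementation). Weight decay is not
#' applied to batch-norm parameters or biases.
#'
#' @param lr learning rate (default 0.001).
#' @param weight_decay L2 coefficient (default 1e-5).
#' @param beta1,beta2,eps standard adaptive-moment constants.
#' @return an `amsgrad` optimizer state.
#' @export
amsgrad <- function(lr = 0.001, weight_decay = 1e-5, beta1 = 0.9,
                    beta2 = 0.999, eps = 1e-8) {
  structure(list(lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2,
                 eps = eps, t = 0L, m = list(), v = list(), vhat = list()),
            class = "amsgrad")
}

#' @rdname amsgrad
#' @param opt optimizer state.
#' @param params,grads named lists from [model_params()]/[model_grads()].
#' @return list with updated `params` and `opt`.
#' @export
amsgrad_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    decay <- opt$wd > 0 && grepl("\\.w$", nm)
    if (decay) g <- g + opt$wd * params[[nm]]
    m <- opt$m[[nm]] %||% (g * 0)
    v <- opt$v[[nm]] %||% (g * 0)
    vh <- opt$vhat[[nm]] %||% (g * 0)
    m <- opt$b1 * m + (1 - opt$b1) * g
    v <- opt$b2 * v + (1 - opt$b2) * g^2
    vh <- pmax(vh, v)
    opt$m[[nm]] <- m; opt$v[[nm]] <- v; opt$vhat[[nm]] <- vh
    params[[nm]] <- params[[nm]] -
      opt$lr * (m / bc1) / (sqrt(vh / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, all parameters and the
#' batch-norm running statistics, so a reloaded model reproduces forward
#' passes bit-identically.
#' @param model a `gazemil_model`.
#' @param path file path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "gazemil_checkpoint_v1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "gazemil_checkpoint_v1")) {
    stop_user("load_model: not a gazemil checkpoint")
  }
  ck$model
}
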