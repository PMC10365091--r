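#' Training configuration
#'
#' Defaults are the full-scale protocol: 60 epochs of AMSGrad (learning
#' rate 0.001, weight decay 1e-5), batches of 20, rotation up to 45
#' degrees, translation up to 15% and scaling up to 15%, a 32x32
#' supervision grid at 512-px letterboxed inputs, heatmap binarization at
#' 0.15, `lambda_A = 3`, `lambda_T = 300`, balanced range normalization,
#' five seeds. Desk-scale experiments override sizes, not semantics.
#'
#' @param epochs,lr,weight_decay,batch_size optimizer protocol.
#' @param lambda_A,lambda_T loss weights, see [loss_weights()].
#' @param norm_mode,norm_base range normalization, see [norm_spec()].
#' @param input_size,grid_size working resolution and supervision grid.
#' @param n_classes number of labels.
#' @param labels label names (defaults to [study_labels()]).
#' @param heatmap_threshold annotation binarization threshold.
#' @param augment list with `rotate` (degrees), `translate`, `scale`
#'   (fractions); `NULL` disables augmentation.
#' @param seeds training seeds for multi-seed averaging.
#' @param backbone,multi_resolution,stage_channels,head_channels,decoder_channels
#'   passed to [encoder_config()].
#' @param threshold_grid candidate binarization thresholds for validated
#'   IoU threshold selection.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 60, lr = 0.001, weight_decay = 1e-5,
                         batch_size = 20, lambda_A = 3, lambda_T = 300,
                         norm_mode = "balanced", norm_base = 0.0056738,
                         input_size = 512, grid_size = 32,
                         n_classes = length(labels),
                         labels = study_labels(),
                         heatmap_threshold = 0.15,
                         augment = list(rotate = 45, translate = 0.15,
                                        scale = 0.15),
                         seeds = 1:5, backbone = "tiny",
                         multi_resolution = TRUE, stage_channels = NULL,
                         head_channels = NULL, decoder_channels = NULL,
                         threshold_grid = seq(0.05, 0.95, by = 0.05)) {
  structure(list(
    epochs = epochs, lr = lr, weight_decay = weight_decay,
    batch_size = batch_size,
    weights = loss_weights(lambda_A, lambda_T),
    spec = norm_spec(norm_mode, norm_base),
    input_size = as.integer(input_size), grid_size = as.integer(grid_size),
    n_classes = as.integer(n_classes), labels = labels,
    heatmap_threshold = heatmap_threshold, augment = augment,
    seeds = seeds, backbone = backbone,
    multi_resolution = multi_resolution, stage_channels = stage_channels,
    head_channels = head_channels, decoder_channels = decoder_channels,
    threshold_grid = threshold_grid), class = "train_config")
}

config_encoder <- function(config) {
  encoder_config(config$backbone, input_size = config$input_size,
                 grid_size = config$grid_size,
                 n_classes = config$n_classes,
                 multi_resolution = config$multi_resolution,
                 stage_channels = config$stage_channels,
                 head_channels = config$head_channels,
                 decoder_channels = config$decoder_channels)
}

# ---- augmentation ---------------------------------------------------------

#' Bilinear affine warp of a matrix (zero outside the source)
#' @param m matrix.
#' @param fwd 3x3 affine matrix mapping 0-based source (x, y, 1) to output
#'   coordinates; the warp samples through its inverse.
#' @return warped matrix of the same size.
#' @export
warp_affine <- function(m, fwd) {
  warp_affine_cpp(m, solve(fwd))
}

random_affine <- function(size, aug) {
  theta <- runif(1, -aug$rotate, aug$rotate) * pi / 180
  s <- runif(1, 1 - aug$scale, 1 + aug$scale)
  tx <- runif(1, -aug$translate, aug$translate) * size
  ty <- runif(1, -aug$translate, aug$translate) * size
  c0 <- (size - 1) / 2
  ca <- cos(theta); sa <- sin(theta)
  rot <- matrix(c(s * ca, s * sa, 0, -s * sa, s * ca, 0, 0, 0, 1), 3, 3)
  t1 <- matrix(c(1, 0, 0, 0, 1, 0, -c0, -c0, 1), 3, 3)
  t2 <- matrix(c(1, 0, 0, 0, 1, 0, c0 + tx, c0 + ty, 1), 3, 3)
  t2 %*% rot %*% t1
}

#' Jointly augment an image and its annotation maps
#'
#' One random rotation/translation/scale draw is applied identically to
#' the image and every annotation map of the case; binary maps are
#' re-binarized at 0.5 after interpolation.
#'
#' @param image matrix.
#' @param maps named list of annotation matrices (possibly empty).
#' @param aug augmentation ranges (`rotate` degrees, `translate`, `scale`
#'   fractions); draws use the current RNG state.
#' @return list with `image` and `maps`.
#' @export
augment_pair <- function(image, maps = list(),
                         aug = list(rotate = 45, translate = 0.15,
                                    scale = 0.15)) {
  fwd <- random_affine(nrow(image), aug)
  out_maps <- lapply(maps, function(mp) {
    wm <- warp_affine(mp, fwd)
    if (all(mp %in% c(0, 1))) (wm > 0.5) * 1 else wm
  })
  list(image = warp_affine(image, fwd), maps = out_maps)
}

# ---- data preparation -----------------------------------------------------

#' Prepare training records for one supervision method
#'
#' Builds per-case records (image, labels, per-label annotation maps) for
#' the three supervision settings: `"et"` extracts label-specific gaze
#' heatmaps from the reading sessions via the window rule, `"ellipse"`
#' uses the ground-truth masks through the identical path, and
#' `"unannotated"` keeps image-level labels only (every image is routed
#' through the unannotated loss indicators; no separate code path).
#'
#' @param cases list of `synthetic_case`-like objects (need `image`,
#'   `labels`; `session`/`masks` as required by the method).
#' @param method `"et"`, `"ellipse"` or `"unannotated"`.
#' @param config a [train_config()].
#' @param policy window policy for ET extraction.
#' @param vocab vocabulary for mention detection.
#' @return list of records: `id`, `image`, `labels`, `maps` (named list,
#'   `NULL` for unannotated records).
#' @export
prepare_training_data <- function(cases, method = c("et", "ellipse",
                                                    "unannotated"),
                                  config = train_config(),
                                  policy = window_policy(),
                                  vocab = load_vocabulary()) {
  method <- match.arg(method)
  lapply(cases, function(cs) {
    labs <- stats::setNames(cs$labels[config$labels] %in% TRUE,
                            config$labels)
    maps <- NULL
    if (method == "et" && !is.null(cs$session)) {
      hm <- extract_heatmaps(cs$session, vocab = vocab, policy = policy)
      maps <- lapply(hm, `[[`, "map")
      maps <- maps[names(maps) %in% config$labels[labs]]
    } else if (method == "ellipse" && !is.null(cs$masks)) {
      maps <- cs$masks[names(cs$masks) %in% config$labels[labs]]
    }
    list(id = cs$id, image = cs$image, labels = labs, maps = maps)
  })
}

#' Whole-session variant of ET preparation (ablation)
#'
#' Replaces every label-specific heatmap by the single whole-session gaze
#' map of the case, mirroring the removal of label-specific heatmaps.
#' @inheritParams prepare_training_data
#' @export
prepare_whole_session_data <- function(cases, config = train_config()) {
  lapply(cases, function(cs) {
    labs <- stats::setNames(cs$labels[config$labels] %in% TRUE,
                            config$labels)
    maps <- NULL
    if (!is.null(cs$session)) {
      wm <- whole_session_heatmap(cs$session)$map
      maps <- stats::setNames(rep(list(wm), sum(labs)),
                              config$labels[labs])
    }
    list(id = cs$id, image = cs$image, labels = labs, maps = maps)
  })
}

record_status <- function(rec, labels) {
  vapply(labels, function(l) {
    positive <- isTRUE(rec$labels[[l]])
    annotated <- !is.null(rec$maps)
    if (annotated && positive && !is.null(rec$maps[[l]])) {
      "annotated_positive"
    } else if (annotated && !positive) {
      "annotated_negative"
    } else if (positive) "unannotated_positive" else "unannotated_negative"
  }, character(1))
}

# ---- training loop --------------------------------------------------------

#' Train the grid classifier
#'
#' Mini-batch AMSGrad training of the encoder/decoder under the combined
#' MIL + multi-task loss. Every epoch records the training loss and the
#' mean validation AUC (image-level soft-OR scores); a parameter snapshot
#' is kept per epoch and the best epoch is the one with the highest mean
#' validation AUC.
#'
#' @param records training records from [prepare_training_data()]
#'   (annotated and unannotated mixed).
#' @param val_cases validation cases (`image` + `labels`).
#' @param config a [train_config()].
#' @param seed training seed (initialization, shuffling, augmentation).
#' @param verbose print per-epoch progress.
#' @return a `gazemil_fit`: `config`, `seed`, `log` (per-epoch
#'   data.frame), `checkpoints` (per-epoch models), `best_epoch`, `model`
#'   (best checkpoint).
#' @export
train_model <- function(records, val_cases, config = train_config(),
                        seed = 1, verbose = FALSE) {
  if (!length(records)) stop_user("train_model: empty training set")
  with_seed(seed, {
    model <- build_model(config_encoder(config))
    opt <- amsgrad(lr = config$lr, weight_decay = config$weight_decay)
    K <- config$n_classes
    g <- config$grid_size
    J <- g * g
    dec_size <- g * 8L
    # the decoder only receives gradient through annotated-positive
    # channels; skip it entirely when no record carries annotation maps
    any_annotated <- any(vapply(records, function(r) !is.null(r$maps),
                                logical(1)))
    use_decoder <- config$weights$lambda_T > 0 && any_annotated
    log_rows <- list()
    checkpoints <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(records))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        N <- length(bi)
        x <- array(0, c(config$input_size, config$input_size, 1, N))
        status <- matrix("", K, N)
        targets <- array(FALSE, c(J, K, N))
        dec_targets <- if (use_decoder) {
          array(0, c(dec_size, dec_size, K, N))
        }
        for (j in seq_len(N)) {
          rec <- records[[bi[j]]]
          img <- rec$image
          maps <- rec$maps %||% list()
          if (!is.null(config$augment)) {
            a <- augment_pair(img, maps, config$augment)
            img <- a$image
            maps <- a$maps
          }
          x[, , 1, j] <- img
          st <- record_status(rec, config$labels)
          status[, j] <- st
          for (k in which(st == "annotated_positive")) {
            mp <- maps[[config$labels[k]]]
            ga <- to_grid(mp, config$heatmap_threshold, c(g, g))
            targets[, k, j] <- as.vector(ga$cells) > 0
            if (use_decoder) {
              dec_targets[, , k, j] <- to_decoder_target(
                mp, config$heatmap_threshold, c(dec_size, dec_size))
            }
          }
        }
        fwd <- model_forward(model, x, train = TRUE,
                             with_decoder = use_decoder)
        model <- fwd$model
        gam <- array(fwd$grid_logits, c(J, K, N))
        mg <- mil_loss_grad(gam, status, targets, config$weights,
                            config$spec)
        d_dec <- NULL
        l_mtl <- 0
        if (use_decoder) {
          mt <- mtl_loss(fwd$decoder_logits, dec_targets, status,
                         want_grad = TRUE)
          l_mtl <- mt$loss
          d_dec <- mt$dlogits * config$weights$lambda_T
        }
        grads <- model_backward(model, fwd,
                                array(mg$dgamma, dim(fwd$grid_logits)),
                                d_dec)
        step <- amsgrad_step(opt, model_params(model),
                             model_grads(model, grads))
        opt <- step$opt
        model <- set_model_params(model, step$params)
        ep_loss <- ep_loss + total_loss(mg$loss, l_mtl, config$weights) * N
      }
      ep_loss <- ep_loss / length(records)
      val_auc <- if (length(val_cases)) {
        sc <- predict_scores(model, lapply(val_cases, `[[`, "image"),
                             config)
        lab_m <- do.call(rbind, lapply(val_cases, function(cs) {
          as.integer(cs$labels[config$labels] %in% TRUE)
        }))
        mean(evaluate_auc(sc, lab_m), na.rm = TRUE)
      } else NA_real_
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                      val_auc = val_auc)
      checkpoints[[epoch]] <- model
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val AUC %.4f", epoch,
                        ep_loss, val_auc))
      }
    }
    log <- do.call(rbind, log_rows)
    best <- if (all(is.na(log$val_auc))) config$epochs else
      which.max(log$val_auc)
    structure(list(config = config, seed = seed, log = log,
                   checkpoints = checkpoints, best_epoch = best,
                   model = checkpoints[[best]]),
              class = "gazemil_fit")
  })
}

# ---- inference and metrics ------------------------------------------------

#' Image-level soft-OR scores for a set of images
#' @param model a `gazemil_model`.
#' @param images list of matrices at the configured input size.
#' @param config a [train_config()] (normalization spec, batch size).
#' @return `[n_images x n_classes]` score matrix.
#' @export
predict_scores <- function(model, images, config = train_config()) {
  K <- config$n_classes
  out <- matrix(NA_real_, length(images), K)
  idx <- split(seq_along(images), ceiling(seq_along(images) /
                                            config$batch_size))
  for (bi in idx) {
    x <- array(0, c(config$input_size, config$input_size, 1, length(bi)))
    for (j in seq_along(bi)) x[, , 1, j] <- images[[bi[j]]]
    fwd <- model_forward(model, x, train = FALSE, with_decoder = FALSE)
    for (j in seq_along(bi)) {
      gam <- matrix(fwd$grid_logits[, , , j],
                    nrow = config$grid_size^2, ncol = K)
      out[bi[j], ] <- image_probability(gam, config$spec)
    }
  }
  out
}

#' Per-class localization heatmaps from a trained model
#'
#' @inheritParams predict_scores
#' @param source `"decoder"` (sigmoid of decoder logit maps) or
#'   `"spatial"` (sigmoid of grid logits, the spatial activations).
#' @return list (per image) of `[h, w, n_classes]` arrays.
#' @export
predict_heatmaps <- function(model, images, config = train_config(),
                             source = c("decoder", "spatial")) {
  source <- match.arg(source)
  out <- vector("list", length(images))
  idx <- split(seq_along(images), ceiling(seq_along(images) /
                                            config$batch_size))
  for (bi in idx) {
    x <- array(0, c(config$input_size, config$input_size, 1, length(bi)))
    for (j in seq_along(bi)) x[, , 1, j] <- images[[bi[j]]]
    fwd <- model_forward(model, x, train = FALSE,
                         with_decoder = source == "decoder")
    maps <- if (source == "decoder") sigmoid(fwd$decoder_logits) else
      fwd$spatial_activation
    for (j in seq_along(bi)) out[[bi[j]]] <- maps[, , , j, drop = FALSE]
  }
  lapply(out, function(a) array(a, dim(a)[1:3]))
}

#' Per-label AUC of image-level scores
#'
#' @param scores `[n x K]` score matrix.
#' @param labels `[n x K]` 0/1 matrix.
#' @return per-label AUC vector; labels with a single observed class are
#'   reported as `NA` (AUC undefined).
#' @export
evaluate_auc <- function(scores, labels) {
  vapply(seq_len(ncol(scores)), function(k) {
    y <- labels[, k]
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, scores[, k], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
}

#' IoU of model heatmaps against ground-truth masks
#'
#' Each positive (image, label) heatmap channel is binarized at the
#' label's threshold, upscaled to the mask resolution with
#' nearest-neighbour interpolation, and scored with IoU; results are
#' averaged over the positive pairs.
#'
#' @param heatmaps list (per case) of `[h, w, K]` arrays from
#'   [predict_heatmaps()].
#' @param cases list of cases with `masks` (named) and `labels`.
#' @param thresholds scalar or per-label named/numeric vector.
#' @param labels label ordering of the heatmap channels.
#' @return list with `pair_iou` (data.frame case/label/iou), `per_label`
#'   (named mean IoU) and `mean` (mean over pairs).
#' @export
evaluate_iou <- function(heatmaps, cases, thresholds,
                         labels = study_labels()) {
  if (length(thresholds) == 1) {
    thresholds <- stats::setNames(rep(thresholds, length(labels)), labels)
  }
  rows <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    for (lab in names(cs$masks)) {
      k <- match(lab, labels)
      if (is.na(k)) next
      mask <- cs$masks[[lab]]
      hm <- nn_resize(heatmaps[[i]][, , k], nrow(mask), ncol(mask))
      rows[[length(rows) + 1L]] <- data.frame(
        case = cs$id %||% i, label = lab,
        iou = heatmap_iou(hm, mask, thresholds[[lab]]),
        stringsAsFactors = FALSE)
    }
  }
  pair <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(0), label = character(0),
               iou = numeric(0))
  per_label <- tapply(pair$iou, pair$label, mean)
  list(pair_iou = pair, per_label = per_label,
       mean = mean(pair$iou))
}

#' Validated binarization threshold per label
#'
#' Selects, per label, the threshold maximizing the mean validation IoU
#' across seeds, considering the full threshold grid; ties break toward
#' the lower threshold.
#'
#' @param heatmap_sets list over seeds of heatmap lists (as returned by
#'   [predict_heatmaps()] on the validation cases).
#' @param cases the validation cases (with masks).
#' @param grid threshold grid (increasing).
#' @param labels heatmap channel ordering.
#' @return named per-label threshold vector (labels without positive
#'   validation pairs get the grid midpoint).
#' @export
select_threshold <- function(heatmap_sets, cases, grid = seq(0.05, 0.95,
                                                             by = 0.05),
                             labels = study_labels()) {
  if (!length(grid)) stop_user("select_threshold: empty threshold grid")
  grid <- sort(grid)
  acc <- list()  # per label: matrix pairs x thresholds
  for (hs in heatmap_sets) {
    for (i in seq_along(cases)) {
      cs <- cases[[i]]
      for (lab in names(cs$masks)) {
        k <- match(lab, labels)
        if (is.na(k)) next
        mask <- cs$masks[[lab]]
        hm <- nn_resize(hs[[i]][, , k], nrow(mask), ncol(mask))
        v <- vapply(grid, function(th) heatmap_iou(hm, mask, th),
                    numeric(1))
        acc[[lab]] <- rbind(acc[[lab]], v)
      }
    }
  }
  out <- stats::setNames(rep(grid[ceiling(length(grid) / 2)],
                             length(labels)), labels)
  for (lab in names(acc)) {
    mi <- colMeans(acc[[lab]])
    out[[lab]] <- grid[which.max(mi)]   # which.max takes the lowest tie
  }
  out
}

#' Choose the heatmap source with the better validation IoU
#' @param iou_by_source named numeric vector (e.g. `c(decoder = .3,
#'   spatial = .2)`).
#' @return the winning source name; exact ties go to `"spatial"` (the
#'   simpler source).
#' @export
select_heatmap_source <- function(iou_by_source) {
  if (isTRUE(iou_by_source[["spatial"]] >= iou_by_source[["decoder"]])) {
    "spatial"
  } else "decoder"
}

# ---- experiment drivers ---------------------------------------------------

#' Train and evaluate one supervision method over several seeds
#'
#' Full protocol: per seed, train on the prepared records, pick the best
#' epoch by mean validation AUC; then select the validated per-label
#' threshold (averaged across seeds) and the heatmap source per method by
#' validation IoU; finally report mean test IoU and AUC across seeds.
#'
#' @param ds dataset from [simulate_dataset()].
#' @param method `"et"`, `"ellipse"`, `"unannotated"`, or
#'   `"whole_session"` (ablation variant of `"et"`).
#' @param config a [train_config()].
#' @param seeds training seeds (default `config$seeds`).
#' @param policy ET extraction window policy.
#' @return a list with `fits`, `source`, `thresholds`, `test_iou`,
#'   `test_auc`, `val_iou`.
#' @export
run_method <- function(ds, method, config = train_config(),
                       seeds = config$seeds, policy = window_policy()) {
  prep_method <- if (method == "whole_session") "et" else method
  records <- if (method == "whole_session") {
    prepare_whole_session_data(ds$train, config)
  } else {
    prepare_training_data(ds$train, prep_method, config, policy)
  }
  records <- c(records, prepare_training_data(ds$unannotated, "unannotated",
                                              config))
  fits <- lapply(seeds, function(s) {
    train_model(records, ds$val, config, seed = s)
  })
  val_images <- lapply(ds$val, `[[`, "image")
  test_images <- lapply(ds$test, `[[`, "image")
  sources <- c("decoder", "spatial")
  val_hm <- lapply(sources, function(src) {
    lapply(fits, function(f) {
      predict_heatmaps(f$model, val_images, config, src)
    })
  })
  names(val_hm) <- sources
  thr <- lapply(sources, function(src) {
    select_threshold(val_hm[[src]], ds$val, config$threshold_grid,
                     config$labels)
  })
  names(thr) <- sources
  val_iou <- vapply(sources, function(src) {
    mean(vapply(val_hm[[src]], function(hs) {
      evaluate_iou(hs, ds$val, thr[[src]], config$labels)$mean
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  src <- select_heatmap_source(val_iou)
  test_iou <- mean(vapply(fits, function(f) {
    hm <- predict_heatmaps(f$model, test_images, config, src)
    evaluate_iou(hm, ds$test, thr[[src]], config$labels)$mean
  }, numeric(1)), na.rm = TRUE)
  lab_m <- do.call(rbind, lapply(ds$test, function(cs) {
    as.integer(cs$labels[config$labels] %in% TRUE)
  }))
  test_auc <- mean(vapply(fits, function(f) {
    mean(evaluate_auc(predict_scores(f$model, test_images, config), lab_m),
         na.rm = TRUE)
  }, numeric(1)), na.rm = TRUE)
  list(method = method, fits = fits, source = src,
       thresholds = thr[[src]], val_iou = val_iou,
       test_iou = test_iou, test_auc = test_auc)
}

#' Compare supervision methods (ET vs ellipse vs unannotated)
#'
#' @inheritParams run_method
#' @param methods methods to run.
#' @return data.frame with one row per method: `test_iou`, `test_auc`,
#'   chosen `source`; the full per-method results are attached as the
#'   `"runs"` attribute.
#' @export
run_supervision_experiment <- function(ds, config = train_config(),
                                       methods = c("unannotated", "et",
                                                   "ellipse"),
                                       seeds = config$seeds) {
  runs <- lapply(methods, function(m) run_method(ds, m, config, seeds))
  names(runs) <- methods
  out <- data.frame(
    method = methods,
    test_iou = vapply(runs, `[[`, numeric(1), "test_iou"),
    test_auc = vapply(runs, `[[`, numeric(1), "test_auc"),
    source = vapply(runs, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  out
}

#' Component ablation harness
#'
#' Re-trains the ET-supervised model with components toggled: LSH
#' (label-specific heatmaps vs one whole-session heatmap), BRN (balanced
#' vs fixed [0.98, 1] normalization), MRA (multi-resolution taps), MTL
#' (decoder loss). The all-off row is the plain MIL baseline.
#'
#' @param ds dataset from [simulate_dataset()].
#' @param config base [train_config()].
#' @param combos data.frame with logical columns `lsh`, `brn`, `mra`,
#'   `mtl`, one row per requested combination.
#' @param seeds training seeds.
#' @return `combos` with an added `test_iou` column.
#' @export
ablation_suite <- function(ds, config = train_config(),
                           combos = expand.grid(lsh = c(FALSE, TRUE),
                                                brn = c(FALSE, TRUE),
                                                mra = c(FALSE, TRUE),
                                                mtl = c(FALSE, TRUE)),
                           seeds = config$seeds) {
  ious <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- config
    cfg$spec <- norm_spec(if (combos$brn[i]) "balanced" else "fixed_098",
                          config$spec$base)
    cfg$multi_resolution <- combos$mra[i]
    if (!combos$mtl[i]) cfg$weights <- loss_weights(
      config$weights$lambda_A, 0)
    method <- if (combos$lsh[i]) "et" else "whole_session"
    ious[i] <- run_method(ds, method, cfg, seeds)$test_iou
  }
  combos$test_iou <- ious
  combos
}
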