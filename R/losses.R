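#' Range-normalization specification for MIL product factors
#'
#' Products over many per-cell probabilities underflow and make their range
#' depend on the number of factors. Balanced range normalization remaps
#' every factor affinely onto `[base^(1/nt), 1]`, where `nt` is the number
#' of factors in the product, so the full product of floor-valued factors
#' always equals `base` regardless of grid size. With the default base
#' 0.0056738 the per-factor floor is 0.98 when `nt = 256`, matching the
#' earlier fixed `[0.98, 1]` scheme at that grid size (`mode =
#' "fixed_098"`); `mode = "none"` disables normalization.
#'
#' @param mode `"balanced"`, `"fixed_098"` or `"none"`.
#' @param base product floor for balanced mode, in (0, 1).
#' @return a `norm_spec` object.
#' @export
norm_spec <- function(mode = c("balanced", "fixed_098", "none"),
                      base = 0.0056738) {
  mode <- match.arg(mode)
  if (base <= 0 || base >= 1) stop_user("norm_spec: base must be in (0,1)")
  structure(list(mode = mode, base = base), class = "norm_spec")
}

#' Per-factor floor of a normalization spec
#' @param nt number of factors being multiplied (>= 1).
#' @param spec a [norm_spec()].
#' @return scalar floor in `[0, 1)`.
#' @export
factor_floor <- function(nt, spec = norm_spec()) {
  if (nt < 1) stop_user("factor_floor: nt must be >= 1")
  switch(spec$mode,
         balanced = spec$base^(1 / nt),
         fixed_098 = 0.98,
         none = 0)
}

#' Remap a product factor into its normalized range
#' @param f probability factor in `[0, 1]` (vectorized).
#' @inheritParams factor_floor
#' @return `lo + (1 - lo) * f` with `lo = factor_floor(nt, spec)`.
#' @export
normalize_factor <- function(f, nt, spec = norm_spec()) {
  lo <- factor_floor(nt, spec)
  lo + (1 - lo) * f
}

as_cell_matrix <- function(gamma) {
  d <- dim(gamma)
  if (is.null(d)) return(matrix(gamma, ncol = 1))
  if (length(d) == 2) return(gamma)
  if (length(d) == 3) return(matrix(gamma, nrow = d[1] * d[2], ncol = d[3]))
  stop_user("expected grid logits as a vector, [cells x classes] matrix, ",
            "or [h x w x classes] array")
}

#' Soft-OR image-level probability from grid logits
#'
#' `Ck = 1 - prod_j g(1 - sigmoid(gamma_jk))`, a differentiable relaxation
#' of the Boolean OR over grid cells, with each complement factor passed
#' through the range normalization `g`. Computed in log space (sum of
#' logs, `-expm1`) so large grids cannot underflow.
#'
#' @param gamma grid logits: vector (one class), `[cells x classes]`
#'   matrix, or `[h x w x classes]` array.
#' @param spec a [norm_spec()].
#' @return per-class probability vector.
#' @export
image_probability <- function(gamma, spec = norm_spec()) {
  g <- as_cell_matrix(gamma)
  lo <- factor_floor(nrow(g), spec)
  log_p <- colSums(log(lo + (1 - lo) * (1 - sigmoid(g))))
  -expm1(log_p)
}

#' MIL loss for an annotated (image, class)
#'
#' Cells inside the annotated set `B` are pushed positive, cells outside
#' negative: the negative log of a single joint product whose factor count
#' `nt` is the full cell count (the normalization therefore uses one floor
#' for both groups).
#'
#' @param gamma_k logits of one class over the grid (any shape).
#' @param B annotated positive cells: integer indices or logical/0-1 mask.
#' @param spec a [norm_spec()].
#' @return scalar loss (>= 0).
#' @export
loss_annotated <- function(gamma_k, B, spec = norm_spec()) {
  g <- as.numeric(gamma_k)
  t <- cells_to_logical(B, length(g))
  lo <- factor_floor(length(g), spec)
  s <- sigmoid(g)
  -sum(log(lo + (1 - lo) * ifelse(t, s, 1 - s)))
}

# B may be a logical mask, a 0/1 matrix (grid_annotation cells), or a
# vector of positive-cell indices.
cells_to_logical <- function(B, n) {
  if (is.null(B)) return(rep(FALSE, n))
  if (inherits(B, "grid_annotation")) B <- B$cells
  if (is.logical(B)) {
    if (length(B) != n) stop_user("annotated mask length mismatch")
    return(as.vector(B))
  }
  if (!is.null(dim(B)) || (length(B) == n && n > 1 && all(B %in% c(0, 1)))) {
    if (length(B) != n) stop_user("annotated mask length mismatch")
    return(as.vector(B) > 0.5)
  }
  out <- rep(FALSE, n)
  if (length(B)) {
    if (any(B < 1 | B > n)) stop_user("annotated cell index outside grid")
    out[as.integer(B)] <- TRUE
  }
  out
}

#' MIL loss for an unannotated positive (image, class): `-log Ck`
#' @inheritParams loss_annotated
#' @export
loss_unannotated_positive <- function(gamma_k, spec = norm_spec()) {
  g <- as.numeric(gamma_k)
  lo <- factor_floor(length(g), spec)
  log_p <- sum(log(lo + (1 - lo) * (1 - sigmoid(g))))
  -log1mexp(min(log_p, 0))
}

#' MIL loss for an unannotated negative (image, class): all cells negative
#' @inheritParams loss_annotated
#' @export
loss_unannotated_negative <- function(gamma_k, spec = norm_spec()) {
  loss_annotated(gamma_k, integer(0), spec)
}

#' Loss weights
#' @param lambda_A weight of annotated images in the MIL loss (default 3).
#' @param lambda_T weight of the multi-task decoder loss (default 300).
#' @export
loss_weights <- function(lambda_A = 3, lambda_T = 300) {
  if (lambda_A < 0 || lambda_T < 0) stop_user("loss weights must be >= 0")
  list(lambda_A = lambda_A, lambda_T = lambda_T)
}

#' Annotation status codes per (image, class)
#'
#' `annotated_positive` (localization annotation with positive cells
#' available), `annotated_negative` (image has localization annotations,
#' class absent), `unannotated_positive`, `unannotated_negative`.
#' @return character vector of the four codes.
#' @export
annotation_statuses <- function() {
  c("annotated_positive", "annotated_negative",
    "unannotated_positive", "unannotated_negative")
}

#' Batch MIL loss
#'
#' Mean over images and classes of
#' `lambda_A * 1A * L_A + 1U+ * L_U+ + 1U- * L_U-`.
#'
#' @param batch list of images; each a list with `gamma` (`[cells x
#'   classes]` or `[h x w x classes]` logits), `status` (character vector,
#'   one of [annotation_statuses()] per class) and `B` (list per class of
#'   positive-cell indices or masks, used for `annotated_positive`).
#' @param weights a [loss_weights()].
#' @param spec a [norm_spec()].
#' @return scalar loss.
#' @export
mil_loss <- function(batch, weights = loss_weights(), spec = norm_spec()) {
  arrs <- batch_to_arrays(batch)
  mil_loss_grad(arrs$gamma, arrs$status, arrs$targets, weights, spec,
                want_grad = FALSE)$loss
}

batch_to_arrays <- function(batch) {
  gm <- lapply(batch, function(b) as_cell_matrix(b$gamma))
  J <- nrow(gm[[1]]); K <- ncol(gm[[1]]); N <- length(batch)
  gamma <- array(unlist(gm), dim = c(J, K, N))
  status <- vapply(batch, function(b) {
    st <- b$status
    if (length(st) != K) stop_user("status must have one entry per class")
    st
  }, character(K))
  status <- matrix(status, nrow = K, ncol = N)
  targets <- array(FALSE, dim = c(J, K, N))
  for (n in seq_len(N)) {
    for (k in seq_len(K)) {
      if (status[k, n] == "annotated_positive") {
        targets[, k, n] <- cells_to_logical(batch[[n]]$B[[k]], J)
      }
    }
  }
  list(gamma = gamma, status = status, targets = targets)
}

#' Batch MIL loss and analytic gradient (vectorized)
#'
#' Training-path implementation of the batch MIL objective. All terms are
#' evaluated in log space; gradients are derived by hand from the
#' normalized-factor form.
#'
#' @param gamma `[cells, classes, batch]` logit array.
#' @param status `[classes, batch]` character matrix of
#'   [annotation_statuses()].
#' @param targets `[cells, classes, batch]` logical array of annotated
#'   positive cells (only read where status is `annotated_positive`).
#' @param weights,spec see [mil_loss()].
#' @param want_grad compute `dgamma` (same shape as `gamma`).
#' @return list with `loss` and (optionally) `dgamma`.
#' @export
mil_loss_grad <- function(gamma, status, targets, weights = loss_weights(),
                          spec = norm_spec(), want_grad = TRUE) {
  d <- dim(gamma); J <- d[1]; K <- d[2]; N <- d[3]
  if (!all(dim(status) == c(K, N))) stop_user("mil_loss_grad: status shape")
  lo <- factor_floor(J, spec); om <- 1 - lo
  sig <- sigmoid(gamma)
  g_s <- lo + om * sig
  g_m <- lo + om * (1 - sig)
  sp <- sig * (1 - sig)

  is_ann <- status %in% c("annotated_positive", "annotated_negative")
  is_up <- status == "unannotated_positive"
  is_un <- status == "unannotated_negative"
  dim(is_ann) <- dim(is_up) <- dim(is_un) <- c(K, N)

  expand <- function(kn) array(rep(kn, each = J), dim = c(J, K, N))
  t <- targets & expand(is_ann)   # product-form target: B for annotated

  # product-form columns (annotated + unannotated negative): per-cell BCE
  # on normalized factors
  pf_cols <- expand(is_ann | is_un)
  cell_loss <- ifelse(t, -log(g_s), -log(g_m))
  loss_pf <- colSums(cell_loss * pf_cols, dims = 1)   # [K, N]

  # unannotated positive columns: -log Ck in log space
  log_p <- colSums(log(g_m), dims = 1)                # [K, N]
  log_p <- pmin(log_p, -1e-12)                        # cap at Ck >= ~1e-12
  log_ck <- log1mexp(log_p)
  loss_up <- -log_ck

  w_kn <- ifelse(is_ann, weights$lambda_A, 1)
  per_kn <- ifelse(is_up, loss_up, loss_pf)
  loss <- sum(w_kn * per_kn) / (K * N)

  out <- list(loss = loss)
  if (want_grad) {
    dg_pf <- om * sp * ifelse(t, -1 / g_s, 1 / g_m)
    ratio <- exp(log_p - log_ck)                      # P / Ck
    dg_up <- -expand(ratio) * om * sp / g_m
    dg <- ifelse(expand(is_up), dg_up, dg_pf * pf_cols)
    dg <- dg * expand(w_kn) / (K * N)
    out$dgamma <- dg
  }
  out
}

#' Multi-task decoder loss (pixel-level cross-entropy)
#'
#' Mean over images and classes of the per-pixel binary cross-entropy
#' between decoder logits and the binarized label-specific map, applied
#' only to channels whose status is `annotated_positive`; all other
#' channels contribute zero.
#'
#' @param decoder_logits `[h, w, classes, batch]` (or `[h, w, classes]`
#'   for a single image) logit array.
#' @param targets binary array of the same shape.
#' @param status `[classes, batch]` character matrix (or vector).
#' @param want_grad also return `dlogits`.
#' @return list with `loss` and optionally `dlogits` (gradient of the loss
#'   w.r.t. the decoder logits).
#' @export
mtl_loss <- function(decoder_logits, targets, status, want_grad = FALSE) {
  if (length(dim(decoder_logits)) == 3) {
    dim(decoder_logits) <- c(dim(decoder_logits), 1)
    dim(targets) <- dim(decoder_logits)
    status <- matrix(status, ncol = 1)
  }
  d <- dim(decoder_logits)
  if (!all(dim(targets) == d)) stop_user("mtl_loss: shape mismatch")
  h <- d[1]; w <- d[2]; K <- d[3]; N <- d[4]
  act <- matrix(status == "annotated_positive", K, N)
  out <- list(loss = 0)
  if (want_grad) out$dlogits <- array(0, dim = d)
  if (!any(act)) return(out)
  scale <- 1 / (h * w * K * N)
  total <- 0
  for (n in seq_len(N)) {
    for (k in seq_len(K)) {
      if (!act[k, n]) next
      z <- decoder_logits[, , k, n]
      t <- targets[, , k, n]
      # numerically stable BCE-with-logits
      total <- total + sum(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
      if (want_grad) out$dlogits[, , k, n] <- (sigmoid(z) - t) * scale
    }
  }
  out$loss <- total * scale
  out
}

#' Total training loss: `L_I + lambda_T * L_T`
#' @param l_mil MIL loss value.
#' @param l_mtl multi-task loss value.
#' @param weights a [loss_weights()].
#' @export
total_loss <- function(l_mil, l_mtl, weights = loss_weights()) {
  l_mil + weights$lambda_T * l_mtl
}
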