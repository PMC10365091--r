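`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) stats::plogis(x)

#' log(1 - exp(a)) for a <= 0, computed without catastrophic cancellation
#' @noRd
log1mexp <- function(a) {
  stopifnot(all(a <= 0 | is.na(a)))
  out <- a
  small <- a > -log(2)   # exp(a) close to 1: use expm1
  out[small] <- log(-expm1(a[small]))
  out[!small] <- log1p(-exp(a[!small]))
  out
}

#' Evaluate an expression under a temporary RNG seed, restoring the
#' caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Run-length encode a binary matrix (column-major scan) for JSON sidecars.
#' @noRd
rle_encode_mask <- function(m) {
  r <- rle(as.integer(m))
  list(dim = dim(m), values = r$values, lengths = r$lengths)
}

#' @noRd
rle_decode_mask <- function(enc) {
  v <- inverse.rle(structure(
    list(lengths = as.integer(enc$lengths), values = as.integer(enc$values)),
    class = "rle"))
  matrix(v, nrow = enc$dim[[1]], ncol = enc$dim[[2]])
}

#' Nearest-neighbour resize of a matrix (used when comparing model heatmaps
#' against ground-truth masks at their native resolution).
#' @noRd
nn_resize <- function(m, out_h, out_w) {
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * nrow(m) / out_h) + 1L, 1L),
             nrow(m))
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * ncol(m) / out_w) + 1L, 1L),
             ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Bilinear resize of a plain matrix via the package kernel.
#' @noRd
bilinear_resize_matrix <- function(m, out_h, out_w) {
  x <- array(m, dim = c(nrow(m), ncol(m), 1L, 1L))
  y <- bilinear_fw(x, as.integer(out_h), as.integer(out_w))
  matrix(y, nrow = out_h, ncol = out_w)
}

#' Concatenate a list of [H,W,C,N] arrays along the channel axis.
#' @noRd
cat_channels <- function(arrs) {
  d <- dim(arrs[[1]])
  chans <- vapply(arrs, function(a) dim(a)[3], integer(1))
  out <- array(0, dim = c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (a in arrs) {
    ca <- dim(a)[3]
    out[, , at + seq_len(ca), ] <- a
    at <- at + ca
  }
  out
}

#' Split a channel-gradient array back into per-source blocks.
#' @noRd
split_channels <- function(arr, chans) {
  out <- vector("list", length(chans))
  at <- 0L
  for (i in seq_along(chans)) {
    out[[i]] <- arr[, , at + seq_len(chans[i]), , drop = FALSE]
    at <- at + chans[i]
  }
  out
}

stop_user <- function(...) stop(..., call. = FALSE)
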