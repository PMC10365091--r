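#' Letterbox an image or annotation map to a square working resolution
#'
#' Aspect-preserving bilinear resize so the longest dimension equals
#' `target`, followed by centred black (zero) padding of the short
#' dimension. Images and their annotation maps must go through the same
#' transform to stay aligned; the returned transform also maps point
#' coordinates.
#'
#' @param m numeric matrix (rows = image rows).
#' @param target working resolution (pixels), default 512.
#' @param binary re-binarize the interpolated map at 0.5 (for masks).
#' @return list with `image` (`target x target` matrix) and `transform`
#'   (a `letterbox_transform`: `scale`, `pad_x`, `pad_y`, `target`,
#'   `orig = c(height, width)`).
#' @export
letterbox <- function(m, target = 512, binary = FALSE) {
  h <- nrow(m); w <- ncol(m)
  if (h <= 0 || w <= 0) stop_user("letterbox: non-positive dimensions")
  scale <- target / max(h, w)
  nh <- as.integer(round(h * scale)); nw <- as.integer(round(w * scale))
  rs <- if (nh == h && nw == w) m else bilinear_resize_matrix(m, nh, nw)
  if (binary) rs <- (rs > 0.5) * 1
  pad_y <- (target - nh) %/% 2L
  pad_x <- (target - nw) %/% 2L
  out <- matrix(0, target, target)
  out[pad_y + seq_len(nh), pad_x + seq_len(nw)] <- rs
  tf <- structure(list(scale = scale, pad_x = pad_x, pad_y = pad_y,
                       target = target, orig = c(h, w)),
                  class = "letterbox_transform")
  list(image = out, transform = tf)
}

#' Map point coordinates through a letterbox transform
#'
#' Uses the pixel-centre convention: a point at 0-based pixel `(x, y)` of
#' the original image lands at `(x + 0.5) * scale - 0.5 + pad` in the
#' letterboxed frame (continuous coordinates; round to index pixels).
#'
#' @param pts matrix or data.frame with columns `x`, `y` (0-based pixels).
#' @param transform a `letterbox_transform`.
#' @return data.frame with transformed `x`, `y`.
#' @export
letterbox_points <- function(pts, transform) {
  data.frame(
    x = (pts[, "x"] + 0.5) * transform$scale - 0.5 + transform$pad_x,
    y = (pts[, "y"] + 0.5) * transform$scale - 0.5 + transform$pad_y)
}

block_max <- function(m, grid_h, grid_w) {
  block_max_cpp(m, as.integer(grid_h), as.integer(grid_w))
}

#' Convert a heatmap to a binary grid annotation
#'
#' A grid cell is positive when the maximum of the heatmap over the cell's
#' pixel block exceeds `threshold`. Thresholding and max-pooling commute
#' (both are monotone), so the order is immaterial; binary ellipse masks
#' pass through the same path unchanged in semantics. Padding regions of a
#' letterboxed map are zero and therefore always negative.
#'
#' @param heatmap numeric matrix in `[0, 1]` at the letterboxed working
#'   geometry; its size must be an exact multiple of the grid.
#' @param threshold binarization threshold (default 0.15, chosen from the
#'   intensity histograms of extracted maps).
#' @param grid `c(rows, cols)` of the annotation grid (default 32 x 32).
#' @param label optional label name to attach.
#' @return a `grid_annotation`: `label`, `cells` (binary matrix),
#'   `positive_cells` (integer indices into `cells`, the annotated set).
#' @export
to_grid <- function(heatmap, threshold = 0.15, grid = c(32, 32),
                    label = NA_character_) {
  if (length(grid) == 1) grid <- c(grid, grid)
  if (nrow(heatmap) %% grid[1] != 0 || ncol(heatmap) %% grid[2] != 0) {
    stop_user("to_grid: grid ", grid[1], "x", grid[2],
              " does not evenly divide the map (",
              nrow(heatmap), "x", ncol(heatmap), ")")
  }
  cells <- (block_max(heatmap, grid[1], grid[2]) > threshold) * 1
  structure(list(label = label, cells = cells,
                 positive_cells = which(cells == 1)),
            class = "grid_annotation")
}

#' Convert a heatmap to a decoder supervision target
#'
#' Same block-max binarization as [to_grid()] but at the decoder output
#' resolution (256 x 256 at the 512-px working geometry).
#' @inheritParams to_grid
#' @param size `c(rows, cols)` of the target.
#' @return binary matrix of dimension `size`.
#' @export
to_decoder_target <- function(heatmap, threshold = 0.15, size = c(256, 256)) {
  if (length(size) == 1) size <- c(size, size)
  if (nrow(heatmap) %% size[1] != 0 || ncol(heatmap) %% size[2] != 0) {
    stop_user("to_decoder_target: size does not evenly divide the map")
  }
  (block_max(heatmap, size[1], size[2]) > threshold) * 1
}

#' Serialize grid annotations for one case to a JSON sidecar
#'
#' Cell masks are run-length encoded (column-major scan).
#' @param annotations named list of `grid_annotation` objects (per label).
#' @param path output JSON path.
#' @export
write_grid_annotations <- function(annotations, path) {
  payload <- lapply(annotations, function(a) {
    list(label = a$label, rle = rle_encode_mask(a$cells))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_annotations
#' @export
read_grid_annotations <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(p) {
    cells <- rle_decode_mask(p$rle)
    structure(list(label = p$label, cells = cells,
                   positive_cells = which(cells == 1)),
              class = "grid_annotation")
  })
  names(out) <- names(payload)
  out
}
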