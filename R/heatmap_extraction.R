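#' Fixation-selection window policy
#'
#' A policy maps a label mention to the time window whose fixations enter
#' the mention's heatmap. The default reproduces the validated rule: start
#' at `max(start of mentioning sentence - delay, start of the previous
#' sentence)` with a delay of 1.5 s (gaze leads dictation by about that
#' much), end at the end of the last mention in the sentence. For the first
#' sentence the previous-sentence cap falls back to the recording start.
#'
#' @param start_rule one of `"mention_sentence_start_minus_delay_capped_prev"`,
#'   `"first_mention_minus_delay_capped_prev"`,
#'   `"sentence_end_minus_delay_capped_prev"`, `"report_start"`,
#'   `"prev_sentence_start"`, `"prev_sentence_end"`,
#'   `"mention_sentence_start"`, `"recording_start"`.
#' @param end_rule one of `"mention_sentence_start"`,
#'   `"mention_sentence_end"`, `"first_mention_end"`, `"last_mention_end"`.
#' @param delay non-negative delay in seconds (used by the `*_minus_delay_*`
#'   start rules).
#' @return a `window_policy` object.
#' @export
window_policy <- function(
    start_rule = "mention_sentence_start_minus_delay_capped_prev",
    end_rule = "last_mention_end", delay = 1.5) {
  start_rule <- match.arg(start_rule, start_rules())
  end_rule <- match.arg(end_rule, end_rules())
  if (delay < 0) stop_user("window_policy: delay must be >= 0")
  structure(list(start_rule = start_rule, end_rule = end_rule,
                 delay = delay), class = "window_policy")
}

#' @rdname window_policy
#' @export
start_rules <- function() {
  c("mention_sentence_start_minus_delay_capped_prev",
    "first_mention_minus_delay_capped_prev",
    "sentence_end_minus_delay_capped_prev",
    "report_start", "prev_sentence_start", "prev_sentence_end",
    "mention_sentence_start", "recording_start")
}

#' @rdname window_policy
#' @export
end_rules <- function() {
  c("mention_sentence_start", "mention_sentence_end",
    "first_mention_end", "last_mention_end")
}

#' Delay grids of the two-stage window validation
#'
#' Stage 1 sweeps coarse delays over all start/end rule combinations;
#' stage 2 refines the delay for the winning rule pair.
#' @return numeric vector of delays in seconds.
#' @export
stage1_delays <- function() c(2.5, 5.0, 7.5)

#' @rdname stage1_delays
#' @export
stage2_delays <- function() {
  c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.5, 3, 3.5, 4, 4.5, 5)
}

#' Compute the fixation-selection window for one mention
#'
#' @param session a `reading_session`.
#' @param mention one row of the data.frame returned by [find_mentions()]
#'   (or a list with `sentence_index`, `first_mention_end`,
#'   `last_mention_end`).
#' @param policy a [window_policy()].
#' @return `c(t0, t1)` in seconds, or `NULL` for an empty window
#'   (`t1 < t0`).
#' @export
mention_window <- function(session, mention, policy = window_policy()) {
  si <- mention$sentence_index
  if (si < 1 || si > length(session$sentences)) {
    stop_user("mention_window: mention references missing sentence index ",
              si)
  }
  sent <- session$sentences[[si]]
  prev_start <- if (si > 1) session$sentences[[si - 1]]$start else
    session$recording_start
  prev_end <- if (si > 1) session$sentences[[si - 1]]$end else
    session$recording_start
  t0 <- switch(policy$start_rule,
    mention_sentence_start_minus_delay_capped_prev =
      max(sent$start - policy$delay, prev_start),
    first_mention_minus_delay_capped_prev =
      max(mention$first_mention_end - policy$delay, prev_start),
    sentence_end_minus_delay_capped_prev =
      max(sent$end - policy$delay, prev_start),
    report_start = session$sentences[[1]]$start,
    prev_sentence_start = prev_start,
    prev_sentence_end = prev_end,
    mention_sentence_start = sent$start,
    recording_start = session$recording_start)
  t1 <- switch(policy$end_rule,
    mention_sentence_start = sent$start,
    mention_sentence_end = sent$end,
    first_mention_end = mention$first_mention_end,
    last_mention_end = mention$last_mention_end)
  if (t1 < t0) return(NULL)
  c(t0 = t0, t1 = t1)
}

#' Select the fixations overlapping a time window
#'
#' Fixations with nonzero temporal overlap with `[t0, t1]` are returned;
#' each carries a `weight_duration` equal to its overlap length, so
#' fixations straddling a window edge contribute proportionally.
#'
#' @inheritParams mention_window
#' @param t0,t1 window bounds in seconds (`t0 <= t1`).
#' @return fixation data.frame with an added `weight_duration` column.
#' @export
select_fixations <- function(session, t0, t1) {
  fx <- session$fixations
  if (is.null(fx) || nrow(fx) == 0 || t1 < t0) {
    fx <- fx[integer(0), , drop = FALSE]
    fx$weight_duration <- numeric(0)
    return(fx)
  }
  ov <- pmin(fx$end, t1) - pmax(fx$start, t0)
  keep <- ov > 0
  out <- fx[keep, , drop = FALSE]
  out$weight_duration <- ov[keep]
  rownames(out) <- NULL
  out
}

#' Render a duration-weighted Gaussian fixation heatmap
#'
#' Each fixation contributes an isotropic Gaussian centred at its image
#' position with standard deviation of one degree of visual angle
#' (per-fixation `ppd` metadata when present, else the `sigma` argument)
#' and amplitude equal to its duration. The summed map is divided by its
#' maximum so the peak is 1; with no fixations an all-zero map is returned.
#' Gaussians are truncated at four standard deviations (the omitted tail is
#' below 3.4e-4 of the peak).
#'
#' @param fixations fixation data.frame; `weight_duration` is used as the
#'   amplitude when present, else `duration`, else `end - start`.
#' @param image_shape `c(height, width)` in pixels.
#' @param sigma fallback Gaussian standard deviation in pixels (one degree
#'   of visual angle under the session's display geometry; 85 px/degree at
#'   a 512-px working resolution is the shipped default calibration).
#' @return numeric matrix `height x width` with values in `[0, 1]`.
#' @export
render_heatmap <- function(fixations, image_shape, sigma = 85) {
  h <- image_shape[1]; w <- image_shape[2]
  if (h <= 0 || w <= 0) stop_user("render_heatmap: non-positive image size")
  map <- matrix(0, nrow = h, ncol = w)
  if (is.null(fixations) || nrow(fixations) == 0) return(map)
  amp <- fixations$weight_duration %||% fixations$duration %||%
    (fixations$end - fixations$start)
  sig <- if (!is.null(fixations$ppd) && all(is.finite(fixations$ppd)) &&
               all(fixations$ppd > 0)) fixations$ppd else rep(sigma, nrow(fixations))
  for (i in seq_len(nrow(fixations))) {
    x0 <- fixations$x[i]; y0 <- fixations$y[i]; s <- sig[i]
    r <- ceiling(4 * s)
    clo <- max(1L, floor(x0 - r) + 1L); chi <- min(w, ceiling(x0 + r) + 1L)
    rlo <- max(1L, floor(y0 - r) + 1L); rhi <- min(h, ceiling(y0 + r) + 1L)
    if (clo > chi || rlo > rhi) next
    cs <- clo:chi; rs <- rlo:rhi
    gx <- exp(-((cs - 1 - x0)^2) / (2 * s^2))
    gy <- exp(-((rs - 1 - y0)^2) / (2 * s^2))
    map[rs, cs] <- map[rs, cs] + amp[i] * (gy %o% gx)
  }
  mx <- max(map)
  if (mx > 0) map <- map / mx
  map
}

#' Label-specific gaze heatmap for one session
#'
#' Renders one map per mention (each normalized to peak 1) and combines
#' them by pixelwise maximum. All mentions must share the label and be
#' non-negated; [find_mentions()] already merges same-sentence matches of a
#' label, so each row corresponds to one mentioning sentence and one
#' window.
#'
#' @inheritParams mention_window
#' @param label label name (attached to the result).
#' @param mentions mention rows for this label (non-negated).
#' @param sigma fallback Gaussian width in pixels, see [render_heatmap()].
#' @return a `gaze_heatmap` object: `label`, `map`, `n_fixations`.
#' @export
heatmap_for_label <- function(session, label, mentions,
                              policy = window_policy(), sigma = 85) {
  stopifnot(all(mentions$label == label), !any(mentions$negated))
  shape <- c(session$image_height, session$image_width)
  map <- matrix(0, shape[1], shape[2])
  nfix <- 0L
  for (i in seq_len(nrow(mentions))) {
    win <- mention_window(session, mentions[i, ], policy)
    if (is.null(win)) next
    fx <- select_fixations(session, win[1], win[2])
    nfix <- nfix + nrow(fx)
    if (nrow(fx)) map <- pmax(map, render_heatmap(fx, shape, sigma))
  }
  structure(list(label = label, map = map, n_fixations = nfix),
            class = "gaze_heatmap")
}

#' Extract all label-specific heatmaps of a session
#'
#' Pipeline entry point: detects mentions, computes one shared window per
#' mentioning sentence (mentions of several labels in the same sentence are
#' associated with the same heatmap, so the window end is the last mention
#' of any label in that sentence), renders each sentence map once and
#' max-aggregates the sentence maps per label.
#'
#' @inheritParams heatmap_for_label
#' @param mentions optional precomputed [find_mentions()] output; computed
#'   from `vocab` when `NULL`.
#' @param vocab vocabulary used when `mentions` is `NULL`.
#' @return named list of `gaze_heatmap` objects, one per label with at
#'   least one positive (non-negated) mention.
#' @export
extract_heatmaps <- function(session, mentions = NULL,
                             vocab = load_vocabulary(),
                             policy = window_policy(), sigma = 85) {
  if (is.null(mentions)) mentions <- find_mentions(session$sentences, vocab)
  pos <- mentions[!mentions$negated, , drop = FALSE]
  if (!nrow(pos)) return(list())
  shape <- c(session$image_height, session$image_width)
  out <- list()
  for (si in unique(pos$sentence_index)) {
    ms <- pos[pos$sentence_index == si, , drop = FALSE]
    shared <- list(sentence_index = si,
                   first_mention_end = min(ms$first_mention_end),
                   last_mention_end = max(ms$last_mention_end))
    win <- mention_window(session, shared, policy)
    if (is.null(win)) next
    fx <- select_fixations(session, win[1], win[2])
    smap <- render_heatmap(fx, shape, sigma)
    for (lab in ms$label) {
      if (is.null(out[[lab]])) {
        out[[lab]] <- structure(
          list(label = lab, map = smap, n_fixations = nrow(fx)),
          class = "gaze_heatmap")
      } else {
        out[[lab]]$map <- pmax(out[[lab]]$map, smap)
        out[[lab]]$n_fixations <- out[[lab]]$n_fixations + nrow(fx)
      }
    }
  }
  out
}

#' Whole-session gaze heatmap
#'
#' Heatmap over all fixations of the session regardless of dictation
#' timing -- the undifferentiated map that label-specific extraction is
#' designed to improve upon (used by the ablation harness).
#' @inheritParams heatmap_for_label
#' @return a `gaze_heatmap` with label `"(whole session)"`.
#' @export
whole_session_heatmap <- function(session, sigma = 85) {
  shape <- c(session$image_height, session$image_width)
  map <- render_heatmap(session$fixations, shape, sigma)
  structure(list(label = "(whole session)", map = map,
                 n_fixations = nrow(session$fixations)),
            class = "gaze_heatmap")
}

#' Intersection-over-union of a binarized map and a binary mask
#' @param map numeric matrix in `[0, 1]`.
#' @param mask binary matrix of the same size.
#' @param threshold binarization threshold applied to `map`.
#' @return IoU in `[0, 1]`; 0 when the union is empty.
#' @export
heatmap_iou <- function(map, mask, threshold) {
  b <- map > threshold
  m <- mask > 0.5
  u <- sum(b | m)
  if (u == 0) return(0)
  sum(b & m) / u
}

#' Sweep window policies against ground-truth masks
#'
#' Evaluates start-rule x end-rule x delay combinations by extracting
#' heatmaps for every positive label of every case and scoring them
#' against the case's ground-truth masks with IoU. For each combination
#' the binarization threshold maximizing the mean IoU over the sweep set
#' is selected from `thresholds` (recorded in the output); rows are
#' emitted only for combinations that produce at least one non-empty
#' window, and delay-free start rules appear once with `delay = NA`.
#' The best row is flagged.
#'
#' @param cases list of cases; each needs `$session` (a `reading_session`)
#'   and `$masks` (named list of binary matrices per positive label).
#'   Optional `$mentions` overrides labeler output.
#' @param start_rules,end_rules rule subsets to sweep.
#' @param delays delays for the delay-dependent start rules, seconds.
#' @param thresholds binarization threshold grid.
#' @param vocab vocabulary for mention detection.
#' @param sigma Gaussian width fallback, pixels.
#' @return data.frame with `start_rule`, `end_rule`, `delay`, `threshold`,
#'   `mean_iou`, `n_pairs`, `best`.
#' @export
sweep_policies <- function(cases, start_rules. = start_rules(),
                           end_rules. = end_rules(),
                           delays = stage2_delays(),
                           thresholds = seq(0.05, 0.95, by = 0.05),
                           vocab = load_vocabulary(), sigma = 85) {
  if (!length(thresholds)) stop_user("sweep_policies: empty threshold grid")
  has_mask <- vapply(cases, function(cs) length(cs$masks) > 0, logical(1))
  if (!any(has_mask)) stop_user("sweep_policies: no ground-truth masks")
  mention_cache <- lapply(cases, function(cs) {
    cs$mentions %||% find_mentions(cs$session$sentences, vocab)
  })
  delayed <- grepl("minus_delay", start_rules.)
  grid <- rbind(
    if (any(delayed)) expand.grid(start_rule = start_rules.[delayed],
                                  delay = delays,
                                  end_rule = end_rules.,
                                  stringsAsFactors = FALSE),
    if (any(!delayed)) expand.grid(start_rule = start_rules.[!delayed],
                                   delay = NA_real_,
                                   end_rule = end_rules.,
                                   stringsAsFactors = FALSE))
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    pol <- window_policy(grid$start_rule[g], grid$end_rule[g],
                         delay = if (is.na(grid$delay[g])) 0 else
                           grid$delay[g])
    ious <- matrix(NA_real_, nrow = 0, ncol = length(thresholds))
    n_windows <- 0L
    for (ci in seq_along(cases)) {
      cs <- cases[[ci]]
      if (!length(cs$masks)) next
      hm <- extract_heatmaps(cs$session, mentions = mention_cache[[ci]],
                             policy = pol, sigma = sigma)
      for (lab in names(cs$masks)) {
        h <- hm[[lab]]
        if (is.null(h)) next
        if (h$n_fixations > 0) n_windows <- n_windows + 1L
        ious <- rbind(ious, vapply(thresholds, function(th) {
          heatmap_iou(h$map, cs$masks[[lab]], th)
        }, numeric(1)))
      }
    }
    if (n_windows == 0L) next   # all windows empty: structurally negative
    mean_iou <- colMeans(ious)
    bi <- which.max(mean_iou)   # ties resolve to the lower threshold
    rows[[length(rows) + 1L]] <- data.frame(
      start_rule = grid$start_rule[g], end_rule = grid$end_rule[g],
      delay = grid$delay[g], threshold = thresholds[bi],
      mean_iou = mean_iou[bi], n_pairs = nrow(ious),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_user("sweep_policies: no valid policy produced a window")
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$mean_iou)
  rownames(out) <- NULL
  out
}

#' Write a gaze heatmap to disk
#'
#' The map is stored as a 16-bit grayscale TIFF plus a JSON sidecar with
#' the label, policy, window parameters and fixation count.
#' @param heatmap a `gaze_heatmap`.
#' @param path output image path (`.tif`); the sidecar gets `.json`.
#' @param policy the policy used for extraction (recorded in the sidecar).
#' @export
write_heatmap <- function(heatmap, path, policy = NULL) {
  tiff::writeTIFF(pmin(pmax(heatmap$map, 0), 1), path,
                  bits.per.sample = 16L)
  meta <- list(label = heatmap$label, n_fixations = heatmap$n_fixations,
               policy = if (!is.null(policy)) unclass(policy))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
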