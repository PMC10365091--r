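#' Parameters of the synthetic reading-session generator
#'
#' The generator emulates the behavioral structure that label-specific
#' heatmap extraction relies on: radiologists first scan the whole image
#' silently, then dictate one sentence per finding with silent gaps, with
#' gaze leading the dictation stream by a lag (gaze at time `t` attends
#' what is dictated at `t + gaze_lag`). During the attention interval of a
#' mentioning sentence, fixations cluster around the lesion; outside it
#' they scan the image uniformly. Fixation durations are log-normal;
#' lesions are additive elliptical intensity bumps with known binary
#' masks; image-level labels follow the vocabulary's grouping (parenchymal
#' findings also imply Opacity, whose mask is the union of its
#' constituents).
#'
#' @param n_cases number of cases to generate.
#' @param image_size square image size in pixels (128 for desk-scale runs,
#'   512 for full-scale geometry).
#' @param labels label set (default the ten study labels).
#' @param prevalence per-label positive probability (scalar or named
#'   vector).
#' @param lesion_radius_range ellipse semi-axis range as a fraction of the
#'   image size.
#' @param lesion_contrast_range additive lesion intensity range.
#' @param gaze_lag seconds by which gaze leads dictation (default 1.5).
#' @param fixation_rate fixations per second (approximate; durations are
#'   sampled, the rate sets their mean).
#' @param on_lesion_dispersion s.d. of on-lesion fixation scatter, as a
#'   fraction of image size.
#' @param scan_fraction probability that a fixation inside an attention
#'   interval nevertheless lands off-lesion.
#' @param speech_rate dictated words per second.
#' @param pause mean silent gap between sentences, seconds.
#' @param initial_silence silent scanning interval before the first
#'   sentence, seconds.
#' @param negation_rate per negative label, probability of adding a
#'   negated distractor sentence ("no ...").
#' @param fix_dur_meanlog,fix_dur_sdlog log-normal fixation duration
#'   parameters (mean about 0.25 s).
#' @param pixels_per_degree display calibration used as the Gaussian width
#'   (one degree of visual angle); default scales 85 px/degree at 512 px.
#' @param seed RNG seed for [simulate_dataset()].
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_cases = 50, image_size = 128,
                       labels = study_labels(), prevalence = 0.2,
                       lesion_radius_range = c(0.08, 0.2),
                       lesion_contrast_range = c(0.2, 0.4),
                       gaze_lag = 1.5, fixation_rate = 3,
                       on_lesion_dispersion = 0.06, scan_fraction = 0.15,
                       speech_rate = 2.5, pause = 2.0,
                       initial_silence = 5.0, negation_rate = 0.15,
                       fix_dur_meanlog = log(0.25), fix_dur_sdlog = 0.4,
                       pixels_per_degree = NULL, seed = 20260101) {
  if (length(prevalence) == 1) {
    prevalence <- stats::setNames(rep(prevalence, length(labels)), labels)
  }
  stopifnot(all(prevalence >= 0 & prevalence <= 1), gaze_lag >= 0,
            fixation_rate > 0, speech_rate > 0)
  structure(list(
    n_cases = n_cases, image_size = as.integer(image_size), labels = labels,
    prevalence = prevalence, lesion_radius_range = lesion_radius_range,
    lesion_contrast_range = lesion_contrast_range, gaze_lag = gaze_lag,
    fixation_rate = fixation_rate,
    on_lesion_dispersion = on_lesion_dispersion,
    scan_fraction = scan_fraction, speech_rate = speech_rate,
    pause = pause, initial_silence = initial_silence,
    negation_rate = negation_rate, fix_dur_meanlog = fix_dur_meanlog,
    fix_dur_sdlog = fix_dur_sdlog,
    pixels_per_degree = pixels_per_degree %||% (85 * image_size / 512),
    seed = seed), class = "sim_params")
}

# canonical dictation phrase per label (all resolve through the shipped
# vocabulary; parenchymal phrases also trigger an Opacity mention)
label_phrases <- function() {
  c("Abnormal Mediastinal Contour" = "abnormal mediastinal contour",
    "Atelectasis" = "atelectasis",
    "Enlarged Cardiac Silhouette" = "cardiomegaly",
    "Consolidation" = "consolidation",
    "Edema" = "pulmonary edema",
    "Fracture" = "rib fracture",
    "Lung Lesion" = "lung nodule",
    "Opacity" = "lung opacity",
    "Pleural Abnormality" = "pleural effusion",
    "Pneumothorax" = "pneumothorax")
}

opacity_children <- function() {
  c("Atelectasis", "Consolidation", "Edema", "Lung Lesion")
}

# characteristic image region per label (fractions of width/height):
# abnormalities appear in anatomically typical locations, which is what
# makes the label identity of a finding learnable from the image
label_homes <- function() {
  rbind("Abnormal Mediastinal Contour" = c(0.50, 0.40),
        "Atelectasis" = c(0.30, 0.70),
        "Enlarged Cardiac Silhouette" = c(0.55, 0.70),
        "Consolidation" = c(0.72, 0.55),
        "Edema" = c(0.35, 0.45),
        "Fracture" = c(0.15, 0.35),
        "Lung Lesion" = c(0.70, 0.30),
        "Opacity" = c(0.30, 0.30),
        "Pleural Abnormality" = c(0.85, 0.75),
        "Pneumothorax" = c(0.80, 0.20))
}

sample_ellipse <- function(size, radius_range, label = NULL) {
  homes <- label_homes()
  home <- if (!is.null(label) && label %in% rownames(homes)) {
    homes[label, ]
  } else c(runif(1, 0.25, 0.75), runif(1, 0.25, 0.75))
  clip <- function(v) min(max(v, 0.15 * size), 0.85 * size)
  list(cx = clip(home[1] * size + rnorm(1, 0, 0.07 * size)),
       cy = clip(home[2] * size + rnorm(1, 0, 0.07 * size)),
       a = runif(1, radius_range[1], radius_range[2]) * size,
       b = runif(1, radius_range[1], radius_range[2]) * size,
       angle = runif(1, 0, pi))
}

ellipse_field <- function(ellipse, size) {
  xs <- (seq_len(size) - 1)
  u0 <- outer(rep(1, size), xs) - ellipse$cx   # columns: x
  v0 <- outer(xs, rep(1, size)) - ellipse$cy   # rows: y
  ca <- cos(ellipse$angle); sa <- sin(ellipse$angle)
  u <- u0 * ca + v0 * sa
  v <- -u0 * sa + v0 * ca
  (u / ellipse$a)^2 + (v / ellipse$b)^2
}

ellipse_mask <- function(ellipse, size) (ellipse_field(ellipse, size) <= 1) * 1

#' Generate one synthetic reading session
#'
#' @param params a [sim_params()] list.
#' @param case_id identifier attached to the case.
#' @return a `synthetic_case`: `id`, `image` (matrix in `[0, 1]`), `masks`
#'   (named list of binary matrices for positive labels), `labels` (named
#'   logical), `session` (a [reading_session()]), `lag` (the programmed
#'   gaze lag).
#' @export
simulate_case <- function(params, case_id = "case") {
  size <- params$image_size
  labs <- params$labels
  pos <- runif(length(labs)) < params$prevalence[labs]
  names(pos) <- labs
  # label grouping closure: parenchymal findings imply Opacity
  kids <- intersect(opacity_children(), labs)
  opacity_direct <- isTRUE(pos["Opacity"])
  if ("Opacity" %in% labs && any(pos[kids])) pos["Opacity"] <- TRUE

  # lesions: one ellipse per mentioned label; Opacity's mask is the union
  mentioned <- names(pos)[pos]
  if ("Opacity" %in% mentioned && !opacity_direct) {
    mentioned <- setdiff(mentioned, "Opacity")
  }
  ellipses <- lapply(mentioned, function(l) sample_ellipse(
    size, params$lesion_radius_range, label = l))
  names(ellipses) <- mentioned
  masks <- lapply(ellipses, ellipse_mask, size = size)
  if (isTRUE(pos["Opacity"])) {
    om <- masks[["Opacity"]] %||% matrix(0, size, size)
    for (k in intersect(kids, names(masks))) om <- pmax(om, masks[[k]])
    masks[["Opacity"]] <- om
  }

  # distractor sentences: negated mentions of absent labels
  negated_labs <- names(pos)[!pos][
    runif(sum(!pos)) < params$negation_rate]
  plan <- c(lapply(mentioned, function(l) list(label = l, negated = FALSE)),
            lapply(negated_labs, function(l) list(label = l, negated = TRUE)))
  if (!length(plan)) {
    warning("simulate_case: degenerate case with no findings and no ",
            "distractor sentences (empty transcript)", call. = FALSE)
  }
  plan <- plan[sample.int(length(plan))]

  # dictation timeline
  phrases <- label_phrases()
  t <- params$initial_silence
  words <- list()
  attention <- list()
  templates <- list(c("there", "is"), c("stable"), c("findings", "of"))
  for (p in plan) {
    pw <- strsplit(phrases[[p$label]], " ")[[1]]
    toks <- if (p$negated) c("no", pw) else c(sample(templates, 1)[[1]], pw)
    toks[length(toks)] <- paste0(toks[length(toks)], ".")
    dur <- runif(length(toks), 0.85, 1.15) / params$speech_rate
    st <- t + c(0, cumsum(head(dur, -1)))
    en <- st + dur
    words[[length(words) + 1L]] <- data.frame(
      text = toks, start = st, end = en, stringsAsFactors = FALSE)
    if (!p$negated) {
      # gaze leads the dictation stream by `lag`: attention on this
      # lesion runs from lag before the sentence to lag before the end
      # of its mention (the phrase ends the sentence)
      attention[[length(attention) + 1L]] <- list(
        t0 = st[1] - params$gaze_lag,
        t1 = en[length(en)] - params$gaze_lag,
        cx = ellipses[[p$label]]$cx, cy = ellipses[[p$label]]$cy)
      # for lag = 0 the attention interval is exactly the dictation span
      if (params$gaze_lag == 0) attention[[length(attention)]]$t1 <-
        en[length(en)]
    }
    t <- en[length(en)] + params$pause * runif(1, 0.8, 1.2)
  }
  words <- if (length(words)) do.call(rbind, words) else
    data.frame(text = character(0), start = numeric(0), end = numeric(0))

  # fixation stream
  session_end <- if (nrow(words)) max(words$end) + 1.5 else
    params$initial_silence
  fx <- list()
  tcur <- 0
  disp <- params$on_lesion_dispersion * size
  while (tcur < session_end) {
    d <- min(max(rlnorm(1, params$fix_dur_meanlog, params$fix_dur_sdlog),
                 0.08), 1.0)
    # mean duration + saccade gap tuned to the requested fixation rate
    gap <- max(1 / params$fixation_rate - exp(params$fix_dur_meanlog +
                                                params$fix_dur_sdlog^2 / 2),
               0.04)
    win <- NULL
    for (a in attention) if (tcur >= a$t0 && tcur < a$t1) win <- a
    on_lesion <- !is.null(win) && runif(1) >= params$scan_fraction
    if (on_lesion) {
      x <- min(max(rnorm(1, win$cx, disp), 0), size - 1)
      y <- min(max(rnorm(1, win$cy, disp), 0), size - 1)
    } else {
      x <- runif(1, 0, size - 1)
      y <- runif(1, 0, size - 1)
    }
    fx[[length(fx) + 1L]] <- c(x = x, y = y, start = tcur, end = tcur + d)
    tcur <- tcur + d + gap
  }
  fixations <- as.data.frame(do.call(rbind, fx))
  fixations$ppd <- params$pixels_per_degree
  fixations$duration <- fixations$end - fixations$start

  # image: smooth background + lesion bumps
  lowfreq <- bilinear_resize_matrix(matrix(rnorm(81, 0, 0.06), 9, 9),
                                    size, size)
  img <- 0.35 + lowfreq + matrix(rnorm(size * size, 0, 0.03), size, size)
  for (l in names(ellipses)) {
    d2 <- ellipse_field(ellipses[[l]], size)
    contrast <- runif(1, params$lesion_contrast_range[1],
                      params$lesion_contrast_range[2])
    bump <- ifelse(d2 <= 1, contrast * sqrt(pmax(1 - d2, 0)), 0)
    img <- img + bump
  }
  img <- pmin(pmax(img, 0), 1)

  session <- reading_session(
    image_id = case_id, image_width = size, image_height = size,
    fixations = fixations, sentences = segment_sentences(words),
    recording_start = 0)
  structure(list(id = case_id, image = img, masks = masks,
                 labels = pos, session = session, lag = params$gaze_lag),
            class = "synthetic_case")
}

#' Generate a full synthetic dataset with splits
#'
#' Produces disjoint train/validation/test splits of fully annotated cases
#' plus an unannotated pool that carries only images and image-level
#' labels (no masks, no reading sessions). Fully reproducible from
#' `params$seed` (or the `seed` argument); the caller's RNG state is
#' restored afterwards.
#'
#' @param params a [sim_params()].
#' @param n_train,n_val,n_test annotated split sizes.
#' @param n_unannotated size of the image-level-only pool.
#' @param seed overrides `params$seed`.
#' @return list with `train`, `val`, `test` (lists of `synthetic_case`),
#'   `unannotated` (cases with `masks = NULL`, `session = NULL`) and
#'   `params`.
#' @export
simulate_dataset <- function(params, n_train = 30, n_val = 10, n_test = 10,
                             n_unannotated = 0, seed = NULL) {
  seed <- seed %||% params$seed
  with_seed(seed, {
    total <- n_train + n_val + n_test + n_unannotated
    cases <- lapply(seq_len(total), function(i) {
      simulate_case(params, sprintf("case_%04d", i))
    })
    split <- rep(c("train", "val", "test", "unannotated"),
                 c(n_train, n_val, n_test, n_unannotated))
    pool <- lapply(cases[split == "unannotated"], function(cs) {
      cs$masks <- NULL
      cs$session <- NULL
      cs
    })
    list(train = cases[split == "train"], val = cases[split == "val"],
         test = cases[split == "test"], unannotated = pool, params = params)
  })
}
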