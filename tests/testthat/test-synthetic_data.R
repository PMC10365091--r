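test_that("prevalence-one labels always get a mask and a mentioning sentence", {
  params <- sim_params(image_size = 64, prevalence = stats::setNames(
    c(1, rep(0, 9)), study_labels()))
  set.seed(40)
  for (i in 1:5) {
    cs <- simulate_case(params, "p1")
    expect_equal(names(cs$masks), "Abnormal Mediastinal Contour")
    m <- find_mentions(cs$session$sentences)
    m <- m[!m$negated, ]
    expect_true("Abnormal Mediastinal Contour" %in% m$label)
  }
})

test_that("generator honesty: mentions match lesions; negations add none", {
  params <- fast_sim_params(negation_rate = 0.4)
  set.seed(41)
  for (i in 1:6) {
    cs <- simulate_case(params, paste0("h", i))
    m <- find_mentions(cs$session$sentences)
    pos_mentioned <- unique(m$label[!m$negated])
    # every positive (non-negated) mention of a positive label has a mask
    for (lab in intersect(pos_mentioned, names(cs$labels)[cs$labels])) {
      expect_false(is.null(cs$masks[[lab]]))
      expect_gt(sum(cs$masks[[lab]]), 0)
    }
    # negated-only labels are negative and have no mask
    neg_only <- setdiff(unique(m$label[m$negated]), pos_mentioned)
    for (lab in neg_only) {
      expect_false(isTRUE(cs$labels[[lab]]))
      expect_null(cs$masks[[lab]])
    }
    # every positive label has a mask and a mentioning sentence
    for (lab in names(cs$labels)[cs$labels]) {
      expect_false(is.null(cs$masks[[lab]]))
      expect_true(lab %in% pos_mentioned)
    }
  }
})

test_that("zero lag starts on-lesion attention at the sentence start", {
  params <- sim_params(image_size = 64, gaze_lag = 0, prevalence =
                         stats::setNames(c(rep(0, 9), 1), study_labels()),
                       scan_fraction = 0, initial_silence = 2,
                       negation_rate = 0)
  set.seed(42)
  cs <- simulate_case(params, "lag0")
  sent <- cs$session$sentences[[1]]
  fx <- cs$session$fixations
  during <- fx[fx$start >= sent$start & fx$start < sent$end, ]
  el_center <- c(mean(which(rowSums(cs$masks[[1]]) > 0)),
                 mean(which(colSums(cs$masks[[1]]) > 0)))
  # fixations during the dictation cluster near the lesion centre
  expect_lt(mean(sqrt((during$y + 1 - el_center[1])^2 +
                        (during$x + 1 - el_center[2])^2)),
            0.35 * 64)
})

test_that("datasets are reproducible, split correctly and strip the pool", {
  params <- sim_params(image_size = 32, n_cases = 8)
  ds1 <- simulate_dataset(params, 4, 2, 2, 3, seed = 43)
  ds2 <- simulate_dataset(params, 4, 2, 2, 3, seed = 43)
  expect_identical(ds1, ds2)
  ds3 <- simulate_dataset(params, 4, 2, 2, 3, seed = 44)
  expect_false(identical(ds1$train[[1]]$image, ds3$train[[1]]$image))

  expect_length(ds1$train, 4)
  expect_length(ds1$val, 2)
  expect_length(ds1$test, 2)
  expect_length(ds1$unannotated, 3)
  ids <- unlist(lapply(c(ds1$train, ds1$val, ds1$test, ds1$unannotated),
                       `[[`, "id"))
  expect_false(any(duplicated(ids)))
  for (cs in ds1$unannotated) {
    expect_null(cs$masks)
    expect_null(cs$session)
    expect_false(is.null(cs$labels))
  }
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(45)
  before <- .Random.seed
  invisible(simulate_dataset(sim_params(image_size = 32), 1, 1, 1, 0,
                             seed = 46))
  expect_identical(.Random.seed, before)
})

test_that("label-specific extraction beats the whole-session map on most lesions", {
  params <- fast_sim_params()
  ds <- simulate_dataset(params, 0, 0, 12, seed = 47)
  wins <- 0L; total <- 0L
  for (cs in ds$test) {
    hm <- extract_heatmaps(cs$session)
    ws <- whole_session_heatmap(cs$session)
    for (lab in names(cs$masks)) {
      h <- hm[[lab]]
      if (is.null(h)) next
      grid <- seq(0.05, 0.95, 0.05)
      iou_ls <- max(vapply(grid, function(t)
        heatmap_iou(h$map, cs$masks[[lab]], t), numeric(1)))
      iou_ws <- max(vapply(grid, function(t)
        heatmap_iou(ws$map, cs$masks[[lab]], t), numeric(1)))
      total <- total + 1L
      if (iou_ls > iou_ws) wins <- wins + 1L
    }
  }
  expect_gt(total, 10)
  expect_gt(wins / total, 0.6)
})
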