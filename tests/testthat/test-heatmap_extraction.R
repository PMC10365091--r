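test_that("the default window rule follows the delay-capped-by-previous-sentence form", {
  s <- toy_session(c(10, 14), c(12, 17))
  # mention in sentence 2, last mention ends at 16.0
  w <- mention_window(s, mention_row(2, 15.0, 16.0))
  expect_equal(unname(w), c(max(14 - 1.5, 10), 16.0))

  # previous sentence starting later than start - delay caps the window
  s2 <- toy_session(c(13.2, 14), c(13.8, 17))
  w2 <- mention_window(s2, mention_row(2, 15.0, 16.0))
  expect_equal(unname(w2[1]), 13.2)

  # first sentence: the cap falls back to the recording start
  s3 <- toy_session(2.0, 5.0, recording_start = 0)
  w3 <- mention_window(s3, mention_row(1, 4.0))
  expect_equal(unname(w3[1]), 0.5)

  expect_error(mention_window(s, mention_row(9, 1)), "missing sentence")
})

test_that("empty windows and alternative rules behave", {
  s <- toy_session(c(10, 14), c(12, 17))
  # end before start yields an empty window
  pol <- window_policy("mention_sentence_start", "first_mention_end")
  expect_null(mention_window(s, mention_row(2, 13.5), pol))
  # delay-free rules
  w <- mention_window(s, mention_row(2, 15, 16),
                      window_policy("prev_sentence_end", "last_mention_end"))
  expect_equal(unname(w), c(12, 16))
  w <- mention_window(s, mention_row(2, 15, 16),
                      window_policy("recording_start",
                                    "mention_sentence_start"))
  expect_equal(unname(w), c(0, 14))
  expect_error(window_policy(delay = -1), "delay")
})

test_that("fixation selection clips durations to the window overlap", {
  fx <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3),
                   start = c(12.0, 16.5, 14.0), end = c(13.0, 17.0, 15.0))
  s <- toy_session(10, 12, fixations = fx)
  sel <- select_fixations(s, 12.5, 16.0)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$weight_duration[sel$x == 1], 0.5)
  expect_equal(sel$weight_duration[sel$x == 3], 1.0)

  # zero temporal overlap (touching the boundary) is excluded
  fx2 <- data.frame(x = 1, y = 1, start = 16.0, end = 16.5)
  s2 <- toy_session(10, 12, fixations = fx2)
  expect_equal(nrow(select_fixations(s2, 12.5, 16.0)), 0)
  expect_equal(nrow(select_fixations(s2, 17, 16)), 0)
})

test_that("rendered heatmaps are duration-weighted normalized Gaussian sums", {
  fx <- data.frame(x = 64, y = 64, start = 0, end = 0.7)
  m <- render_heatmap(fx, c(128, 128), sigma = 5)
  expect_equal(m[65, 65], 1)
  expect_equal(which(m == max(m)), 65 + 64 * 128)

  # two distant fixations with durations 2t and t: peaks 1 and ~0.5
  fx2 <- data.frame(x = c(20, 100), y = c(20, 100), start = c(0, 1),
                    end = c(0.8, 1.4))
  m2 <- render_heatmap(fx2, c(128, 128), sigma = 3)
  expect_equal(m2[21, 21], 1)
  expect_equal(m2[101, 101], 0.5, tolerance = 1e-6)

  expect_equal(max(render_heatmap(fx[0, ], c(64, 64), 5)), 0)
  expect_error(render_heatmap(fx, c(0, 64), 5), "image size")
})

test_that("normalization is invariant to rescaling all durations", {
  set.seed(2)
  fx <- data.frame(x = runif(15, 0, 127), y = runif(15, 0, 127),
                   start = 0, end = runif(15, 0.1, 0.6))
  m1 <- render_heatmap(fx, c(128, 128), sigma = 10)
  fx2 <- fx
  fx2$end <- fx$start + 2 * (fx$end - fx$start)
  m2 <- render_heatmap(fx2, c(128, 128), sigma = 10)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("per-label aggregation is a commutative max of per-mention maps", {
  fx <- data.frame(x = c(20, 100), y = c(20, 100),
                   start = c(10.5, 14.5), end = c(11.2, 15.2))
  s <- toy_session(c(10, 14), c(12, 17), fixations = fx)
  men <- rbind(mention_row(1, 11.5), mention_row(2, 15.5, 16))
  h <- heatmap_for_label(s, "Opacity", men, window_policy(), sigma = 3)
  expect_equal(h$map[21, 21], 1)
  expect_equal(h$map[101, 101], 1)
  h2 <- heatmap_for_label(s, "Opacity", men[2:1, ], window_policy(),
                          sigma = 3)
  expect_identical(h$map, h2$map)
  expect_true(all(h$map >= 0 & h$map <= 1))
})

test_that("policy sweeps score policies, drop impossible ones and flag the best", {
  set.seed(4)
  params <- fast_sim_params()
  cs <- simulate_case(params, "sweep_case")
  skip_if(length(cs$masks) == 0)
  cases <- list(list(session = cs$session, masks = cs$masks))
  tab <- sweep_policies(
    cases,
    start_rules. = c("mention_sentence_start_minus_delay_capped_prev",
                     "sentence_end_minus_delay_capped_prev"),
    end_rules. = c("first_mention_end", "last_mention_end"),
    delays = c(0, 1.5))
  # sentence_end - 0 starts after every mention end: structurally negative
  expect_false(any(tab$start_rule == "sentence_end_minus_delay_capped_prev" &
                     tab$delay == 0))
  expect_equal(sum(tab$best), 1)
  expect_true(all(tab$mean_iou >= 0 & tab$mean_iou <= 1))
  expect_error(sweep_policies(list(list(session = cs$session,
                                        masks = list()))),
               "masks")
})

test_that("heatmap files round-trip as 16-bit images with sidecars", {
  h <- structure(list(label = "Edema",
                      map = matrix(runif(64 * 64), 64),
                      n_fixations = 5L), class = "gaze_heatmap")
  f <- withr::local_tempfile(fileext = ".tif")
  write_heatmap(h, f, window_policy())
  back <- tiff::readTIFF(f)
  expect_equal(back, h$map, tolerance = 2e-5)
  meta <- jsonlite::read_json(sub("\\.tif$", ".json", f))
  expect_equal(meta$label, "Edema")
  expect_equal(meta$policy$delay, 1.5)
})
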