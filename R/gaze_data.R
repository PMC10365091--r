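#' Column dialect for fixation and transcript tables
#'
#' Delimited eye-tracking exports name their columns differently between
#' acquisition setups. A dialect maps the package's canonical field names to
#' the column names found in a particular file, and declares the time unit.
#' The shipped default follows the column naming of public chest x-ray
#' eye-tracking releases (REFLACX-style).
#'
#' @param x,y,start,end column names for fixation position (pixels) and
#'   start/end timestamps.
#' @param ppd optional column name holding pixels-per-degree angular
#'   resolution for each fixation (`NA` to skip).
#' @param time_unit `"s"` or `"ms"`; timestamps are converted to seconds.
#' @return a `fixation_dialect` list.
#' @export
fixation_dialect <- function(x = "x_position", y = "y_position",
                             start = "timestamp_start_fixation",
                             end = "timestamp_end_fixation",
                             ppd = "angular_resolution_x_coordinate_pixel_per_degree",
                             time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  structure(list(x = x, y = y, start = start, end = end, ppd = ppd,
                 time_unit = time_unit),
            class = "fixation_dialect")
}

#' @rdname fixation_dialect
#' @param word,start_w,end_w column names of the word-level transcript table.
#' @export
transcript_dialect <- function(word = "word", start_w = "timestamp_start_word",
                               end_w = "timestamp_end_word",
                               time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  structure(list(word = word, start = start_w, end = end_w,
                 time_unit = time_unit),
            class = "transcript_dialect")
}

time_scale <- function(unit) if (identical(unit, "ms")) 1e-3 else 1

#' Read a fixation table
#'
#' Reads a delimited file of fixations (one row per fixation: image x/y in
#' pixels, start and end time). Rows violating `end >= start` or with
#' non-finite coordinates are dropped with a warning naming their line
#' numbers. The result is sorted by start time.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [fixation_dialect()] mapping canonical fields to columns.
#' @param sep field separator.
#' @return a `data.frame` with columns `x`, `y`, `start`, `end`, `duration`
#'   and (when available) `ppd`.
#' @export
read_fixations <- function(path, dialect = fixation_dialect(), sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c(x = dialect$x, y = dialect$y, start = dialect$start,
            end = dialect$end)
  missing_cols <- need[!need %in% names(raw)]
  if (length(missing_cols)) {
    stop_user("fixation file ", path, " is missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "),
              " (check the dialect configuration)")
  }
  if (nrow(raw) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0)))
  }
  num <- function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & nzchar(trimws(as.character(v))))
    if (length(bad)) {
      stop_user("non-numeric value in column '", col, "' of ", path,
                " at data row(s) ", paste(bad, collapse = ", "))
    }
    out
  }
  sc <- time_scale(dialect$time_unit)
  fx <- data.frame(x = num(dialect$x), y = num(dialect$y),
                   start = num(dialect$start) * sc,
                   end = num(dialect$end) * sc)
  if (!is.null(dialect$ppd) && !is.na(dialect$ppd) &&
      dialect$ppd %in% names(raw)) {
    fx$ppd <- num(dialect$ppd)
  }
  bad <- which(!is.finite(fx$start) | !is.finite(fx$end) | fx$end < fx$start |
                 !is.finite(fx$x) | !is.finite(fx$y))
  if (length(bad)) {
    warning("dropping ", length(bad), " malformed fixation row(s) in ", path,
            " (data row ", paste(bad, collapse = ", "),
            "): end < start or non-finite values", call. = FALSE)
    fx <- fx[-bad, , drop = FALSE]
  }
  fx <- fx[order(fx$start), , drop = FALSE]
  rownames(fx) <- NULL
  fx$duration <- fx$end - fx$start
  fx
}

#' Write a fixation table
#'
#' Inverse of [read_fixations()]; values are written with six decimal places
#' so that a read/write round trip preserves them to that precision.
#' @param fixations data.frame as returned by [read_fixations()].
#' @inheritParams read_fixations
#' @export
write_fixations <- function(fixations, path, dialect = fixation_dialect()) {
  sc <- time_scale(dialect$time_unit)
  out <- data.frame(
    fmt6(fixations$x), fmt6(fixations$y),
    fmt6(fixations$start / sc), fmt6(fixations$end / sc),
    check.names = FALSE)
  names(out) <- c(dialect$x, dialect$y, dialect$start, dialect$end)
  if (!is.null(fixations$ppd) && !is.null(dialect$ppd) &&
      !is.na(dialect$ppd)) {
    out[[dialect$ppd]] <- fmt6(fixations$ppd)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt6 <- function(v) sprintf("%.6f", v)

#' Read a word-level transcript table
#'
#' @param path delimited file with one row per dictated word and its
#'   start/end timestamps.
#' @param dialect a [transcript_dialect()].
#' @return data.frame with columns `text`, `start`, `end`, ordered by start.
#' @export
read_transcript <- function(path, dialect = transcript_dialect(), sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c(dialect$word, dialect$start, dialect$end)
  missing_cols <- need[!need %in% names(raw)]
  if (length(missing_cols)) {
    stop_user("transcript file ", path, " is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  sc <- time_scale(dialect$time_unit)
  words <- data.frame(text = as.character(raw[[dialect$word]]),
                      start = as.numeric(raw[[dialect$start]]) * sc,
                      end = as.numeric(raw[[dialect$end]]) * sc,
                      stringsAsFactors = FALSE)
  words[order(words$start), , drop = FALSE]
}

#' Segment a word stream into sentences
#'
#' Sentences are split after tokens that end in sentence-final punctuation
#' (`.`, `?`, `!`); trailing unpunctuated words form a final sentence. No
#' word is dropped or duplicated.
#'
#' @param words data.frame with columns `text`, `start`, `end`, ordered by
#'   start time.
#' @return list of `sentence` objects, each with fields `index`, `words`,
#'   `start` (first word start) and `end` (last word end).
#' @export
segment_sentences <- function(words) {
  if (is.null(words) || nrow(words) == 0) return(list())
  final <- grepl("[.?!]['\")]*$", words$text)
  final[nrow(words)] <- TRUE
  ends <- which(final)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    w <- words[starts[i]:ends[i], , drop = FALSE]
    rownames(w) <- NULL
    out[[i]] <- structure(
      list(index = i, words = w, start = w$start[1], end = w$end[nrow(w)]),
      class = "sentence")
  }
  out
}

#' Assemble a reading session
#'
#' A reading session is one radiologist's recording over one image: the
#' fixation table, the sentence-segmented transcript, the image geometry and
#' the recording start time. Fixations starting before `recording_start` are
#' an error; fixations whose coordinates fall outside the image are kept but
#' flagged in an `in_bounds` column (off-screen glances are legal).
#'
#' @param image_id identifier string.
#' @param image_width,image_height image size in pixels.
#' @param fixations data.frame from [read_fixations()].
#' @param sentences list from [segment_sentences()] (may be empty).
#' @param recording_start recording start time in seconds.
#' @return a `reading_session` object.
#' @export
reading_session <- function(image_id, image_width, image_height,
                            fixations, sentences = list(),
                            recording_start = 0) {
  if (nrow(fixations) && any(fixations$start < recording_start)) {
    stop_user("reading_session: fixations before recording_start")
  }
  if (length(sentences) > 1) {
    s0 <- vapply(sentences, `[[`, numeric(1), "start")
    e0 <- vapply(sentences, `[[`, numeric(1), "end")
    if (is.unsorted(s0) || any(s0[-1] < e0[-length(e0)] - 1e-9)) {
      stop_user("reading_session: sentences must be ordered and non-overlapping")
    }
  }
  if (nrow(fixations)) {
    fixations$in_bounds <- fixations$x >= 0 & fixations$x < image_width &
      fixations$y >= 0 & fixations$y < image_height
  }
  structure(list(image_id = image_id, image_width = image_width,
                 image_height = image_height, fixations = fixations,
                 sentences = sentences, recording_start = recording_start),
            class = "reading_session")
}

#' @export
print.reading_session <- function(x, ...) {
  cat("<reading_session>", x$image_id, ":", x$image_width, "x",
      x$image_height, "px,", nrow(x$fixations), "fixations,",
      length(x$sentences), "sentences\n")
  invisible(x)
}

#' Read a grayscale image (8/16-bit PNG) as a [0,1] intensity matrix
#' @param path PNG file path.
#' @return numeric matrix, rows = image rows.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
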