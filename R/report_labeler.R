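#' The ten study labels
#' @return character vector of the label names used throughout the package.
#' @export
study_labels <- function() {
  c("Abnormal Mediastinal Contour", "Atelectasis",
    "Enlarged Cardiac Silhouette", "Consolidation", "Edema", "Fracture",
    "Lung Lesion", "Opacity", "Pleural Abnormality", "Pneumothorax")
}

#' Load a label vocabulary
#'
#' The vocabulary maps lowercase report phrases to the ten study labels,
#' with optional per-label unmatch phrases (longer phrases whose presence
#' suppresses a contained match, e.g. "mass effect" for "mass") and shared
#' negation/hedge cue lists. The shipped file groups source terms the way
#' the public chest x-ray datasets do: "cardiomegaly" maps to Enlarged
#' Cardiac Silhouette, parenchymal terms such as "pulmonary edema" or
#' "atelectasis" map both to their own label and to Opacity, and
#' "pleural effusion" maps to Pleural Abnormality.
#'
#' @param path JSON vocabulary file; default is the file shipped with the
#'   package.
#' @return a `label_vocabulary` object.
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary.json", package = "gazemil")
  }
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  labs <- names(v$labels)
  vocab <- list(
    labels = lapply(v$labels, function(l) {
      list(match_phrases = as.character(l$match_phrases %||% character(0)),
           unmatch_phrases = as.character(l$unmatch_phrases %||% character(0)))
    }),
    negation_cues = as.character(v$negation_cues %||%
                                   c("no", "without", "negative for",
                                     "clear of")),
    hedge_cues = as.character(v$hedge_cues %||% character(0)),
    version = v$version %||% "unversioned")
  names(vocab$labels) <- labs
  class(vocab) <- "label_vocabulary"
  vocab
}

# lowercase a token and strip punctuation for matching purposes
norm_token <- function(x) gsub("[^a-z0-9']+", "", tolower(x))

split_phrase <- function(p) strsplit(tolower(p), "\\s+")[[1]]

# all occurrences of phrase (token vector) in token vector; returns start idx
phrase_occurrences <- function(tokens, phrase) {
  np <- length(phrase)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nt - np + 1L)) {
    if (all(tokens[i:(i + np - 1L)] == phrase)) hits <- c(hits, i)
  }
  hits
}

#' Detect whether a phrase span is negated within its sentence
#'
#' A span counts as negated when a negation cue occurs in the same sentence
#' before the span, with no sentence-final punctuation between cue and span.
#' Cues may be multi-word ("negative for"). The scope rule means that in
#' "consolidation without effusion" the effusion span is negated while the
#' consolidation span is not.
#'
#' @param sentence a `sentence` object.
#' @param span integer vector `c(first, last)` of word indices (1-based).
#' @param cues character vector of negation cue phrases.
#' @return logical.
#' @export
detect_negation <- function(sentence, span,
                            cues = load_vocabulary()$negation_cues) {
  words <- sentence$words$text
  if (span[1] < 1 || span[2] > length(words)) {
    stop_user("detect_negation: span outside sentence bounds")
  }
  if (span[1] == 1) return(FALSE)
  pre <- words[seq_len(span[1] - 1L)]
  # a clause boundary between cue and span ends the cue's scope
  punct_after <- rev(cumsum(rev(grepl("[.?!]['\")]*$", pre))))
  tokens <- vapply(pre, norm_token, character(1), USE.NAMES = FALSE)
  for (cue in cues) {
    cp <- split_phrase(cue)
    for (i in phrase_occurrences(tokens, cp)) {
      if (punct_after[i] == 0) return(TRUE)
    }
  }
  FALSE
}

#' Find label mentions in sentence-segmented transcripts
#'
#' Per label, phrases are matched longest-first against the lowercased,
#' punctuation-stripped word stream of each sentence; a span consumed by a
#' longer phrase of the same label is not re-matched by a shorter one.
#' Matches contained inside an occurrence of an unmatch phrase are
#' suppressed. All surviving matches of one label in one sentence are
#' merged into a single mention carrying the end times of the first and
#' last matched phrase; phrases mapped to several labels (e.g. "pulmonary
#' edema" to both Edema and Opacity) yield one mention per label.
#'
#' @param sentences list of `sentence` objects.
#' @param vocab a `label_vocabulary`.
#' @param drop_hedged drop mentions preceded by a hedge cue ("may",
#'   "possible", ...) in the same sentence; hedged mentions are kept as
#'   positive by default.
#' @return data.frame with one row per (label, sentence) mention: `label`,
#'   `sentence_index`, `span_start`, `span_end`, `first_mention_end`,
#'   `last_mention_end`, `negated`.
#' @export
find_mentions <- function(sentences, vocab = load_vocabulary(),
                          drop_hedged = FALSE) {
  if (!length(vocab$labels)) stop_user("find_mentions: empty vocabulary")
  rows <- list()
  for (sent in sentences) {
    words <- sent$words
    tokens <- vapply(words$text, norm_token, character(1), USE.NAMES = FALSE)
    hedged_before <- rep(FALSE, length(tokens))
    if (drop_hedged && length(vocab$hedge_cues)) {
      for (cue in vocab$hedge_cues) {
        for (i in phrase_occurrences(tokens, split_phrase(cue))) {
          if (i < length(tokens)) {
            hedged_before[(i + 1L):length(tokens)] <- TRUE
          }
        }
      }
    }
    for (lab in names(vocab$labels)) {
      spec <- vocab$labels[[lab]]
      unmatch_spans <- list()
      for (up in spec$unmatch_phrases) {
        upt <- split_phrase(up)
        for (i in phrase_occurrences(tokens, upt)) {
          unmatch_spans[[length(unmatch_spans) + 1L]] <-
            c(i, i + length(upt) - 1L)
        }
      }
      phrases <- spec$match_phrases[order(-vapply(
        spec$match_phrases, function(p) length(split_phrase(p)), numeric(1)))]
      consumed <- rep(FALSE, length(tokens))
      spans <- list()
      for (ph in phrases) {
        pht <- split_phrase(ph)
        for (i in phrase_occurrences(tokens, pht)) {
          j <- i + length(pht) - 1L
          if (any(consumed[i:j])) next
          inside_unmatch <- any(vapply(unmatch_spans, function(u) {
            i >= u[1] && j <= u[2]
          }, logical(1)))
          if (inside_unmatch) next
          consumed[i:j] <- TRUE
          spans[[length(spans) + 1L]] <- c(i, j)
        }
      }
      if (!length(spans)) next
      spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
      if (drop_hedged) {
        spans <- Filter(function(sp) !hedged_before[sp[1]], spans)
        if (!length(spans)) next
      }
      negated <- vapply(spans, function(sp) {
        detect_negation(sent, sp, vocab$negation_cues)
      }, logical(1))
      ends <- vapply(spans, function(sp) words$end[sp[2]], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, sentence_index = sent$index,
        span_start = min(vapply(spans, `[`, numeric(1), 1)),
        span_end = max(vapply(spans, `[`, numeric(1), 2)),
        first_mention_end = min(ends), last_mention_end = max(ends),
        negated = all(negated), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(label = character(0), sentence_index = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      first_mention_end = numeric(0),
                      last_mention_end = numeric(0), negated = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sentence_index, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
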