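# Shared fixture builders: everything is generated in code at test time.

# word table from a whitespace-tokenized string, fixed cadence
words_from_text <- function(text, t0 = 0, word_dur = 0.4) {
  toks <- strsplit(text, "\\s+")[[1]]
  start <- t0 + (seq_along(toks) - 1) * word_dur
  data.frame(text = toks, start = start, end = start + word_dur,
             stringsAsFactors = FALSE)
}

sentences_from_text <- function(text, t0 = 0, word_dur = 0.4) {
  segment_sentences(words_from_text(text, t0, word_dur))
}

# reading session with explicit sentence timing: sentence_starts[i] is the
# start of sentence i; each sentence is one three-word utterance whose
# mention phrase ends at mention_ends[i].
toy_session <- function(sentence_starts, sentence_ends, fixations = NULL,
                        recording_start = 0, size = 128) {
  sentences <- lapply(seq_along(sentence_starts), function(i) {
    w <- data.frame(
      text = c("there", "is", "finding."),
      start = seq(sentence_starts[i], sentence_ends[i], length.out = 4)[1:3],
      end = seq(sentence_starts[i], sentence_ends[i], length.out = 4)[2:4])
    structure(list(index = i, words = w, start = sentence_starts[i],
                   end = sentence_ends[i]), class = "sentence")
  })
  if (is.null(fixations)) {
    fixations <- data.frame(x = numeric(0), y = numeric(0),
                            start = numeric(0), end = numeric(0))
  }
  fixations$duration <- fixations$end - fixations$start
  reading_session("toy", size, size, fixations, sentences, recording_start)
}

mention_row <- function(sentence_index, first_end, last_end = first_end,
                        label = "Opacity") {
  data.frame(label = label, sentence_index = sentence_index,
             span_start = 1L, span_end = 2L,
             first_mention_end = first_end, last_mention_end = last_end,
             negated = FALSE, stringsAsFactors = FALSE)
}

# small training config for smoke tests
smoke_config <- function(size = 64, ...) {
  train_config(input_size = size, grid_size = size / 16, epochs = 2,
               seeds = 1, ...)
}

fast_sim_params <- function(...) sim_params(image_size = 128, ...)
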