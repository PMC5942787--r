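# Independent oracles and fixture builders shared across test files.

# Brute-force n-gram window enumerator, deliberately naive: one explicit
# loop per window, no sharing with count_ngrams().
bf_count_ngrams <- function(pitches, order) {
  counts <- list()
  if (length(pitches) >= order + 1) {
    for (i in seq_len(length(pitches) - order)) {
      w <- pitches[i:(i + order)]
      offs <- w - w[1]
      ctx <- paste(offs[seq_len(order)], collapse = ",")
      out <- as.character(offs[order + 1])
      if (is.null(counts[[ctx]])) counts[[ctx]] <- numeric(0)
      counts[[ctx]][out] <- if (is.na(counts[[ctx]][out])) 1
                            else counts[[ctx]][out] + 1
    }
  }
  counts
}

# canonical form for comparing count structures
canon_counts <- function(counts) {
  counts <- counts[order(names(counts))]
  lapply(counts, function(v) v[order(names(v))])
}

expect_same_counts <- function(table, pitches, order) {
  expect_identical(canon_counts(table$counts),
                   canon_counts(bf_count_ngrams(pitches, order)))
}

# normal-equations OLS oracle
ne_ols <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# two columns with sample correlation exactly r (n rows)
make_correlated_pair <- function(n, r, seed = 42) {
  set.seed(seed)
  a <- scale(rnorm(n))[, 1]
  b <- rnorm(n)
  b <- scale(residuals(lm(b ~ a)))[, 1]
  cbind(x1 = a, x2 = r * a + sqrt(1 - r^2) * b)
}

# --- minimal MusicXML builder -------------------------------------------
# notes: list of lists with fields
#   step, alter (default 0), octave        -- or rest = TRUE
#   dur (divisions, default 4), grace, chord, tie_start, slur ("start"/"stop")
make_musicxml <- function(notes, path = tempfile(fileext = ".xml"),
                          divisions = 4) {
  body <- vapply(notes, function(nt) {
    if (isTRUE(nt$rest))
      return(sprintf("<note><rest/><duration>%d</duration></note>",
                     nt$dur %||% divisions))
    paste0("<note>",
           if (isTRUE(nt$grace)) "<grace/>" else "",
           if (isTRUE(nt$chord)) "<chord/>" else "",
           sprintf("<pitch><step>%s</step><alter>%d</alter><octave>%d</octave></pitch>",
                   nt$step, nt$alter %||% 0L, nt$octave),
           if (!isTRUE(nt$grace))
             sprintf("<duration>%d</duration>", nt$dur %||% divisions) else "",
           if (isTRUE(nt$tie_start)) '<tie type="start"/>' else "",
           if (!is.null(nt$slur))
             sprintf('<notations><slur type="%s" number="1"/></notations>',
                     nt$slur) else "",
           "</note>")
  }, "")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<score-partwise version=\"3.1\"><part-list>",
    '<score-part id="P1"><part-name>Test</part-name></score-part>',
    "</part-list><part id=\"P1\"><measure number=\"1\">",
    sprintf("<attributes><divisions>%d</divisions></attributes>", divisions),
    paste(body, collapse = ""),
    "</measure></part></score-partwise>")
  writeLines(xml, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

note <- function(step, octave, ...) c(list(step = step, octave = octave),
                                      list(...))

# small deterministic corpus of plain pitch sequences, one movement each
toy_corpus_tables <- function(seqs, order) {
  lapply(seqs, function(p) pool_movements(list(count_ngrams(p, order))))
}

# fast spec for synthetic pipeline tests
small_drift_spec <- function(...) {
  args <- list(...)
  defaults <- list(movement_length = 400L, n_pieces = 16L,
                   movements_per_piece = 2L, seed = 7L)
  do.call(drift_spec, utils::modifyList(defaults, args))
}
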