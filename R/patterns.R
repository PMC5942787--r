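#' Interval patterns
#'
#' An interval pattern is a run of `order + 1` tones re-expressed relative to
#' its first pitch: the first element is always 0 and every other element is
#' the signed distance in semitones from that first pitch. Encoding
#' transitions this way makes them invariant under transposition, so a
#' pattern captures relative-pitch structure only.
#'
#' @param offsets integer vector of semitone offsets; `offsets[1]` must be 0
#'   and the vector must have at least two elements.
#' @return An `interval_pattern`: an integer vector with an `order` attribute
#'   equal to `length(offsets) - 1`.
#' @examples
#' interval_pattern(c(0, -2, -3, -5, -7))
#' @export
interval_pattern <- function(offsets) {
  offsets <- as.integer(offsets)
  if (length(offsets) < 2)
    stop("an interval pattern needs at least two tones (order >= 1)")
  if (offsets[1] != 0)
    stop("the first offset of an interval pattern must be 0, got ", offsets[1])
  structure(offsets, order = length(offsets) - 1L, class = "interval_pattern")
}

#' Re-express a pitch run relative to its first pitch
#'
#' @param pitches integer vector of semitone pitch numbers (MIDI convention,
#'   C4 = 60), length at least 2.
#' @return An [interval_pattern()] with `offsets[i] = pitches[i] - pitches[1]`.
#'   The result is identical for any transposition of `pitches`.
#' @examples
#' to_interval_pattern(c(65, 63, 62, 60, 58))  # [0,-2,-3,-5,-7]
#' @export
to_interval_pattern <- function(pitches) {
  if (length(pitches) < 2)
    stop("need at least two pitches to form a transition")
  interval_pattern(pitches - pitches[1])
}

#' Format / parse the field's pattern notation
#'
#' Patterns are written as comma-joined offsets, e.g. `"0,-2,-3,-5"`.
#'
#' @param pattern an [interval_pattern()] or plain integer vector.
#' @return `pattern_string()`: a single string. `parse_pattern()`: an
#'   `interval_pattern`.
#' @export
pattern_string <- function(pattern) {
  paste(as.integer(pattern), collapse = ",")
}

#' @rdname pattern_string
#' @param x a pattern string such as `"0,-2,-3,-5"`.
#' @export
parse_pattern <- function(x) {
  interval_pattern(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
}

#' @export
print.interval_pattern <- function(x, ...) {
  cat("interval pattern [", pattern_string(x), "] (order ",
      attr(x, "order"), ")\n", sep = "")
  invisible(x)
}

# lexicographic order on offset tuples; shorter tuple wins a tied prefix.
# Names that are not offset tuples (plain labels) order as strings.
pattern_lex_order <- function(strings) {
  tuples <- suppressWarnings(
    lapply(strings, function(s) as.integer(strsplit(s, ",")[[1]])))
  if (any(vapply(tuples, anyNA, NA))) return(order(strings))
  maxlen <- max(lengths(tuples))
  keys <- lapply(seq_len(maxlen), function(i)
    vapply(tuples, function(tp) if (i <= length(tp)) tp[i] else -Inf, 0))
  do.call(order, keys)
}
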