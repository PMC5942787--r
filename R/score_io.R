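#' Melodic sequences
#'
#' The ordered highest-pitch note numbers of one movement of one piece.
#' Pitches are integer semitones in the MIDI convention (C4 = 60). Grace
#' notes are never part of a melodic sequence, and tied or slur-repeated
#' notes appear once.
#'
#' @param piece_id,movement_id identifiers.
#' @param pitches integer vector of semitone note numbers in temporal order.
#'   Score-derived sequences lie in the MIDI range 0..127; synthetic
#'   random-walk sequences are not range-restricted, since the analysis is
#'   transposition-invariant and only pitch differences matter.
#' @return A `melodic_sequence` object.
#' @export
melodic_sequence <- function(piece_id, movement_id, pitches) {
  pitches <- as.integer(pitches)
  structure(list(piece_id = as.character(piece_id),
                 movement_id = as.character(movement_id),
                 pitches = pitches),
            class = "melodic_sequence")
}

#' @export
print.melodic_sequence <- function(x, ...) {
  cat("melodic sequence ", x$piece_id, "/", x$movement_id, ": ",
      length(x$pitches), " notes\n", sep = "")
  invisible(x)
}

midi_step <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Read note events from an uncompressed MusicXML file
#'
#' Parses a partwise MusicXML score into a flat table of pitched note
#' events on a single global timeline. Onsets and durations are returned in
#' integer ticks of a common resolution (the least common multiple of all
#' `<divisions>` values in the score), so simultaneity comparisons are
#' exact. Rests produce no events; grace notes are kept but flagged and
#' carry zero duration; `<backup>`/`<forward>` and chord notation are
#' honoured.
#'
#' @param path path to an uncompressed `.xml` / `.musicxml` file.
#' @return A data frame with one row per pitched note: `onset`, `duration`
#'   (ticks), `pitch` (MIDI semitones), `is_grace`, `tie_to_next`,
#'   `slur_ids` (list column of character ids), `voice_id`, `part_id`,
#'   sorted by onset. The tick resolution is stored in attribute
#'   `ticks_per_quarter`.
#' @export
read_musicxml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed MusicXML in ", path,
                                           ": ", conditionMessage(e)))
  if (xml2::xml_name(doc) != "score-partwise")
    stop("expected a <score-partwise> document, found <",
         xml2::xml_name(doc), ">")

  parts <- xml2::xml_find_all(doc, "./part")
  rows <- list()
  slur_counter <- 0L

  for (pi in seq_along(parts)) {
    part <- parts[[pi]]
    part_id <- xml2::xml_attr(part, "id")
    if (is.na(part_id)) part_id <- paste0("P", pi)
    divisions <- 1L
    cursor_num <- 0L          # onset in current-division units, exact later
    onset_frac <- list()      # per-event (numerator, divisions)
    open_slurs <- character(0)   # ids keyed by slur number
    names(open_slurs) <- character(0)

    prev_onset <- c(0L, 1L)   # numerator, divisions of previous note's onset
    for (meas in xml2::xml_find_all(part, "./measure")) {
      for (el in xml2::xml_children(meas)) {
        nm <- xml2::xml_name(el)
        if (nm == "attributes") {
          dv <- xml2::xml_find_first(el, "./divisions")
          if (!inherits(dv, "xml_missing"))
            divisions <- as.integer(xml2::xml_text(dv))
        } else if (nm == "backup") {
          d <- as.integer(xml2::xml_text(xml2::xml_find_first(el, "./duration")))
          cursor_num <- cursor_num - d
        } else if (nm == "forward") {
          d <- as.integer(xml2::xml_text(xml2::xml_find_first(el, "./duration")))
          cursor_num <- cursor_num + d
        } else if (nm == "note") {
          is_grace <- !inherits(xml2::xml_find_first(el, "./grace"), "xml_missing")
          is_chord <- !inherits(xml2::xml_find_first(el, "./chord"), "xml_missing")
          is_rest  <- !inherits(xml2::xml_find_first(el, "./rest"), "xml_missing")
          dnode <- xml2::xml_find_first(el, "./duration")
          dur <- if (inherits(dnode, "xml_missing")) 0L
                 else as.integer(xml2::xml_text(dnode))

          onset <- if (is_chord) prev_onset else c(cursor_num, divisions)

          # slur bookkeeping: a note carries every slur open at it,
          # including ones that start or stop on the note itself
          slurs <- xml2::xml_find_all(el, "./notations/slur")
          started <- stopped <- character(0)
          for (s in slurs) {
            num <- xml2::xml_attr(s, "number"); if (is.na(num)) num <- "1"
            type <- xml2::xml_attr(s, "type")
            if (identical(type, "start")) {
              slur_counter <- slur_counter + 1L
              open_slurs[num] <- paste0("s", slur_counter)
              started <- c(started, num)
            } else if (identical(type, "stop")) {
              stopped <- c(stopped, num)
            }
          }
          note_slurs <- unname(open_slurs)
          if (length(stopped))
            open_slurs <- open_slurs[setdiff(names(open_slurs), stopped)]

          if (!is_rest) {
            pnode <- xml2::xml_find_first(el, "./pitch")
            if (inherits(pnode, "xml_missing"))
              stop("note without <pitch> or <rest> in ", path)
            step <- xml2::xml_text(xml2::xml_find_first(pnode, "./step"))
            alter <- xml2::xml_find_first(pnode, "./alter")
            alter <- if (inherits(alter, "xml_missing")) 0L
                     else as.integer(xml2::xml_text(alter))
            octave <- as.integer(xml2::xml_text(xml2::xml_find_first(pnode, "./octave")))
            pitch <- (octave + 1L) * 12L + midi_step[[step]] + alter

            tie_start <- any(xml2::xml_attr(
              xml2::xml_find_all(el, "./tie"), "type") == "start")
            voice <- xml2::xml_find_first(el, "./voice")
            voice <- if (inherits(voice, "xml_missing")) "1"
                     else xml2::xml_text(voice)

            rows[[length(rows) + 1L]] <- list(
              onset_num = onset[1], onset_den = onset[2],
              dur_num = dur, dur_den = divisions,
              pitch = pitch, is_grace = is_grace,
              tie_to_next = isTRUE(tie_start),
              slur_ids = note_slurs,
              voice_id = paste0(part_id, ":", voice), part_id = part_id)
          }
          if (!is_chord) prev_onset <- c(cursor_num, divisions)
          if (!is_chord && !is_grace) cursor_num <- cursor_num + dur
        }
      }
    }
  }

  if (!length(rows)) stop("score contains zero pitched notes: ", path)

  dens <- unique(c(vapply(rows, function(r) r$onset_den, 0),
                   vapply(rows, function(r) r$dur_den, 0)))
  lcm2 <- function(a, b) a / gcd2(a, b) * b
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  ticks <- Reduce(lcm2, dens)

  ev <- data.frame(
    onset = vapply(rows, function(r) r$onset_num * ticks / r$onset_den, 0),
    duration = vapply(rows, function(r) r$dur_num * ticks / r$dur_den, 0),
    pitch = vapply(rows, function(r) r$pitch, 0),
    is_grace = vapply(rows, function(r) r$is_grace, NA),
    tie_to_next = vapply(rows, function(r) r$tie_to_next, NA),
    voice_id = vapply(rows, function(r) r$voice_id, ""),
    part_id = vapply(rows, function(r) r$part_id, ""),
    stringsAsFactors = FALSE)
  ev$slur_ids <- lapply(rows, function(r) r$slur_ids)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "ticks_per_quarter") <- ticks
  ev
}

#' Extract the highest-pitch line of a movement
#'
#' Implements the melodic proxy used throughout the package: at each onset
#' where at least one non-grace note begins, the highest pitch sounding at
#' that instant (started and not yet ended) is taken. Grace notes are
#' excluded. Consecutive emissions collapse into one element when they are
#' the same sustained note, a tie continuation, or a slurred repetition of
#' the same pitch; slurred notes of different pitches are kept, since
#' merging them would delete melodic intervals.
#'
#' @param events the event table from [read_musicxml()].
#' @param piece_id,movement_id identifiers attached to the result.
#' @return A [melodic_sequence()].
#' @export
extract_highest_line <- function(events, piece_id = "piece",
                                 movement_id = "mvt") {
  if (!NROW(events)) stop("empty event list: no notes to extract")
  main <- events[!events$is_grace, , drop = FALSE]
  if (!NROW(main)) stop("empty event list: only grace notes present")

  onsets <- sort(unique(main$onset))
  chosen <- integer(0)          # row indices into main
  for (t in onsets) {
    sounding <- which(main$onset <= t & (main$onset + main$duration) > t)
    if (!length(sounding)) sounding <- which(main$onset == t)
    top <- sounding[order(-main$pitch[sounding], main$onset[sounding] != t)][1]
    chosen <- c(chosen, top)
  }

  keep <- rep(TRUE, length(chosen))
  for (i in seq_along(chosen)[-1]) {
    a <- chosen[i - 1L]; b <- chosen[i]
    if (b == a) { keep[i] <- FALSE; next }        # same sustained note
    if (main$pitch[a] == main$pitch[b]) {
      tied <- main$tie_to_next[a]
      slurred <- length(intersect(main$slur_ids[[a]], main$slur_ids[[b]])) > 0
      if (tied || slurred) keep[i] <- FALSE
    }
  }
  melodic_sequence(piece_id, movement_id, main$pitch[chosen[keep]])
}

#' Read / write the coded-sequence CSV interchange format
#'
#' One note per row with columns `piece_id`, `movement_id`, `note_index`,
#' `pitch`; comma-separated, UTF-8, header mandatory. Sequences are kept in
#' file row order; a gap in `note_index` is tolerated with a warning.
#'
#' @param path CSV file path.
#' @return `read_coded_csv()`: a list of [melodic_sequence()]s in file
#'   order. `write_coded_csv()`: the path, invisibly.
#' @export
read_coded_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("piece_id", "movement_id", "note_index", "pitch")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("coded CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (!nrow(d)) return(list())
  if (!is.numeric(d$pitch) || any(d$pitch != floor(d$pitch)))
    stop("column 'pitch' must contain integers")

  key <- paste(d$piece_id, d$movement_id, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- d[key == k, , drop = FALSE]
    if (any(diff(rows$note_index) != 1))
      warning("note_index gap in ", rows$piece_id[1], "/",
              rows$movement_id[1], "; keeping file row order")
    out[[length(out) + 1L]] <- melodic_sequence(
      rows$piece_id[1], rows$movement_id[1], rows$pitch)
  }
  out
}

#' @rdname read_coded_csv
#' @param sequences list of [melodic_sequence()]s.
#' @export
write_coded_csv <- function(sequences, path) {
  frames <- lapply(sequences, function(s)
    data.frame(piece_id = s$piece_id, movement_id = s$movement_id,
               note_index = seq_along(s$pitches), pitch = s$pitches,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, c(frames, list(
    data.frame(piece_id = character(0), movement_id = character(0),
               note_index = integer(0), pitch = integer(0))))),
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
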