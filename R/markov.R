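#' Transition tables: n-gram counts and transitional probabilities
#'
#' A transition table holds, for one Markov order n, the observed counts of
#' every context (an n-tuple of offsets with first element 0, i.e. the
#' relative form of n consecutive pitches) together with the outcome offsets
#' that followed it. The transitional probability of an outcome given a
#' context is the count ratio
#' \deqn{P(e_{n+1} \mid e_n) = P(e_{n+1} \cap e_n) / P(e_n),}
#' i.e. count(context, outcome) / total count(context). No smoothing is
#' applied: a context never observed has no probability, it is absent.
#'
#' @param order integer Markov order (1..7).
#' @param counts named list mapping context strings (e.g. `"0,-2"`) to named
#'   numeric vectors of outcome-offset counts (names are offsets relative to
#'   the window's first pitch).
#' @return A `transition_table` object.
#' @export
transition_table <- function(order, counts = list()) {
  order <- as.integer(order)
  if (order < 1L || order > 7L)
    stop("order must be between 1 and 7, got ", order)
  structure(list(order = order, counts = counts), class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  ncontext <- length(x$counts)
  total <- sum(vapply(x$counts, sum, 0))
  cat("transition table, order ", x$order, ": ", ncontext, " context",
      if (ncontext != 1) "s", ", ", total, " transitions\n", sep = "")
  invisible(x)
}

#' Count interval n-grams in one melodic line
#'
#' Every window of `order + 1` consecutive pitches contributes one count:
#' the window is re-expressed relative to its first pitch, the first `order`
#' offsets form the context and the final offset is the outcome. Windows
#' never cross movement boundaries (call once per movement and pool with
#' [pool_movements()]).
#'
#' @param seq a [melodic_sequence()] or plain integer pitch vector.
#' @param order Markov order, 1 to 7.
#' @return A [transition_table()]; empty when the sequence is shorter than
#'   `order + 1`.
#' @examples
#' tab <- count_ngrams(c(60, 62, 60, 62, 60), order = 1)
#' pattern_probability(tab, interval_pattern(c(0, 2)))  # 0.5
#' @export
count_ngrams <- function(seq, order) {
  order <- as.integer(order)
  if (order < 1L || order > 7L)
    stop("order must be between 1 and 7, got ", order)
  pitches <- if (inherits(seq, "melodic_sequence")) seq$pitches else as.integer(seq)
  n <- length(pitches)
  if (n < order + 1L) return(transition_table(order))

  nwin <- n - order
  win <- vapply(0:order, function(k) pitches[(1L + k):(nwin + k)],
                integer(nwin))
  win <- matrix(win, nrow = nwin)
  offs <- win - win[, 1L]
  ctx <- do.call(paste, c(lapply(seq_len(order), function(j) offs[, j]),
                          sep = ","))
  out <- as.character(offs[, order + 1L])

  counts <- list()
  for (cx in unique(ctx)) {
    tab <- table(out[ctx == cx])
    counts[[cx]] <- stats::setNames(as.numeric(tab), names(tab))
  }
  transition_table(order, counts)
}

#' Pool per-movement tables into one per-piece table
#'
#' Counts are summed across movements and probabilities recomputed from the
#' pooled counts. This equals a weighted average of per-movement
#' probabilities with weights proportional to each movement's context
#' counts, and is invariant to how a piece is split into movements.
#'
#' @param tables list of [transition_table()]s of a common order.
#' @return A single pooled [transition_table()].
#' @export
pool_movements <- function(tables) {
  if (!length(tables)) stop("no tables to pool")
  orders <- vapply(tables, function(t) t$order, 0L)
  if (length(unique(orders)) != 1L)
    stop("cannot pool tables of mixed orders: ", paste(unique(orders), collapse = ", "))
  pooled <- list()
  for (tb in tables) {
    for (cx in names(tb$counts)) {
      add <- tb$counts[[cx]]
      if (is.null(pooled[[cx]])) {
        pooled[[cx]] <- add
      } else {
        keys <- union(names(pooled[[cx]]), names(add))
        merged <- stats::setNames(numeric(length(keys)), keys)
        merged[names(pooled[[cx]])] <- pooled[[cx]]
        merged[names(add)] <- merged[names(add)] + add
        pooled[[cx]] <- merged
      }
    }
  }
  transition_table(orders[1], pooled)
}

#' Per-context transitional probabilities of a table
#'
#' @param table a [transition_table()].
#' @return Named list: context string to named probability vector (each
#'   summing to 1).
#' @export
tp_probabilities <- function(table) {
  lapply(table$counts, function(v) v / sum(v))
}

#' Transitional probability of one full interval pattern
#'
#' Splits the pattern into its context (all but the last offset) and outcome
#' (the last offset) and returns the estimated conditional probability.
#'
#' @param table a [transition_table()].
#' @param pattern an [interval_pattern()] whose order equals the table's.
#' @return The probability in \[0, 1\], or `NA_real_` when the pattern's
#'   context was never observed (absent — not zero).
#' @export
pattern_probability <- function(table, pattern) {
  offs <- as.integer(pattern)
  if (length(offs) != table$order + 1L)
    stop("pattern order ", length(offs) - 1L,
         " does not match table order ", table$order)
  ctx <- paste(offs[-length(offs)], collapse = ",")
  out <- as.character(offs[length(offs)])
  v <- table$counts[[ctx]]
  if (is.null(v) || sum(v) == 0) return(NA_real_)
  p <- v[out] / sum(v)
  if (is.na(p)) 0 else unname(p)
}

#' All full patterns observed in a table
#'
#' @param table a [transition_table()].
#' @return Character vector of pattern strings (context plus outcome) with
#'   count of at least 1, in lexicographic offset order.
#' @export
observed_patterns <- function(table) {
  if (!length(table$counts)) return(character(0))
  pats <- unlist(lapply(names(table$counts), function(cx) {
    v <- table$counts[[cx]]
    paste(cx, names(v)[v > 0], sep = ",")
  }), use.names = FALSE)
  pats[pattern_lex_order(pats)]
}
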