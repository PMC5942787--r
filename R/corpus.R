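#' Piece-by-pattern probability matrices
#'
#' A corpus matrix holds, for one Markov order, the pooled transitional
#' probability of each universal interval pattern (columns) in each piece
#' (rows), with rows ordered by the corpus' serial index — the regressand
#' representing time course.
#'
#' @param values numeric matrix, pieces by patterns.
#' @param patterns character vector of pattern strings (column names).
#' @param piece_index integer vector of piece serial numbers (row order).
#' @param order the Markov order of the probabilities.
#' @return A `corpus_matrix`: the numeric matrix with dimnames and
#'   `order` attribute.
#' @export
corpus_matrix <- function(values, patterns, piece_index, order) {
  values <- as.matrix(values)
  if (nrow(values) != length(piece_index) || ncol(values) != length(patterns))
    stop("dimension mismatch between values, patterns and piece_index")
  if (any(!is.finite(values)) || any(values <= 0) || any(values > 1))
    stop("corpus matrix cells must be defined probabilities in (0, 1]")
  dimnames(values) <- list(piece_index, patterns)
  structure(values, order = as.integer(order),
            class = c("corpus_matrix", "matrix", "array"))
}

#' @export
print.corpus_matrix <- function(x, ...) {
  cat("corpus matrix, order ", attr(x, "order"), ": ", nrow(x),
      " pieces x ", ncol(x), " universal patterns\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Interval patterns universal to every piece
#'
#' A pattern is universal when its full (context + outcome) count is at
#' least 1 in every piece's pooled table. Only universal patterns enter the
#' trend regression: a probability of exactly zero in some piece cannot be
#' distinguished from an unobserved context.
#'
#' @param tables list of pooled [transition_table()]s, one per piece.
#' @param order the common Markov order (checked).
#' @return Character vector of pattern strings in lexicographic offset
#'   order; possibly empty.
#' @export
universal_patterns <- function(tables, order) {
  if (length(tables) < 2L)
    stop("universality needs a corpus of at least 2 pieces")
  ords <- vapply(tables, function(t) t$order, 0L)
  if (any(ords != order))
    stop("tables are not all of order ", order)
  sets <- lapply(tables, observed_patterns)
  univ <- Reduce(intersect, sets)
  if (!length(univ)) return(character(0))
  univ[pattern_lex_order(univ)]
}

#' Assemble the corpus matrix for regression
#'
#' @param tables named or ordered list of pooled per-piece tables.
#' @param patterns character vector of universal pattern strings.
#' @param piece_order integer serial indices giving the row order; defaults
#'   to `seq_along(tables)`.
#' @return A [corpus_matrix()]. Errors if any pattern is absent from any
#'   piece (universality violation).
#' @export
build_matrix <- function(tables, patterns, piece_order = seq_along(tables)) {
  if (!length(patterns)) stop("no patterns to tabulate")
  ord <- tables[[1]]$order
  vals <- matrix(NA_real_, length(piece_order), length(patterns))
  for (i in seq_along(piece_order)) {
    tb <- tables[[piece_order[i]]]
    for (j in seq_along(patterns)) {
      p <- pattern_probability(tb, parse_pattern(patterns[j]))
      if (is.na(p) || p == 0)
        stop("universality violation: pattern [", patterns[j],
             "] unobserved in piece ", piece_order[i])
      vals[i, j] <- p
    }
  }
  corpus_matrix(vals, patterns, piece_order, ord)
}

#' Bundled Beethoven piano-sonata probability matrices
#'
#' Pooled transitional probabilities of the interval patterns universal to
#' all 32 Beethoven piano sonatas, by Markov order: 20 two-tone patterns
#' (order 1), 37 three-tone (order 2), 12 four-tone (order 3), 3 five-tone
#' (order 4) and a single six-tone pattern (order 5). Rows follow the
#' sonata serial numbers 1..32 (publication order). Values are printed to
#' three decimals in the source data.
#'
#' @param order 1, 2, 3, 4 or 5.
#' @return A [corpus_matrix()], 32 rows.
#' @export
sonata_tp_matrix <- function(order) {
  if (!order %in% 1:5)
    stop("bundled matrices exist for orders 1-5, got ", order)
  path <- system.file("extdata",
                      sprintf("beethoven_tp_order%d.csv", order),
                      package = "melodicdrift", mustWork = TRUE)
  read_corpus_csv(path, order = order)
}

#' Read / write a corpus matrix as CSV
#'
#' First column `piece_index`, remaining columns pattern strings. The
#' round trip is exact at full precision when `digits = NA`.
#'
#' @param path CSV file path.
#' @param order Markov order recorded on the object (inferred from the
#'   first pattern string when `NULL`).
#' @return `read_corpus_csv()`: a [corpus_matrix()];
#'   `write_corpus_csv()`: the path, invisibly.
#' @export
read_corpus_csv <- function(path, order = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "piece_index")
    stop("corpus CSV must start with a 'piece_index' column")
  pats <- names(d)[-1]
  if (is.null(order)) order <- length(strsplit(pats[1], ",")[[1]]) - 1L
  corpus_matrix(as.matrix(d[, -1, drop = FALSE]), pats, d$piece_index, order)
}

#' @rdname read_corpus_csv
#' @param mat a [corpus_matrix()].
#' @param digits round values on output (`NA` keeps full precision; the
#'   published tables use 3).
#' @export
write_corpus_csv <- function(mat, path, digits = NA) {
  vals <- unclass(mat)
  if (!is.na(digits)) vals <- round(vals, digits)
  d <- data.frame(piece_index = as.integer(rownames(mat)),
                  vals, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
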