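#' Specification of a synthetic drifting-corpus generator
#'
#' Describes an ordered corpus of pieces whose melodic lines are drawn from
#' an order-n Markov chain over relative interval patterns, in which one
#' designated pattern's transitional probability drifts linearly with the
#' piece serial index: at piece t the target outcome has probability
#' `clamp(p0 + slope * (t - 1), 0.01, 0.99)` and the remaining outcomes of
#' the same context share the remainder proportionally.
#'
#' The defaults mirror the geometry of the sonata corpus: 32 pieces of 3
#' movements each, order 1, about two thousand melody notes per movement,
#' and a drift of 0.012 per piece step on the rising-whole-tone pattern
#' `[0,2]` (a total drift of about 0.37 across the corpus).
#'
#' @param order Markov order of the generating chain.
#' @param base_table named list mapping context strings to named outcome
#'   probability vectors (each summing to 1) — the piece-1 chain.
#' @param target_pattern an [interval_pattern()] whose probability drifts.
#' @param slope drift in probability per piece-index step.
#' @param n_pieces,movements_per_piece,movement_length corpus geometry.
#' @param seed integer seed; corpora are reproducible bit-for-bit from the
#'   spec.
#' @return A `drift_spec` list.
#' @export
drift_spec <- function(order = 1L,
                       base_table = list("0" = c("-2" = 0.30, "-1" = 0.25,
                                                 "1" = 0.25, "2" = 0.20)),
                       target_pattern = interval_pattern(c(0L, 2L)),
                       slope = 0.012,
                       n_pieces = 32L,
                       movements_per_piece = 3L,
                       movement_length = 2000L,
                       seed = 1L) {
  for (cx in names(base_table)) {
    s <- sum(base_table[[cx]])
    if (abs(s - 1) > 1e-9)
      stop("base table context [", cx, "] probabilities sum to ", s)
  }
  if (length(target_pattern) != order + 1L)
    stop("target pattern order does not match chain order")
  structure(list(order = as.integer(order), base_table = base_table,
                 target_pattern = target_pattern, slope = slope,
                 n_pieces = as.integer(n_pieces),
                 movements_per_piece = as.integer(movements_per_piece),
                 movement_length = as.integer(movement_length),
                 seed = as.integer(seed)),
            class = "drift_spec")
}

#' Drifted chain probabilities at one piece index
#'
#' @param spec a [drift_spec()].
#' @param t piece index in `1..n_pieces`.
#' @return Named list of per-context outcome probability vectors, each
#'   summing to 1.
#' @export
drifted_table <- function(spec, t) {
  offs <- as.integer(spec$target_pattern)
  ctx <- paste(offs[-length(offs)], collapse = ",")
  out <- as.character(offs[length(offs)])
  tab <- spec$base_table
  v <- tab[[ctx]]
  if (is.null(v) || !(out %in% names(v)))
    stop("target pattern not present in base table context [", ctx, "]")
  p0 <- v[[out]]
  pt <- min(max(p0 + spec$slope * (t - 1), 0.01), 0.99)
  others <- setdiff(names(v), out)
  v[others] <- v[others] * (1 - pt) / sum(v[others])
  v[[out]] <- pt
  tab[[ctx]] <- v
  tab
}

movement_seed <- function(spec, t, m) {
  as.integer((as.double(spec$seed) * 7919 + t * 104729 + m * 1299709) %%
               2147483629)
}

# one realization of the order-n chain with the table at piece t
sample_movement <- function(spec, t, m) {
  tab <- drifted_table(spec, t)
  set.seed(movement_seed(spec, t, m))
  len <- spec$movement_length
  n <- spec$order

  dead <- names(tab)[vapply(tab, function(v) !length(v) || sum(v) == 0, NA)]
  if (length(dead))
    stop("dead-end context [", dead[1], "] in generator table")

  ctx <- sample(names(tab), 1L)
  start_offs <- as.integer(strsplit(ctx, ",")[[1]])
  pitches <- 60L + start_offs

  if (n == 1L) {
    # single relative context: interval increments are i.i.d.
    v <- tab[["0"]]
    outs <- as.integer(names(v))
    steps <- outs[sample.int(length(outs), len - 1L, replace = TRUE, prob = v)]
    pitches <- as.integer(60 + cumsum(c(0L, steps)))
  } else {
    while (length(pitches) < len) {
      first <- pitches[length(pitches) - n + 1L]
      ctx <- paste(pitches[(length(pitches) - n + 1L):length(pitches)] - first,
                   collapse = ",")
      v <- tab[[ctx]]
      if (is.null(v) || !length(v))
        stop("dead-end context [", ctx, "] reached during generation")
      outs <- as.integer(names(v))
      out <- outs[sample.int(length(outs), 1L, prob = v)]
      pitches <- c(pitches, first + out)
    }
  }
  melodic_sequence(sprintf("piece%02d", t), sprintf("mvt%d", m), pitches)
}

#' Generate one piece of a synthetic corpus
#'
#' Each movement is an independent realization of the order-n chain with
#' the drifted table at piece index `t`, started from a uniformly chosen
#' context and pitch-realized from C4 by cumulative offsets. Deterministic
#' given `(seed, t, movement index)`.
#'
#' @param spec a [drift_spec()].
#' @param t piece index in `1..n_pieces`.
#' @return List of [melodic_sequence()]s, one per movement.
#' @export
generate_piece <- function(spec, t) {
  if (t < 1 || t > spec$n_pieces)
    stop("piece index out of range 1..", spec$n_pieces)
  lapply(seq_len(spec$movements_per_piece),
         function(m) sample_movement(spec, t, m))
}

#' Generate the full synthetic corpus
#'
#' @param spec a [drift_spec()].
#' @return List of length `n_pieces`; element t is [generate_piece()]`(spec, t)`.
#' @export
generate_corpus <- function(spec) {
  lapply(seq_len(spec$n_pieces), function(t) generate_piece(spec, t))
}

# pooled per-piece tables for a generated corpus
pooled_piece_tables <- function(corpus, order) {
  lapply(corpus, function(movs)
    pool_movements(lapply(movs, count_ngrams, order = order)))
}

#' Parameter-recovery experiment on synthetic drifting corpora
#'
#' Runs the complete analysis pipeline — n-gram counting per movement,
#' pooling per piece, universality filtering, corpus-matrix assembly,
#' stepwise regression of piece index on probabilities and the screened
#' final-model rule — on `replicates` independently seeded corpora, and
#' reports how often the drifting target pattern is recovered.
#'
#' @param spec a [drift_spec()].
#' @param replicates number of simulated corpora.
#' @param p_enter,p_remove,vif_limit,ci_limit analysis settings, defaulting
#'   to the pipeline's.
#' @return List with `selection_rate` (fraction of replicates whose final
#'   model contains the target pattern), `sign_match_rate` (fraction in
#'   which additionally `sign(B)` equals `sign(slope)`), and `replicates`.
#' @export
recovery_experiment <- function(spec, replicates,
                                p_enter = 0.05, p_remove = 0.10,
                                vif_limit = 2, ci_limit = 20) {
  if (replicates < 1) stop("replicates must be >= 1")
  target <- pattern_string(spec$target_pattern)
  selected <- sign_ok <- logical(replicates)
  for (r in seq_len(replicates)) {
    rspec <- spec
    rspec$seed <- as.integer((as.double(spec$seed) + r * 49999) %% 2147483629)
    corpus <- generate_corpus(rspec)
    tabs <- pooled_piece_tables(corpus, spec$order)
    univ <- universal_patterns(tabs, spec$order)
    if (!(target %in% univ)) next
    mat <- build_matrix(tabs, univ)
    sw <- stepwise_regression(mat, as.numeric(rownames(mat)),
                              p_enter, p_remove)
    final <- tryCatch(select_final(sw, vif_limit, ci_limit),
                      error = function(e) NULL)
    if (is.null(final)) next
    if (target %in% final$predictors) {
      selected[r] <- TRUE
      sign_ok[r] <- sign(final$B[[target]]) == sign(spec$slope)
    }
  }
  list(selection_rate = mean(selected),
       sign_match_rate = mean(sign_ok),
       replicates = replicates)
}
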