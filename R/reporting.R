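#' Pipeline configuration
#'
#' @param orders Markov orders to analyse, a subset of 1..7.
#' @param p_enter,p_remove stepwise entry/removal thresholds.
#' @param vif_limit,ci_limit collinearity screening limits (the analysis
#'   convention is VIF < 2 and CI < 20).
#' @param seed integer seed for any stochastic stage.
#' @param out_dir directory for report files.
#' @param verbose emit one log line per pipeline stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(orders = 1:7, p_enter = 0.05, p_remove = 0.10,
                            vif_limit = 2, ci_limit = 20, seed = 1L,
                            out_dir = ".", verbose = TRUE) {
  if (!all(orders %in% 1:7)) stop("orders must be a subset of 1..7")
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1))
    stop("need 0 < p_enter <= p_remove < 1")
  structure(list(orders = as.integer(orders), p_enter = p_enter,
                 p_remove = p_remove, vif_limit = vif_limit,
                 ci_limit = ci_limit, seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

log_stage <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf(fmt, ...))
  invisible(NULL)
}

note_names_default <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Diatonic instantiations of an interval pattern
#'
#' Realizes a relative interval pattern from every degree of a seven-tone
#' major scale and keeps the realizations in which every pitch class stays
#' in the scale (octave-reduced). Note names are the natural names of the
#' given scale; no enharmonic inference is attempted.
#'
#' @param pattern an [interval_pattern()].
#' @param scale named integer vector of 7 pitch classes; default C major.
#' @return Data frame with columns `degrees` (roman-numeral path, e.g.
#'   `"III,IV"`) and `notes` (e.g. `"E,F"`); zero rows when no degree
#'   admits the pattern diatonically.
#' @examples
#' diatonic_instantiations(interval_pattern(c(0, 1)))   # E,F and B,C
#' @export
diatonic_instantiations <- function(pattern, scale = note_names_default) {
  if (length(scale) != 7L)
    stop("scale must have exactly 7 pitch classes, got ", length(scale))
  offs <- as.integer(pattern)
  romans <- c("I", "II", "III", "IV", "V", "VI", "VII")
  pcs <- as.integer(scale) %% 12L
  rows <- list()
  for (d in 1:7) {
    realized <- (pcs[d] + offs) %% 12L
    if (all(realized %in% pcs)) {
      idx <- match(realized, pcs)
      rows[[length(rows) + 1L]] <- data.frame(
        degrees = paste(romans[idx], collapse = ","),
        notes = paste(names(scale)[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(degrees = character(0), notes = character(0)))
  do.call(rbind, rows)
}

# model report mirroring the published regression tables
model_report_frame <- function(model) {
  k <- length(model$predictors)
  rows <- data.frame(
    Variable = c(model$predictors, "R2", "adj R2", "F", "F p"),
    B = c(round(model$B, 3), model$R2, model$adj_R2, model$F, model$F_p),
    `SE B` = c(round(model$SE, 3), rep(NA, 4)),
    beta = c(round(model$beta, 3), rep(NA, 4)),
    VIF = c(round(model$VIF, 3), rep(NA, 4)),
    CI = c(rep(round(max(model$CI), 2), k), rep(NA, 4)),
    check.names = FALSE, stringsAsFactors = FALSE)
  rows
}

model_json <- function(model) {
  list(predictors = as.list(model$predictors),
       intercept = model$intercept,
       B = as.list(model$B), SE = as.list(model$SE),
       beta = as.list(model$beta), p_values = as.list(model$p_values),
       VIF = as.list(model$VIF), CI = model$CI,
       R2 = model$R2, adj_R2 = model$adj_R2,
       F = model$F, F_df = model$F_df, F_p = model$F_p, n = model$n)
}

#' Write the regression report for one order
#'
#' Emits a CSV mirroring the published stepwise tables (per-variable rows
#' B, SE B, beta, VIF, CI, then model rows R2, adj R2, F, F p — the CI
#' column carries the model's largest condition index; the per-dimension
#' indices are in the JSON) and a machine-readable JSON of the full path.
#'
#' @param result a [stepwise_regression()] result.
#' @param final the adopted model from [select_final()], or `NULL` when no
#'   predictor entered.
#' @param prefix output file prefix (paths `<prefix>.csv`,
#'   `<prefix>.json`).
#' @return Invisibly, the two file paths.
#' @export
write_model_report <- function(result, final, prefix) {
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  if (is.null(final)) {
    utils::write.csv(data.frame(
      Variable = "(none)",
      note = "no predictor met the entry criterion"), csv_path,
      row.names = FALSE, quote = TRUE)
  } else {
    utils::write.csv(model_report_frame(final), csv_path,
                     row.names = FALSE, quote = TRUE, na = "")
  }
  jsonlite::write_json(
    list(settings = result$settings,
         path = lapply(result$path, model_json),
         final = if (is.null(final)) NULL else model_json(final)),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Re-run the sonata trend regressions from the bundled matrices
#'
#' Loads the bundled piece-by-pattern matrix for the given order, runs
#' stepwise selection with collinearity screening against the piece serial
#' numbers 1..32, and (optionally) writes the report files. At order 5 the
#' single universal pattern does not reach the entry criterion and the
#' result has an empty path.
#'
#' @param order 1, 2, 3, 4 or 5.
#' @param config a [pipeline_config()].
#' @param write write report files under `config$out_dir`?
#' @return List with `matrix`, `result` (the stepwise path), `final` (the
#'   adopted model or `NULL`).
#' @export
reproduce_regression <- function(order, config = pipeline_config(),
                                 write = FALSE) {
  mat <- sonata_tp_matrix(order)
  y <- as.numeric(rownames(mat))
  log_stage(config, "order %d: %d pieces x %d universal patterns",
            order, nrow(mat), ncol(mat))
  result <- stepwise_regression(mat, y, config$p_enter, config$p_remove)
  final <- if (length(result$path))
    select_final(result, config$vif_limit, config$ci_limit) else NULL
  log_stage(config, "order %d: %d path model(s); final model has %d predictor(s)",
            order, length(result$path),
            if (is.null(final)) 0L else length(final$predictors))
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_report(result, final,
                       file.path(config$out_dir,
                                 sprintf("trend_order%d", order)))
  }
  list(matrix = mat, result = result, final = final)
}

# read a corpus from a directory of MusicXML files named
# <piece>_<movement>.xml / .musicxml, or from a coded CSV
read_corpus_input <- function(input) {
  if (dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(xml|musicxml)$",
                        full.names = TRUE)
    if (!length(files)) stop("no MusicXML files found under ", input)
    lapply(sort(files), function(f) {
      stem <- sub("\\.(xml|musicxml)$", "", basename(f))
      parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
      piece <- parts[1]
      mvt <- if (length(parts) > 1) paste(parts[-1], collapse = "_") else "1"
      extract_highest_line(read_musicxml(f), piece, mvt)
    })
  } else if (file.exists(input)) {
    read_coded_csv(input)
  } else {
    stop("unreadable input: ", input)
  }
}

#' Run the full corpus pipeline
#'
#' Encode (MusicXML directory or coded CSV to melodic sequences), count
#' transitional probabilities per movement and pool per piece for each
#' requested order, filter universal patterns, assemble the corpus matrix,
#' regress piece order on probabilities stepwise with screening, and write
#' per-order reports. Pieces are ordered by sorted `piece_id`.
#'
#' @param input a directory of `.xml`/`.musicxml` files named
#'   `<piece>_<movement>.xml`, or a coded-sequence CSV path.
#' @param config a [pipeline_config()].
#' @return Invisibly, a named list per order with elements `patterns`,
#'   `matrix` (or `NULL`), `result`, `final`, `files`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  sequences <- read_corpus_input(input)
  pieces <- sort(unique(vapply(sequences, function(s) s$piece_id, "")))
  if (length(pieces) < 2L)
    stop("corpus must contain at least 2 pieces, found ", length(pieces))
  log_stage(config, "encode: %d movement(s) across %d piece(s)",
            length(sequences), length(pieces))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  out <- list()
  for (ord in config$orders) {
    tabs <- lapply(pieces, function(p) {
      movs <- sequences[vapply(sequences, function(s) s$piece_id, "") == p]
      pool_movements(lapply(movs, count_ngrams, order = ord))
    })
    univ <- universal_patterns(tabs, ord)
    log_stage(config, "order %d: %d universal pattern(s)", ord, length(univ))
    prefix <- file.path(config$out_dir, sprintf("trend_order%d", ord))
    if (!length(univ)) {
      utils::write.csv(data.frame(
        Variable = "(none)",
        note = "zero candidate patterns: no interval pattern appears in every piece"),
        paste0(prefix, ".csv"), row.names = FALSE, quote = TRUE)
      out[[as.character(ord)]] <- list(patterns = character(0), matrix = NULL,
                                       result = NULL, final = NULL,
                                       files = paste0(prefix, ".csv"))
      next
    }
    mat <- build_matrix(tabs, univ)
    write_corpus_csv(mat, paste0(prefix, "_matrix.csv"))
    sw <- stepwise_regression(mat, as.numeric(seq_along(pieces)),
                              config$p_enter, config$p_remove)
    final <- if (length(sw$path))
      tryCatch(select_final(sw, config$vif_limit, config$ci_limit),
               error = function(e) NULL) else NULL
    files <- write_model_report(sw, final, prefix)
    log_stage(config, "order %d: final model has %d predictor(s)", ord,
              if (is.null(final)) 0L else length(final$predictors))
    out[[as.character(ord)]] <- list(patterns = univ, matrix = mat,
                                     result = sw, final = final,
                                     files = files)
  }
  invisible(out)
}

#' Emit a synthetic coded-sequence corpus with provenance sidecar
#'
#' Generates the corpus described by `spec`, writes it as a coded-sequence
#' CSV and records the generator settings in a JSON sidecar.
#'
#' @param spec a [drift_spec()].
#' @param path output CSV path (`<path>.json` gets the sidecar).
#' @return Invisibly, the CSV path.
#' @export
simulate_corpus_csv <- function(spec, path) {
  corpus <- generate_corpus(spec)
  write_coded_csv(unlist(corpus, recursive = FALSE), path)
  side <- spec
  side$target_pattern <- pattern_string(spec$target_pattern)
  jsonlite::write_json(unclass(side), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
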