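#' Ordinary least squares with the report statistics used for trend tests
#'
#' Fits `y ~ X` with an intercept and returns the quantities reported in
#' the stepwise trend analysis: unstandardized coefficients B with standard
#' errors and two-sided t-based p-values, standardized coefficients
#' `beta_j = B_j * sd(x_j) / sd(y)` (sample standard deviations), variance
#' inflation factors, condition indices of the unit-scaled design including
#' the intercept, R-squared, adjusted R-squared and the overall F test.
#'
#' @param X numeric matrix (N rows, k predictors) with column names; `k = 0`
#'   fits the intercept-only null model.
#' @param y numeric response of length N.
#' @return A `tp_model` list: `predictors`, `intercept`, `B`, `SE`, `beta`,
#'   `p_values`, `VIF`, `CI`, `R2`, `adj_R2`, `F`, `F_df`, `F_p`, `n`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (k == 0L) {
    fit <- stats::lm(y ~ 1)
    return(structure(list(predictors = character(0), intercept = mean(y),
                          B = numeric(0), SE = numeric(0), beta = numeric(0),
                          p_values = numeric(0), VIF = numeric(0),
                          CI = 1, R2 = 0, adj_R2 = 0, F = NA_real_,
                          F_df = c(0L, n - 1L), F_p = NA_real_, n = n,
                          fit = fit),
                     class = "tp_model"))
  }
  if (n <= k + 1L)
    stop("need more observations than predictors plus intercept")
  if (qr(cbind(1, X))$rank < k + 1L)
    stop("singular design: predictors are exactly collinear")

  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  ct <- sm$coefficients
  B <- ct[-1, 1]; SE <- ct[-1, 2]; pv <- ct[-1, 4]
  names(B) <- names(SE) <- names(pv) <- colnames(X)
  R2 <- sm$r.squared
  Fstat <- (R2 / k) / ((1 - R2) / (n - k - 1))
  structure(list(
    predictors = colnames(X),
    intercept = unname(ct[1, 1]),
    B = B, SE = SE,
    beta = B * apply(X, 2, stats::sd) / stats::sd(y),
    p_values = pv,
    VIF = vif(X),
    CI = condition_indices(X),
    R2 = R2,
    adj_R2 = 1 - (1 - R2) * (n - 1) / (n - k - 1),
    F = Fstat,
    F_df = c(k, n - k - 1L),
    F_p = stats::pf(Fstat, k, n - k - 1, lower.tail = FALSE),
    n = n, fit = fit), class = "tp_model")
}

#' @export
print.tp_model <- function(x, ...) {
  k <- length(x$predictors)
  cat("trend model: ", k, " predictor", if (k != 1) "s", "\n", sep = "")
  if (k) {
    print(data.frame(B = x$B, `SE B` = x$SE, beta = x$beta, p = x$p_values,
                     VIF = x$VIF, check.names = FALSE), digits = 4)
    cat(sprintf("R2 = %.3f, adj R2 = %.3f, F(%d,%d) = %.2f, p = %.4g, max CI = %.2f\n",
                x$R2, x$adj_R2, x$F_df[1], x$F_df[2], x$F, x$F_p, max(x$CI)))
  } else {
    cat("intercept-only (no predictor entered)\n")
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column j on
#' the remaining columns plus an intercept. With a single column VIF is
#' exactly 1. Exact collinearity yields `Inf`, not an error, so screening
#' can report it.
#'
#' @param X numeric matrix with at least one column.
#' @return Numeric vector of length `ncol(X)`, each at least 1.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 1L) stop("vif needs at least one column")
  if (k == 1L) return(stats::setNames(1, colnames(X)))
  out <- vapply(seq_len(k), function(j) {
    # a perfect auxiliary fit is the detected condition, not a defect, so
    # summary.lm's perfect-fit warning is silenced here
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(X))
}

#' Condition indices of the scaled design
#'
#' Appends an intercept column of ones, scales every column to unit
#' Euclidean norm without centering, and returns the ratios of the largest
#' singular value to each singular value, sorted ascending (the smallest is
#' 1 by construction). This is the collinearity-diagnostics convention of
#' the major statistics packages whose regression tables report "CI".
#'
#' @param X numeric matrix with at least one column.
#' @return Ascending numeric vector of `ncol(X) + 1` condition indices.
#' @export
condition_indices <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("condition_indices needs at least one column")
  Xd <- cbind(`(Intercept)` = 1, X)
  norms <- sqrt(colSums(Xd^2))
  if (any(norms == 0)) stop("degenerate design: zero column")
  sv <- svd(sweep(Xd, 2, norms, "/"), nu = 0, nv = 0)$d
  sv <- pmax(sv, .Machine$double.eps)
  sort(max(sv) / sv)
}

#' Adjusted R-squared implied by an F statistic
#'
#' Inverts the identities `F = (R2/k) / ((1 - R2)/(n - k - 1))` and
#' `adj R2 = 1 - (1 - R2)(n - 1)/(n - k - 1)`, which every fitted model in
#' this package satisfies. Useful for consistency checks of reported
#' F / adjusted-R-squared pairs.
#'
#' @param F overall F statistic.
#' @param k number of predictors.
#' @param n number of observations.
#' @return The implied adjusted R-squared.
#' @export
adj_r2_from_f <- function(F, k, n) {
  R2 <- F * k / (F * k + n - k - 1)
  1 - (1 - R2) * (n - 1) / (n - k - 1)
}

# lexicographically smallest pattern first among tied p-values
order_candidates <- function(p, names) {
  ord <- pattern_lex_order(names)
  names_sorted <- names[ord]
  names_sorted[order(p[names_sorted])][1]
}

#' Stepwise selection of drifting interval patterns
#'
#' Forward-stepwise multiple regression of the piece serial index on
#' transitional probabilities: at each step the candidate with the smallest
#' partial p-value enters if below `p_enter`; any included predictor whose
#' p-value then exceeds `p_remove` is removed; the procedure stops when no
#' change occurs. Every accepted model along the path is recorded. Ties in
#' partial p are broken toward the lexicographically smaller pattern.
#'
#' @param X a [corpus_matrix()] or plain numeric matrix of candidate
#'   columns.
#' @param y numeric response (piece serial indices).
#' @param p_enter,p_remove entry and removal thresholds (defaults 0.05 and
#'   0.10).
#' @return A `stepwise_result` list: `path` (list of [fit_ols()] models),
#'   `final` (last path model, or the intercept-only null model when
#'   nothing enters), `settings`.
#' @export
stepwise_regression <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1))
    stop("need 0 < p_enter <= p_remove < 1")
  X <- as.matrix(X)
  if (length(y) < 4L) stop("need at least 4 observations")
  if (!ncol(X)) stop("no candidate columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  sel <- character(0)
  path <- list()
  repeat {
    cand <- setdiff(colnames(X), sel)
    if (!length(cand)) break
    partial_p <- vapply(cand, function(v) {
      Xt <- X[, c(sel, v), drop = FALSE]
      if (qr(cbind(1, Xt))$rank < ncol(Xt) + 1L) return(NA_real_)
      stats::coef(summary(stats::lm(y ~ Xt)))[length(sel) + 2L, 4]
    }, 0)
    partial_p <- partial_p[!is.na(partial_p)]
    if (!length(partial_p) || min(partial_p) >= p_enter) break
    entered <- order_candidates(partial_p, names(partial_p))
    sel <- c(sel, entered)
    path[[length(path) + 1L]] <- fit_ols(X[, sel, drop = FALSE], y)
    # backward pass: drop predictors that no longer hold up
    repeat {
      m <- path[[length(path)]]
      if (max(m$p_values) <= p_remove) break
      worst <- names(which.max(m$p_values))
      sel <- setdiff(sel, worst)
      if (!length(sel)) break
      path[[length(path) + 1L]] <- fit_ols(X[, sel, drop = FALSE], y)
    }
  }

  final <- if (length(path)) path[[length(path)]]
           else fit_ols(X[, character(0), drop = FALSE], y)
  structure(list(path = path, final = final,
                 settings = list(p_enter = p_enter, p_remove = p_remove)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("stepwise path of", length(x$path), "model(s)\n")
  for (i in seq_along(x$path))
    cat(sprintf("  model %d: {%s}  adj R2 = %.3f\n", i,
                paste(x$path[[i]]$predictors, collapse = "; "),
                x$path[[i]]$adj_R2))
  if (!length(x$path)) cat("  (no predictor entered)\n")
  invisible(x)
}

#' Final-model rule with collinearity screening
#'
#' Among the models on the stepwise path in which every predictor's VIF is
#' below `vif_limit` and every condition index is below `ci_limit`, the
#' model with the greatest number of interval patterns is adopted; ties go
#' to the higher R-squared.
#'
#' @param result a [stepwise_regression()] result with a non-empty path.
#' @param vif_limit,ci_limit screening limits (defaults 2 and 20).
#' @return The adopted `tp_model`.
#' @export
select_final <- function(result, vif_limit = 2, ci_limit = 20) {
  if (!length(result$path)) stop("stepwise path is empty: nothing to select")
  ok <- vapply(result$path, function(m)
    all(m$VIF < vif_limit) && all(m$CI < ci_limit), NA)
  if (!any(ok)) {
    worst <- result$path[[1]]
    reason <- if (any(worst$VIF >= vif_limit)) "VIF" else "condition index"
    stop("no path model passes the collinearity screens (", reason,
         " limit violated in every model)")
  }
  passing <- result$path[ok]
  sizes <- vapply(passing, function(m) length(m$predictors), 0L)
  best <- passing[sizes == max(sizes)]
  best[[which.max(vapply(best, function(m) m$R2, 0))]]
}
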