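## One-step fitting, thresholding and trivalent discretization.
##
## A gene's expression values are sorted ascending and a one-step function
## (low mean before position k, high mean at/after it) is fitted by scanning
## every step position and keeping the one with minimal residual sum of
## squares.  The midpoint of the two segment means is the gene's threshold;
## a symmetric noise margin around it defines an intermediate band whose
## calls are ignored by all Boolean counting.

.check_expression <- function(mat, what = "matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop(what, " is empty", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop(what, " must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene identifiers in ", what, call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifiers in ", what, call. = FALSE)
  if (!all(is.finite(mat)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(mat)
}

#' Fit a one-step function to an expression profile
#'
#' Sorts the values ascending, evaluates every step position k in 1..n-1,
#' and returns the fit minimizing the residual sum of squares (ties broken
#' toward the smallest k).  The threshold is the midpoint of the two segment
#' means.  A regression statistic
#' \deqn{F = \frac{\sum_i (\hat X_i - \bar X)^2 / (m-1)}{\sum_i (X_i - \hat X_i)^2 / (n-m)}}
#' measures the sharpness of the step, with \code{df_model} = m the adaptive
#' regression degrees of freedom (default 3: two segment means plus the step
#' position).  A perfect two-level profile has zero residual; its F statistic
#' is reported as \code{Inf} and \code{exact_fit} is set.
#'
#' @param values numeric vector of log2 intensities, length >= 4.
#' @param df_model model degrees of freedom m used in the F statistic.
#' @return an object of class \code{StepFit}: a list with
#'   \code{step_index}, \code{low_mean}, \code{high_mean}, \code{sse},
#'   \code{fstat}, \code{df_model}, \code{threshold}, \code{exact_fit},
#'   \code{n}.
#' @examples
#' fitStep(c(1, 1, 1, 1, 5, 5, 5, 5))
#' @export
fitStep <- function(values, df_model = 3) {
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("values must be finite numeric", call. = FALSE)
  n <- length(values)
  if (n < 4L) stop("need at least 4 values to fit a step", call. = FALSE)
  x <- sort(unname(values))
  if (x[n] - x[1] == 0)
    stop("degenerate fit: constant series has no step", call. = FALSE)
  k <- seq_len(n - 1L)
  cs <- cumsum(x)
  tot <- cs[n]
  totss <- sum(x * x)
  low_mean <- cs[k] / k
  high_mean <- (tot - cs[k]) / (n - k)
  sse <- totss - cs[k]^2 / k - (tot - cs[k])^2 / (n - k)
  sse <- pmax(sse, 0)                      # guard rounding
  best <- which.min(sse)                   # ties -> smallest k
  s <- sse[best]
  exact <- s <= totss * 1e-12
  ssr <- cs[best]^2 / best + (tot - cs[best])^2 / (n - best) - tot^2 / n
  fstat <- if (exact) Inf else
    (ssr / (df_model - 1)) / (s / (n - df_model))
  structure(list(
    step_index = best,
    low_mean = low_mean[best],
    high_mean = high_mean[best],
    sse = if (exact) 0 else s,
    fstat = fstat,
    df_model = df_model,
    threshold = (low_mean[best] + high_mean[best]) / 2,
    exact_fit = exact,
    n = n), class = "StepFit")
}

#' @export
print.StepFit <- function(x, ...) {
  cat(sprintf(
    "StepFit: step at %d/%d, low %.3f / high %.3f, threshold %.3f, sse %.4g%s\n",
    x$step_index, x$n, x$low_mean, x$high_mean, x$threshold, x$sse,
    if (x$exact_fit) " (exact)" else ""))
  invisible(x)
}

#' Per-gene step thresholds for an expression matrix
#'
#' Applies \code{\link{fitStep}} independently to every gene.  Genes whose
#' fit is degenerate (constant profile) are flagged rather than dropped so
#' callers can exclude them downstream.  The per-gene standard deviation is
#' the sample SD across all samples of the matrix (used later by the
#' composite score normalization).
#'
#' @param mat numeric genes x samples matrix of log2 values with dimnames.
#' @param margin half-width of the intermediate band in log2 units; the
#'   default 0.5 makes the full band one log2 unit, i.e. a 2-fold change.
#' @param df_model passed to \code{\link{fitStep}}.
#' @return data.frame with columns \code{gene_id}, \code{threshold},
#'   \code{margin}, \code{stddev}, \code{degenerate}.
#' @export
thresholdMatrix <- function(mat, margin = 0.5, df_model = 3) {
  .check_expression(mat)
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  thr <- rep(NA_real_, nrow(mat))
  degen <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    fit <- tryCatch(fitStep(mat[i, ], df_model = df_model),
                    error = function(e) NULL)
    if (is.null(fit)) degen[i] <- TRUE else thr[i] <- fit$threshold
  }
  data.frame(
    gene_id = rownames(mat),
    threshold = thr,
    margin = margin,
    stddev = unname(apply(mat, 1, stats::sd)),
    degenerate = degen,
    row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Discretize an expression matrix into trivalent states
#'
#' Values above threshold + margin become HIGH, below threshold - margin
#' LOW, and anything inside the noise band MID.  Every gene of the matrix
#' must have a non-degenerate threshold; subset degenerate genes out first.
#'
#' @param mat numeric genes x samples matrix of log2 values.
#' @param thresholds data.frame as returned by \code{\link{thresholdMatrix}}.
#' @return a \linkS4class{TrivalentMatrix}.
#' @export
discretizeMatrix <- function(mat, thresholds) {
  .check_expression(mat)
  idx <- match(rownames(mat), thresholds$gene_id)
  if (anyNA(idx))
    stop("missing threshold for gene(s): ",
         paste(utils::head(rownames(mat)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  thr <- thresholds$threshold[idx]
  mar <- thresholds$margin[idx]
  bad <- thresholds$degenerate[idx] | !is.finite(thr)
  if (any(bad))
    stop("degenerate threshold for gene(s): ",
         paste(utils::head(rownames(mat)[bad], 5), collapse = ", "),
         call. = FALSE)
  states <- matrix(STATE_MID, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  states[mat > thr + mar] <- STATE_HIGH
  states[mat < thr - mar] <- STATE_LOW
  storage.mode(states) <- "integer"
  new("TrivalentMatrix", states = states)
}

#' Dynamic-range gene filter
#'
#' A gene is retained iff at least \code{min_state_frac} of samples are
#' called HIGH, at least \code{min_state_frac} are called LOW, and its
#' 10th-to-90th percentile expression spread is at least
#' \code{min_percentile_range} log2 units.  Genes failing either rule carry
#' too little dynamic range for reliable Boolean calls.
#'
#' @param mat numeric genes x samples matrix of log2 values.
#' @param states \linkS4class{TrivalentMatrix} computed from \code{mat}.
#' @param min_state_frac minimum fraction of samples in each extreme state.
#' @param min_percentile_range minimum 10th-90th percentile spread (log2).
#' @return character vector of retained gene ids, in input order.
#' @export
filterGenes <- function(mat, states, min_state_frac = 0.05,
                        min_percentile_range = 1.0) {
  .check_expression(mat)
  stopifnot(is(states, "TrivalentMatrix"))
  st <- stateMatrix(states)
  if (!identical(rownames(st), rownames(mat)) ||
      !identical(colnames(st), colnames(mat)))
    stop("states were not computed from this matrix", call. = FALSE)
  n <- ncol(mat)
  frac_high <- rowSums(st == STATE_HIGH) / n
  frac_low <- rowSums(st == STATE_LOW) / n
  qs <- t(apply(mat, 1, stats::quantile, probs = c(0.1, 0.9), names = FALSE))
  keep <- frac_high >= min_state_frac & frac_low >= min_state_frac &
    (qs[, 2] - qs[, 1]) >= min_percentile_range
  rownames(mat)[keep]
}
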