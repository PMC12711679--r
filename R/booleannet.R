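## Pairwise Boolean implication statistics and relation discovery.
##
## For a gene pair (A, B) the samples in which both genes are called LOW or
## HIGH are tallied into four quadrants a00, a01, a10, a11 (first index =
## state of A, second = state of B; 0 = LOW, 1 = HIGH; MID calls excluded
## pairwise).  A quadrant is sparse when its observed count falls well below
## the count expected under independence:
##   n_hat_ij = (row marginal / total) * (column marginal / total) * total
##   S_ij     = (n_hat_ij - a_ij) / sqrt(n_hat_ij)
##   p_ij     = 1/2 * (a_ij / row marginal + a_ij / column marginal)
## and the sparse-quadrant pattern determines the relation type: one sparse
## quadrant gives one of the four asymmetric implications, both off-diagonal
## quadrants sparse gives EQUIVALENT, both diagonal quadrants sparse gives
## OPPOSITE.

#' Discovery thresholds for sparse quadrants
#'
#' Two named presets are provided: \code{"network"} (statistic > 10, error
#' rate < 0.15), the stringent pair used to build implication networks on
#' large compendia, and \code{"screen"} (statistic > 3, error rate < 0.1)
#' for smaller designed experiments.
#'
#' @param preset one of \code{"network"}, \code{"screen"}; ignored when both
#'   \code{s_min} and \code{p_max} are supplied.
#' @param s_min sparsity statistic threshold (must be > 0).
#' @param p_max error-rate threshold in (0, 1).
#' @return list with elements \code{s_min}, \code{p_max}, \code{preset}.
#' @export
discoveryParams <- function(preset = c("network", "screen"),
                            s_min = NULL, p_max = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
                network = list(s_min = 10, p_max = 0.15),
                screen = list(s_min = 3, p_max = 0.1))
  if (is.null(s_min)) s_min <- def$s_min
  if (is.null(p_max)) p_max <- def$p_max
  if (!(s_min > 0)) stop("s_min must be > 0", call. = FALSE)
  if (!(p_max > 0 && p_max < 1)) stop("p_max must be in (0,1)", call. = FALSE)
  list(s_min = s_min, p_max = p_max, preset = preset)
}

#' Count Boolean scatter quadrants for two trivalent series
#'
#' A sample contributes only when both genes are called non-MID.
#'
#' @param states_a,states_b integer vectors in \{0,1,2\} of equal length.
#' @return named integer vector \code{a00, a01, a10, a11} (first index is
#'   the state of gene A, second of gene B; 0 = LOW, 1 = HIGH).
#' @export
countQuadrants <- function(states_a, states_b) {
  if (length(states_a) != length(states_b))
    stop("state series differ in length", call. = FALSE)
  use <- states_a != STATE_MID & states_b != STATE_MID
  a <- states_a[use] == STATE_HIGH
  b <- states_b[use] == STATE_HIGH
  c(a00 = sum(!a & !b), a01 = sum(!a & b),
    a10 = sum(a & !b), a11 = sum(a & b))
}

## Vectorized quadrant statistics over parallel count vectors.  Returns
## S, p, expected as n x 4 matrices (columns q00, q01, q10, q11).
.quadrant_stats <- function(a00, a01, a10, a11) {
  total <- a00 + a01 + a10 + a11
  nA0 <- a00 + a01; nA1 <- a10 + a11
  nB0 <- a00 + a10; nB1 <- a01 + a11
  row_m <- cbind(nA0, nA0, nA1, nA1)
  col_m <- cbind(nB0, nB1, nB0, nB1)
  a <- cbind(a00, a01, a10, a11)
  expected <- row_m * col_m / total
  S <- (expected - a) / sqrt(expected)
  p <- 0.5 * (a / row_m + a / col_m)
  colnames(expected) <- colnames(S) <- colnames(p) <-
    c("q00", "q01", "q10", "q11")
  list(S = S, p = p, expected = expected)
}

#' Sparsity statistics for a quadrant count table
#'
#' Evaluates, for each of the four quadrants, the expected count under
#' independence, the sparsity statistic S and the error rate p (see the
#' module description).  Both genes must have at least one LOW and one HIGH
#' call among the jointly non-MID samples; otherwise the marginal
#' probabilities are degenerate and an error is raised.
#'
#' @param counts named vector as returned by \code{\link{countQuadrants}}.
#' @return list with numeric length-4 vectors \code{s}, \code{p},
#'   \code{expected} (names \code{q00}..\code{q11}).
#' @export
implicationStats <- function(counts) {
  counts <- counts[c("a00", "a01", "a10", "a11")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative a00..a11", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("no jointly non-MID samples", call. = FALSE)
  marg <- c(counts["a00"] + counts["a01"], counts["a10"] + counts["a11"],
            counts["a00"] + counts["a10"], counts["a01"] + counts["a11"])
  if (any(marg == 0))
    stop("degenerate marginal: a gene has no LOW or no HIGH calls",
         call. = FALSE)
  st <- .quadrant_stats(counts[["a00"]], counts[["a01"]],
                        counts[["a10"]], counts[["a11"]])
  list(s = st$S[1, ], p = st$p[1, ], expected = st$expected[1, ])
}

## Vectorized relation classification from S/p matrices.
.classify <- function(S, p, s_min, p_max) {
  sparse <- S > s_min & p < p_max
  n_sparse <- rowSums(sparse)
  out <- rep("NONE", nrow(S))
  eq <- sparse[, "q01"] & sparse[, "q10"] & n_sparse == 2L
  op <- sparse[, "q00"] & sparse[, "q11"] & n_sparse == 2L
  out[eq] <- "EQUIVALENT"
  out[op] <- "OPPOSITE"
  one <- n_sparse == 1L
  single <- c(q00 = "LOW_HIGH", q01 = "LOW_LOW",
              q10 = "HIGH_HIGH", q11 = "HIGH_LOW")
  for (q in names(single))
    out[one & sparse[, q]] <- single[[q]]
  out
}

#' Classify the Boolean relation implied by quadrant statistics
#'
#' A quadrant (i,j) is sparse iff \code{S_ij > s_min} and
#' \code{p_ij < p_max}.  Exactly one sparse quadrant maps to an asymmetric
#' implication: (0,0) to LOW_HIGH, (0,1) to LOW_LOW, (1,0) to HIGH_HIGH,
#' (1,1) to HIGH_LOW.  Sparse off-diagonal pair gives EQUIVALENT, sparse
#' diagonal pair OPPOSITE.  No sparse quadrant, an adjacent sparse pair or
#' three or more sparse quadrants give NONE (the latter patterns are outside
#' the six-type taxonomy and treated as degenerate).
#'
#' @param stats list as returned by \code{\link{implicationStats}}.
#' @param params list as returned by \code{\link{discoveryParams}}.
#' @return a single relation type string.
#' @export
classifyRelation <- function(stats, params = discoveryParams()) {
  .classify(matrix(stats$s, 1, dimnames = list(NULL, c("q00", "q01", "q10", "q11"))),
            matrix(stats$p, 1, dimnames = list(NULL, c("q00", "q01", "q10", "q11"))),
            params$s_min, params$p_max)
}

## Converse of a relation when the gene pair is read in the other direction:
## "A high => B high" is the same constraint as "B low => A low".
.converse <- c(LOW_LOW = "HIGH_HIGH", HIGH_HIGH = "LOW_LOW",
               LOW_HIGH = "LOW_HIGH", HIGH_LOW = "HIGH_LOW",
               EQUIVALENT = "EQUIVALENT", OPPOSITE = "OPPOSITE",
               NONE = "NONE")

#' Discover all Boolean implication relations in a discretized matrix
#'
#' Evaluates every unordered gene pair once.  Asymmetric relations are
#' emitted in both directions (the converse relation holds when the pair is
#' read the other way round); symmetric relations are emitted once with
#' \code{gene_a < gene_b}.  Pairs with a degenerate marginal (a gene with no
#' LOW or no HIGH among the jointly non-MID samples) are skipped; gene
#' pre-filtering with \code{\link{filterGenes}} makes these rare.
#'
#' @param states a \linkS4class{TrivalentMatrix} (genes pre-filtered).
#' @param params list from \code{\link{discoveryParams}}.
#' @return data.frame of implication records ordered lexicographically by
#'   (gene_a, gene_b): columns \code{gene_a}, \code{gene_b},
#'   \code{relation}, quadrant counts \code{a00..a11}, statistics
#'   \code{s00..s11} and error rates \code{p00..p11} (oriented so that the
#'   first index is always the state of \code{gene_a}).
#' @export
discoverImplications <- function(states, params = discoveryParams()) {
  stopifnot(is(states, "TrivalentMatrix"))
  st <- stateMatrix(states)
  if (nrow(st) < 2L)
    stop("need at least 2 genes to discover implications", call. = FALSE)
  genes <- rownames(st)
  L <- (st == STATE_LOW) * 1
  H <- (st == STATE_HIGH) * 1
  A00 <- tcrossprod(L); A01 <- tcrossprod(L, H)
  A10 <- tcrossprod(H, L); A11 <- tcrossprod(H)
  iu <- which(upper.tri(A00), arr.ind = TRUE)
  i <- iu[, 1]; j <- iu[, 2]
  a00 <- A00[iu]; a01 <- A01[iu]; a10 <- A10[iu]; a11 <- A11[iu]
  tot <- a00 + a01 + a10 + a11
  ok <- tot > 0 & (a00 + a01) > 0 & (a10 + a11) > 0 &
    (a00 + a10) > 0 & (a01 + a11) > 0
  if (!all(ok)) {
    i <- i[ok]; j <- j[ok]
    a00 <- a00[ok]; a01 <- a01[ok]; a10 <- a10[ok]; a11 <- a11[ok]
  }
  if (!length(i)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      relation = character()))
  }
  qs <- .quadrant_stats(a00, a01, a10, a11)
  rel <- .classify(qs$S, qs$p, params$s_min, params$p_max)
  keep <- rel != "NONE"
  if (!any(keep)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      relation = character()))
  }
  mk <- function(ga, gb, relation, a00, a01, a10, a11, S, p) {
    data.frame(gene_a = ga, gene_b = gb, relation = relation,
               a00 = a00, a01 = a01, a10 = a10, a11 = a11,
               s00 = S[, 1], s01 = S[, 2], s10 = S[, 3], s11 = S[, 4],
               p00 = p[, 1], p01 = p[, 2], p10 = p[, 3], p11 = p[, 4],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  w <- which(keep)
  fwd <- mk(genes[i[w]], genes[j[w]], rel[w],
            a00[w], a01[w], a10[w], a11[w],
            qs$S[w, , drop = FALSE], qs$p[w, , drop = FALSE])
  asym <- rel[w] %in% ASYMMETRIC_TYPES
  recs <- fwd
  if (any(asym)) {
    wa <- w[asym]
    # swapped orientation: transpose the quadrant table
    qs_sw <- .quadrant_stats(a00[wa], a10[wa], a01[wa], a11[wa])
    rev <- mk(genes[j[wa]], genes[i[wa]], unname(.converse[rel[wa]]),
              a00[wa], a10[wa], a01[wa], a11[wa], qs_sw$S, qs_sw$p)
    recs <- rbind(fwd, rev)
  }
  # symmetric records stored once with gene_a < gene_b
  sym <- recs$relation %in% SYMMETRIC_TYPES & recs$gene_a > recs$gene_b
  if (any(sym)) {
    tmp <- recs$gene_a[sym]
    recs$gene_a[sym] <- recs$gene_b[sym]
    recs$gene_b[sym] <- tmp
    recs[sym, c("a01", "a10")] <- recs[sym, c("a10", "a01")]
    recs[sym, c("s01", "s10")] <- recs[sym, c("s10", "s01")]
    recs[sym, c("p01", "p10")] <- recs[sym, c("p10", "p01")]
  }
  recs <- recs[order(recs$gene_a, recs$gene_b, method = "radix"), ]
  rownames(recs) <- NULL
  recs
}

## Full discovery pipeline used both on observed data and on permuted nulls.
.discover_pipeline <- function(mat, params, margin = 0.5,
                               min_state_frac = 0.05,
                               min_percentile_range = 1.0, df_model = 3) {
  thr <- thresholdMatrix(mat, margin = margin, df_model = df_model)
  usable <- thr$gene_id[!thr$degenerate]
  if (length(usable) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      relation = character()))
  }
  sub <- mat[usable, , drop = FALSE]
  states <- discretizeMatrix(sub, thr)
  kept <- filterGenes(sub, states, min_state_frac = min_state_frac,
                      min_percentile_range = min_percentile_range)
  if (length(kept) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      relation = character()))
  }
  st <- new("TrivalentMatrix",
            states = stateMatrix(states)[kept, , drop = FALSE])
  discoverImplications(st, params)
}

#' Permutation estimate of the implication discovery FDR
#'
#' Each permutation shuffles every gene's values independently across
#' samples, destroying inter-gene structure while preserving each gene's
#' marginal distribution, then re-runs the full pipeline (threshold,
#' discretize, filter, discover).  The returned ratio is the mean permuted
#' discovery count divided by the original discovery count.  Because the
#' step fit is order-free, a within-gene shuffle leaves the gene's own
#' threshold unchanged; re-thresholding per permutation is therefore
#' equivalent and is done for symmetry with the observed analysis.
#'
#' @param mat numeric genes x samples log2 matrix.
#' @param params list from \code{\link{discoveryParams}}.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation RNG.
#' @param ... further arguments (\code{margin}, \code{min_state_frac},
#'   \code{min_percentile_range}, \code{df_model}) passed to the pipeline.
#' @return list with \code{fdr}, \code{n_original}, \code{n_permuted}
#'   (per-permutation counts).
#' @export
estimateFdr <- function(mat, params = discoveryParams(), n_perm = 10,
                        seed = 1, ...) {
  .check_expression(mat)
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("n_perm must be >= 1", call. = FALSE)
  orig <- nrow(.discover_pipeline(mat, params, ...))
  if (orig == 0)
    stop("no implications discovered in the original matrix; FDR undefined",
         call. = FALSE)
  set.seed(seed)
  counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- mat
    for (g in seq_len(nrow(mat)))
      perm[g, ] <- sample(mat[g, ])
    counts[b] <- nrow(.discover_pipeline(perm, params, ...))
  }
  list(fdr = mean(counts) / orig, n_original = orig, n_permuted = counts)
}
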