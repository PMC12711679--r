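## Composite signature scores, sample ordering/classification, survival
## stratification, response-signature refinement and the t-test sample-size
## calculation.

#' Signature specification
#'
#' A signature is a list of gene clusters, each carrying a weight of +1
#' (elevated on the disease side of the trajectory) or -1 (elevated on the
#' healthy side).
#'
#' @param clusters list of non-empty character vectors of gene ids.
#' @param weights numeric vector of +1/-1, one per cluster.
#' @return validated list with elements \code{clusters}, \code{weights}.
#' @export
signatureSpec <- function(clusters, weights) {
  if (!is.list(clusters) || length(clusters) == 0L)
    stop("clusters must be a non-empty list", call. = FALSE)
  if (any(lengths(clusters) == 0L))
    stop("empty cluster in signature", call. = FALSE)
  if (length(weights) != length(clusters))
    stop("one weight per cluster required", call. = FALSE)
  if (!all(weights %in% c(-1, 1)))
    stop("weights must be +1 or -1", call. = FALSE)
  list(clusters = clusters, weights = as.numeric(weights))
}

#' Composite signature score per sample
#'
#' Every signature gene is normalized with a modified Z score centered on
#' its step threshold, \eqn{z = (expr - SThr) / (3\,stddev)}; cluster
#' scores are the mean z over the cluster's genes and the composite score
#' is the weighted sum of cluster scores.
#'
#' @param mat numeric genes x samples log2 matrix.
#' @param thresholds data.frame from \code{\link{thresholdMatrix}} (must
#'   cover every signature gene with a non-degenerate threshold and a
#'   positive stddev).
#' @param spec signature from \code{\link{signatureSpec}}.
#' @return named numeric vector of scores, one per sample, in column order.
#' @export
compositeScore <- function(mat, thresholds, spec) {
  .check_expression(mat)
  genes <- unique(unlist(spec$clusters))
  missing_m <- setdiff(genes, rownames(mat))
  if (length(missing_m))
    stop("signature gene(s) absent from matrix: ",
         paste(utils::head(missing_m, 5), collapse = ", "), call. = FALSE)
  idx <- match(genes, thresholds$gene_id)
  if (anyNA(idx))
    stop("signature gene(s) without threshold: ",
         paste(utils::head(genes[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  th <- thresholds[idx, ]
  if (any(th$degenerate | !is.finite(th$threshold)))
    stop("degenerate threshold for signature gene(s): ",
         paste(utils::head(genes[th$degenerate], 5), collapse = ", "),
         call. = FALSE)
  if (any(th$stddev <= 0))
    stop("zero stddev for signature gene(s): ",
         paste(utils::head(genes[th$stddev <= 0], 5), collapse = ", "),
         call. = FALSE)
  z <- (mat[genes, , drop = FALSE] -
          th$threshold[match(genes, th$gene_id)]) /
    (3 * th$stddev[match(genes, th$gene_id)])
  score <- rep(0, ncol(mat))
  for (k in seq_along(spec$clusters)) {
    cl <- spec$clusters[[k]]
    score <- score + spec$weights[k] * colMeans(z[cl, , drop = FALSE])
  }
  stats::setNames(score, colnames(mat))
}

#' Order samples by composite score
#'
#' Ascending by score; ties keep input order (stable sort).
#'
#' @param scores named numeric vector of composite scores.
#' @return character vector of sample ids, lowest score first.
#' @export
orderSamples <- function(scores) {
  names(scores)[order(scores, method = "radix")]
}

#' ROC area under the curve
#'
#' Equals the Mann-Whitney probability that a randomly chosen positive
#' sample outranks a randomly chosen negative one, ties counted one half.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1/TRUE = positive) aligned with scores.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be non-empty", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratify survival at the step threshold of a composite score
#'
#' The step-fit threshold of the score vector splits samples into low and
#' high groups; the two groups are compared with the standard two-group
#' log-rank test (chi-square with 1 df).  Events at time zero are kept.
#'
#' @param scores named numeric vector of composite scores.
#' @param surv data.frame with columns \code{sample_id}, \code{time}
#'   (>= 0) and \code{event} (1 = event observed, 0 = censored).
#' @return list with \code{group} (named "low"/"high" per sample),
#'   \code{threshold}, \code{chisq}, \code{p_value}.
#' @export
stratifySurvival <- function(scores, surv) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(surv)))
  if (any(surv$time < 0) || !all(surv$event %in% 0:1))
    stop("survival table invalid (time >= 0, event in {0,1})", call. = FALSE)
  idx <- match(names(scores), surv$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from survival table: ",
         paste(utils::head(names(scores)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  if (length(unique(scores)) < 2L)
    stop("degenerate split: scores are constant", call. = FALSE)
  thr <- fitStep(scores)$threshold
  group <- ifelse(scores >= thr, "high", "low")
  if (length(unique(group)) < 2L)
    stop("degenerate split: all samples on one side of the threshold",
         call. = FALSE)
  surv <- surv[idx, ]
  sd <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ group, rho = 0)
  chisq <- unname(sd$chisq)
  list(group = stats::setNames(group, names(scores)), threshold = thr,
       chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Refine a treatment-response signature
#'
#' Candidate genes must pass \code{|log2fc| > fc_min} and
#' \code{padj < padj_max} in both differential-expression lists; a
#' candidate is retained when its single-gene ROC AUC for treated versus
#' vehicle in the validation expression matrix reaches \code{auc_min}
#' (direction-agnostic: \code{max(AUC, 1 - AUC)}).
#'
#' @param deg_a,deg_b data.frames with columns \code{gene}, \code{log2fc},
#'   \code{padj}.
#' @param mat numeric genes x samples log2 matrix of the validation set.
#' @param treated binary vector (1 = treated) aligned with the columns of
#'   \code{mat}.
#' @param fc_min absolute log2 fold-change gate (default 10, the printed
#'   DEG rule; see the methods vignette for discussion).
#' @param padj_max adjusted p-value gate.
#' @param auc_min minimum direction-agnostic single-gene AUC.
#' @return character vector of retained genes (sorted; may be empty).
#' @export
refineSignature <- function(deg_a, deg_b, mat, treated, fc_min = 10,
                            padj_max = 0.05, auc_min = 0.9) {
  for (d in list(deg_a, deg_b))
    stopifnot(all(c("gene", "log2fc", "padj") %in% names(d)))
  pass <- function(d) d$gene[abs(d$log2fc) > fc_min & d$padj < padj_max]
  cand <- sort(intersect(pass(deg_a), pass(deg_b)))
  if (!length(cand)) return(character(0))
  missing_m <- setdiff(cand, rownames(mat))
  if (length(missing_m))
    stop("candidate gene(s) absent from matrix: ",
         paste(utils::head(missing_m, 5), collapse = ", "), call. = FALSE)
  keep <- vapply(cand, function(g) {
    auc <- rocAuc(mat[g, ], treated)
    max(auc, 1 - auc) >= auc_min
  }, logical(1))
  cand[keep]
}

#' Minimal per-group sample size for a two-sample t test
#'
#' Smallest integer n >= 2 per group such that an equal-n, pooled-variance
#' two-sample t test with \code{df = 2n - 2} and noncentrality
#' \code{d * sqrt(n / 2)} attains the target power at the stated alpha
#' (two-sided by default).  Found by incremental search on the noncentral t
#' distribution.
#'
#' @param effect_size standardized mean difference d (> 0).
#' @param alpha type-I error rate.
#' @param power target power (must exceed alpha).
#' @param two_sided two-sided test (default) or one-sided.
#' @param n_max search cap.
#' @return minimal per-group n (integer).
#' @examples
#' sampleSizeTTest(1.0)   # 17
#' sampleSizeTTest(2.5)   # 4
#' @export
sampleSizeTTest <- function(effect_size, alpha = 0.05, power = 0.80,
                            two_sided = TRUE, n_max = 1e6) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > alpha, power < 1)
  attained <- function(n) {
    df <- 2 * n - 2
    ncp <- effect_size * sqrt(n / 2)
    if (two_sided) {
      tc <- stats::qt(1 - alpha / 2, df)
      stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
    } else {
      stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
    }
  }
  n <- 2L
  while (n <= n_max) {
    if (attained(n) >= power) return(n)
    n <- n + 1L
  }
  stop("power not attainable within n_max", call. = FALSE)
}
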