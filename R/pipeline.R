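## End-to-end pipeline: threshold -> discretize -> filter -> discover ->
## cluster -> link -> (optional) paths and scores, with persisted artifacts
## and a JSON run manifest for reproducibility.

#' Run the full implication-network pipeline
#'
#' Executes thresholding, discretization, dynamic-range filtering,
#' implication discovery, equivalence clustering, inter-cluster linking and
#' (when a seed gene is given) Boolean path charting, plus composite
#' scoring when a signature is supplied.  All intermediate artifacts are
#' written to \code{out_dir} together with a manifest (inputs, parameters,
#' seed, package version) from which the run can be reproduced exactly.
#'
#' @param matrix_path TSV expression matrix (see
#'   \code{\link{readExpression}}), or a numeric matrix.
#' @param out_dir output directory (created if needed).
#' @param preset discovery preset, \code{"network"} or \code{"screen"}.
#' @param margin noise-margin half width (log2).
#' @param min_state_frac,min_percentile_range gene filter settings.
#' @param jaccard_min,sample_size,majority_frac,sampling cluster settings.
#' @param seed RNG seed for cluster-member sampling.
#' @param seed_gene optional gene whose cluster anchors path charting.
#' @param max_len maximum path length (edges).
#' @param signature optional \code{\link{signatureSpec}} (or GMT path plus
#'   \code{weights}) for composite scoring.
#' @param weights weights for a GMT-supplied signature.
#' @return invisibly, a list with the in-memory artifacts
#'   (\code{thresholds}, \code{states}, \code{kept}, \code{records},
#'   \code{bin}, \code{cbin}, \code{paths}, \code{scores}).
#' @export
runPipeline <- function(matrix_path, out_dir, preset = "network",
                        margin = 0.5, min_state_frac = 0.05,
                        min_percentile_range = 1.0, jaccard_min = 0.7,
                        sample_size = 6, majority_frac = 2 / 3,
                        sampling = "random", seed = 1, seed_gene = NULL,
                        max_len = 3, signature = NULL, weights = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  mat <- stage("read", {
    if (is.character(matrix_path)) readExpression(matrix_path)
    else .check_expression(matrix_path)
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- discoveryParams(preset)
  cpar <- clusterParams(jaccard_min = jaccard_min,
                        sample_size = sample_size,
                        majority_frac = majority_frac, rng_seed = seed,
                        sampling = sampling)

  thresholds <- stage("threshold", thresholdMatrix(mat, margin = margin))
  writeThresholds(thresholds, file.path(out_dir, "thresholds.tsv"))
  usable <- thresholds$gene_id[!thresholds$degenerate]
  sub <- mat[usable, , drop = FALSE]
  states <- stage("discretize", discretizeMatrix(sub, thresholds))
  kept <- stage("filter",
                filterGenes(sub, states, min_state_frac = min_state_frac,
                            min_percentile_range = min_percentile_range))
  records <- stage("implications", {
    if (length(kept) < 2L)
      data.frame(gene_a = character(), gene_b = character(),
                 relation = character())
    else discoverImplications(
      new("TrivalentMatrix",
          states = stateMatrix(states)[kept, , drop = FALSE]), params)
  })
  writeImplications(records, file.path(out_dir, "edges.tsv"))
  bin <- stage("network", buildBIN(records, genes = kept))
  cbin <- stage("cluster", clusterEquivalences(bin, cpar))
  cbin <- stage("link", linkClusters(cbin, bin, cpar))
  writeCBIN(cbin, file.path(out_dir, "cbin.json"))

  paths <- NULL
  if (!is.null(seed_gene)) {
    paths <- stage("paths", {
      cl <- geneClusters(cbin)
      hit <- names(cl)[vapply(cl, function(m) seed_gene %in% m, logical(1))]
      if (!length(hit))
        stop("seed gene ", seed_gene, " not in any cluster")
      chartPaths(cbin, hit[1], max_len = max_len)
    })
    jsonlite::write_json(paths, file.path(out_dir, "paths.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  scores <- NULL
  if (!is.null(signature)) {
    scores <- stage("score", {
      spec <- if (is.character(signature)) {
        sets <- readGeneSets(signature)
        signatureSpec(sets, weights)
      } else signature
      compositeScore(mat, thresholds, spec)
    })
    data.table::fwrite(
      data.frame(sample_id = names(scores), score = scores),
      file.path(out_dir, "scores.tsv"), sep = "\t")
  }
  manifest <- list(
    input = if (is.character(matrix_path)) matrix_path else "<in-memory>",
    n_genes = nrow(mat), n_samples = ncol(mat),
    preset = params$preset, s_min = params$s_min, p_max = params$p_max,
    margin = margin, min_state_frac = min_state_frac,
    min_percentile_range = min_percentile_range,
    jaccard_min = jaccard_min, sample_size = sample_size,
    majority_frac = majority_frac, sampling = sampling, seed = seed,
    seed_gene = seed_gene, max_len = max_len,
    package_version = as.character(utils::packageVersion("implinet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(thresholds = thresholds, states = states, kept = kept,
                 records = records, bin = bin, cbin = cbin, paths = paths,
                 scores = scores))
}
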