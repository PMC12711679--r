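#' @import methods
NULL

## Discrete state codes shared across the package.  MID samples fall inside
## the noise margin around a gene's step threshold and are ignored whenever
## quadrants are counted.
STATE_LOW <- 0L
STATE_MID <- 1L
STATE_HIGH <- 2L

## The six Boolean implication relation types plus NONE.  A directed record
## (a, b, LOW_LOW) reads "a low implies b low".
RELATION_TYPES <- c("LOW_LOW", "LOW_HIGH", "HIGH_HIGH", "HIGH_LOW",
                    "EQUIVALENT", "OPPOSITE", "NONE")
SYMMETRIC_TYPES <- c("EQUIVALENT", "OPPOSITE")
ASYMMETRIC_TYPES <- c("LOW_LOW", "LOW_HIGH", "HIGH_HIGH", "HIGH_LOW")

#' TrivalentMatrix: discretized expression states
#'
#' Holds the per-gene, per-sample discrete expression state obtained by
#' applying a step threshold with a symmetric noise margin: values above
#' threshold + margin are HIGH (2), below threshold - margin LOW (0), and
#' everything inside the band MID (1).  MID calls are excluded from all
#' downstream quadrant counting.
#'
#' @slot states integer matrix in \{0, 1, 2\} with gene rownames and sample
#'   colnames.
#' @export
setClass("TrivalentMatrix", representation(states = "matrix"))

setValidity("TrivalentMatrix", function(object) {
  st <- object@states
  if (is.null(rownames(st)) || is.null(colnames(st)))
    return("states must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(st)) || anyDuplicated(colnames(st)))
    return("duplicate gene or sample identifiers")
  if (!all(st %in% c(STATE_LOW, STATE_MID, STATE_HIGH)))
    return("states must be coded 0 (LOW), 1 (MID) or 2 (HIGH)")
  TRUE
})

#' BooleanNetwork: gene-level Boolean implication network
#'
#' A directed graph whose nodes are genes and whose edges carry one of the
#' six Boolean implication relation types.  Symmetric relations (EQUIVALENT,
#' OPPOSITE) are stored once per unordered pair with \code{gene_a < gene_b};
#' asymmetric relations are stored as directed records.
#'
#' @slot nodes character vector of gene identifiers (may include isolated
#'   genes).
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{relation} and optionally the supporting quadrant counts and
#'   statistics.
#' @export
setClass("BooleanNetwork",
         representation(nodes = "character", edges = "data.frame"))

setValidity("BooleanNetwork", function(object) {
  if (anyDuplicated(object@nodes)) return("duplicate node identifiers")
  ed <- object@edges
  need <- c("gene_a", "gene_b", "relation")
  if (!all(need %in% names(ed)))
    return("edges must have gene_a, gene_b, relation columns")
  if (nrow(ed)) {
    if (!all(ed$relation %in% setdiff(RELATION_TYPES, "NONE")))
      return("edge relation outside the six implication types")
    if (!all(c(ed$gene_a, ed$gene_b) %in% object@nodes))
      return("edge endpoint missing from node set")
    sym <- ed$relation %in% SYMMETRIC_TYPES
    if (any(sym) && any(ed$gene_a[sym] >= ed$gene_b[sym]))
      return("symmetric edges must be stored once with gene_a < gene_b")
  }
  TRUE
})

#' ClusteredBooleanNetwork: cluster-level implication network
#'
#' Obtained by collapsing equivalence-connected genes of a
#' \linkS4class{BooleanNetwork} into clusters (minimum spanning forest of the
#' equivalence subgraph, pruned at a Jaccard similarity cutoff) and linking
#' clusters by the majority relation between a representative gene and a
#' sample of the target cluster's members.
#'
#' @slot clusters named list of character vectors partitioning the gene set.
#' @slot representatives named character vector, one member gene per cluster.
#' @slot edges data.frame with columns \code{cluster_a}, \code{cluster_b},
#'   \code{relation}, \code{support} (agreeing sampled pairs) and
#'   \code{sampled} (pairs examined).
#' @export
setClass("ClusteredBooleanNetwork",
         representation(clusters = "list", representatives = "character",
                        edges = "data.frame"))

setValidity("ClusteredBooleanNetwork", function(object) {
  cl <- object@clusters
  if (is.null(names(cl)) || anyDuplicated(names(cl)))
    return("clusters must have unique names")
  members <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(members))
    return("clusters must be disjoint")
  reps <- object@representatives
  if (!identical(sort(names(reps)), sort(names(cl))))
    return("one representative per cluster required")
  ok <- vapply(names(cl), function(k) reps[[k]] %in% cl[[k]], logical(1))
  if (!all(ok)) return("each representative must belong to its cluster")
  need <- c("cluster_a", "cluster_b", "relation", "support", "sampled")
  if (!all(need %in% names(object@edges)))
    return("edges must have cluster_a, cluster_b, relation, support, sampled")
  TRUE
})

#' @describeIn TrivalentMatrix compact display
#' @param object a \code{TrivalentMatrix}
#' @export
setMethod("show", "TrivalentMatrix", function(object) {
  st <- object@states
  cat("TrivalentMatrix:", nrow(st), "genes x", ncol(st), "samples\n")
  tab <- table(factor(st, levels = 0:2, labels = c("LOW", "MID", "HIGH")))
  cat("  state calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @describeIn BooleanNetwork compact display
#' @param object a \code{BooleanNetwork}
#' @export
setMethod("show", "BooleanNetwork", function(object) {
  cat("BooleanNetwork:", length(object@nodes), "genes,",
      nrow(object@edges), "implication edges\n")
  if (nrow(object@edges)) {
    tab <- table(object@edges$relation)
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' @describeIn ClusteredBooleanNetwork compact display
#' @param object a \code{ClusteredBooleanNetwork}
#' @export
setMethod("show", "ClusteredBooleanNetwork", function(object) {
  sizes <- lengths(object@clusters)
  cat("ClusteredBooleanNetwork:", length(sizes), "clusters (sizes",
      paste(sizes, collapse = ","), "),", nrow(object@edges), "edges\n")
})
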