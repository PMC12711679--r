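## Assembly of the gene-level implication network, equivalence clustering
## (minimum spanning forest + Jaccard pruning) and cluster-level linking.

#' Clustering and linking parameters
#'
#' @param jaccard_min minimum Jaccard similarity for a spanning-forest edge
#'   to survive pruning (default 0.7: two cluster mates should share at
#'   least 70\% of their combined equivalence neighborhoods).
#' @param sample_size number of target-cluster members sampled when typing
#'   an inter-cluster edge (default 6).
#' @param majority_frac fraction of sampled pairs a single relation type
#'   must reach for an inter-cluster edge to be emitted (default 2/3).
#' @param rng_seed seed for the member sampling RNG.
#' @param sampling \code{"random"} (seeded, without replacement) or
#'   \code{"top-degree"} (deterministic: highest within-cluster equivalence
#'   degree first, ties lexicographic).
#' @return parameter list.
#' @export
clusterParams <- function(jaccard_min = 0.7, sample_size = 6,
                          majority_frac = 2 / 3, rng_seed = 1,
                          sampling = c("random", "top-degree")) {
  stopifnot(jaccard_min >= 0, jaccard_min <= 1, sample_size >= 1,
            majority_frac > 0.5, majority_frac <= 1)
  list(jaccard_min = jaccard_min, sample_size = sample_size,
       majority_frac = majority_frac, rng_seed = rng_seed,
       sampling = match.arg(sampling))
}

#' Assemble a Boolean implication network from discovered records
#'
#' Symmetric relations are canonicalized to \code{gene_a < gene_b};
#' asymmetric records given in both directions are kept if mutually
#' consistent (converse types).  Conflicting duplicate records raise an
#' error.
#'
#' @param records data.frame with at least \code{gene_a}, \code{gene_b},
#'   \code{relation} (as from \code{\link{discoverImplications}}).
#' @param genes optional character vector of genes to include as nodes even
#'   when isolated.
#' @return a \linkS4class{BooleanNetwork}.
#' @export
buildBIN <- function(records, genes = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(gene_a = character(), gene_b = character(),
                          relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_a", "gene_b", "relation") %in% names(records)))
  if (nrow(records) && !all(records$relation %in% RELATION_TYPES))
    stop("unknown relation type in records", call. = FALSE)
  records <- records[records$relation != "NONE", , drop = FALSE]
  ed <- records[, c("gene_a", "gene_b", "relation"), drop = FALSE]
  if (nrow(ed)) {
    if (any(ed$gene_a == ed$gene_b))
      stop("self-relation in records", call. = FALSE)
    sym <- ed$relation %in% SYMMETRIC_TYPES
    flip <- sym & ed$gene_a > ed$gene_b
    if (any(flip)) {
      tmp <- ed$gene_a[flip]
      ed$gene_a[flip] <- ed$gene_b[flip]
      ed$gene_b[flip] <- tmp
    }
    # canonical orientation for conflict checking: unordered pair plus the
    # relation read from the lexicographically smaller gene
    swap <- ed$gene_a > ed$gene_b
    canon_type <- ifelse(swap, unname(.converse[ed$relation]), ed$relation)
    pa <- ifelse(swap, ed$gene_b, ed$gene_a)
    pb <- ifelse(swap, ed$gene_a, ed$gene_b)
    key <- paste(pa, pb)
    for (k in unique(key[duplicated(key)])) {
      tys <- unique(canon_type[key == k])
      if (length(tys) > 1L)
        stop("conflicting relation records for pair ", k, call. = FALSE)
    }
    ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b, ed$relation)), ,
             drop = FALSE]
    ed <- ed[order(ed$gene_a, ed$gene_b, method = "radix"), , drop = FALSE]
    rownames(ed) <- NULL
  }
  nodes <- sort(unique(c(genes, ed$gene_a, ed$gene_b)))
  new("BooleanNetwork", nodes = nodes, edges = ed)
}

## Directed relation between two genes, derived from stored records.
.relation_between <- function(edges, u, v) {
  hit <- edges$gene_a == u & edges$gene_b == v
  if (any(hit)) return(edges$relation[which(hit)[1]])
  hit <- edges$gene_a == v & edges$gene_b == u
  if (any(hit)) return(unname(.converse[edges$relation[which(hit)[1]]]))
  "NONE"
}

## Adjacency list of the equivalence subgraph (closed neighborhoods built
## on demand by callers).
.equiv_adjacency <- function(bin) {
  ed <- binEdges(bin)
  ed <- ed[ed$relation == "EQUIVALENT", , drop = FALSE]
  adj <- stats::setNames(vector("list", length(binNodes(bin))), binNodes(bin))
  for (k in seq_len(nrow(ed))) {
    a <- ed$gene_a[k]; b <- ed$gene_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Jaccard similarity of two genes' equivalence neighborhoods
#'
#' Computed over closed neighborhoods (each gene's equivalence neighbors
#' plus the gene itself), so a mutually equivalent pendant pair scores 1.
#'
#' @param u,v distinct gene ids present in the network.
#' @param bin a \linkS4class{BooleanNetwork}.
#' @return similarity in [0, 1].
#' @export
jaccardSimilarity <- function(u, v, bin) {
  if (identical(u, v)) stop("u and v must differ", call. = FALSE)
  if (!all(c(u, v) %in% binNodes(bin)))
    stop("gene not in network", call. = FALSE)
  adj <- .equiv_adjacency(bin)
  nu <- union(adj[[u]], u)
  nv <- union(adj[[v]], v)
  length(intersect(nu, nv)) / length(union(nu, nv))
}

#' Cluster equivalent genes into network clusters
#'
#' Restricts the network to its equivalence subgraph, weights each edge by
#' one minus the Jaccard similarity of the closed equivalence neighborhoods
#' of its endpoints, builds a minimum spanning forest, deletes forest edges
#' whose Jaccard similarity falls below \code{jaccard_min}, and takes
#' connected components of what remains as clusters.  Genes without
#' equivalence edges become singletons.  The representative of a cluster is
#' the member with the most within-cluster equivalence edges (ties broken
#' lexicographically).  Edges are pre-sorted lexicographically so the forest
#' is deterministic under weight ties.
#'
#' @param bin a \linkS4class{BooleanNetwork}.
#' @param params list from \code{\link{clusterParams}}.
#' @return a \linkS4class{ClusteredBooleanNetwork} with no inter-cluster
#'   edges yet (see \code{\link{linkClusters}}).
#' @export
clusterEquivalences <- function(bin, params = clusterParams()) {
  nodes <- binNodes(bin)
  ed <- binEdges(bin)
  eq <- ed[ed$relation == "EQUIVALENT", , drop = FALSE]
  keep_edges <- NULL
  if (nrow(eq)) {
    eq <- eq[order(eq$gene_a, eq$gene_b, method = "radix"), , drop = FALSE]
    adj <- .equiv_adjacency(bin)
    closed <- lapply(stats::setNames(nodes, nodes),
                     function(g) union(adj[[g]], g))
    jac <- mapply(function(a, b) {
      na <- closed[[a]]; nb <- closed[[b]]
      length(intersect(na, nb)) / length(union(na, nb))
    }, eq$gene_a, eq$gene_b, USE.NAMES = FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = eq$gene_a, to = eq$gene_b, weight = 1 - jac),
      directed = FALSE, vertices = nodes)
    forest <- igraph::mst(g)
    fe <- igraph::as_data_frame(forest, what = "edges")
    # recover the jaccard of each forest edge and prune weak links
    key <- paste(pmin(eq$gene_a, eq$gene_b), pmax(eq$gene_a, eq$gene_b))
    fkey <- paste(pmin(fe$from, fe$to), pmax(fe$from, fe$to))
    fjac <- jac[match(fkey, key)]
    keep_edges <- fe[fjac >= params$jaccard_min, c("from", "to"), drop = FALSE]
  }
  gf <- igraph::graph_from_data_frame(
    if (is.null(keep_edges) || nrow(keep_edges) == 0L)
      data.frame(from = character(), to = character())
    else keep_edges,
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(gf)
  members <- split(names(comp$membership), comp$membership)
  # deterministic naming: order clusters by their smallest member
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1))]
  names(members) <- sprintf("C%02d", seq_along(members))
  # representative: most within-cluster equivalence edges, ties lexicographic
  adj <- .equiv_adjacency(bin)
  reps <- vapply(members, function(mem) {
    deg <- vapply(mem, function(g) sum(adj[[g]] %in% mem), integer(1))
    mem[order(-deg, mem)][1]
  }, character(1))
  new("ClusteredBooleanNetwork", clusters = members,
      representatives = reps,
      edges = data.frame(cluster_a = character(), cluster_b = character(),
                         relation = character(), support = integer(),
                         sampled = integer(), stringsAsFactors = FALSE))
}

#' Infer typed edges between clusters
#'
#' For every ordered cluster pair (A, B) the representative of A is compared
#' with \code{min(sample_size, |B|)} members of B (seeded random draw
#' without replacement, or the highest-equivalence-degree members under
#' \code{sampling = "top-degree"}).  The relation of each pair is read off
#' the stored gene-level records; a directed typed edge A -> B is emitted
#' iff a single non-NONE type accounts for at least \code{majority_frac} of
#' the sampled pairs.
#'
#' @param cbin clusters from \code{\link{clusterEquivalences}}.
#' @param bin the underlying \linkS4class{BooleanNetwork}.
#' @param params list from \code{\link{clusterParams}}.
#' @return the \linkS4class{ClusteredBooleanNetwork} with its edge table
#'   filled in (columns cluster_a, cluster_b, relation, support, sampled).
#' @export
linkClusters <- function(cbin, bin, params = clusterParams()) {
  clusters <- geneClusters(cbin)
  reps <- representatives(cbin)
  ed <- binEdges(bin)
  adj <- if (params$sampling == "top-degree") .equiv_adjacency(bin) else NULL
  set.seed(params$rng_seed)
  out <- list()
  ids <- names(clusters)
  for (a in ids) for (b in ids) {
    if (a == b) next
    mem <- clusters[[b]]
    k <- min(params$sample_size, length(mem))
    picked <- if (params$sampling == "random") {
      if (length(mem) == 1L) mem else sample(mem, k)
    } else {
      deg <- vapply(mem, function(g) sum(adj[[g]] %in% mem), integer(1))
      mem[order(-deg, mem)][seq_len(k)]
    }
    rels <- vapply(picked, function(m) .relation_between(ed, reps[[a]], m),
                   character(1))
    tab <- table(rels[rels != "NONE"])
    if (!length(tab)) next
    top <- which.max(tab)
    if (tab[top] >= params$majority_frac * k) {
      out[[length(out) + 1L]] <- data.frame(
        cluster_a = a, cluster_b = b, relation = names(tab)[top],
        support = as.integer(tab[top]), sampled = as.integer(k),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_a = character(), cluster_b = character(),
               relation = character(), support = integer(),
               sampled = integer(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  methods::initialize(cbin, edges = edges)
}

#' Chart Boolean paths through the cluster network
#'
#' Enumerates simple directed paths (no repeated cluster) that start at
#' \code{seed_cluster}, traverse only asymmetric implication edges, and are
#' at most \code{max_len} edges long; optionally only paths ending at
#' \code{end_cluster} are kept (the two-seed mode used to mine intermediate
#' states between a start and an end point of a differentiation
#' trajectory).  Paths are returned in deterministic lexicographic order of
#' their cluster sequence.
#'
#' @param cbin a linked \linkS4class{ClusteredBooleanNetwork}.
#' @param seed_cluster cluster id to start from.
#' @param end_cluster optional cluster id paths must end at.
#' @param max_len maximum number of edges per path.
#' @param weights optional named vector of +1/-1 per cluster (+1 for
#'   clusters elevated on the disease side); defaults to +1 everywhere.
#' @return list of paths; each path is a list with \code{clusters},
#'   \code{relations} (edge types along the path) and \code{weights}.
#' @export
chartPaths <- function(cbin, seed_cluster, end_cluster = NULL, max_len = 3,
                       weights = NULL) {
  clusters <- geneClusters(cbin)
  if (!seed_cluster %in% names(clusters))
    stop("unknown seed cluster: ", seed_cluster, call. = FALSE)
  if (!is.null(end_cluster) && !end_cluster %in% names(clusters))
    stop("unknown end cluster: ", end_cluster, call. = FALSE)
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(clusters)), names(clusters))
  ed <- clusterEdges(cbin)
  ed <- ed[ed$relation %in% ASYMMETRIC_TYPES, , drop = FALSE]
  ed <- ed[order(ed$cluster_a, ed$cluster_b, method = "radix"), , drop = FALSE]
  paths <- list()
  walk <- function(node, seq_cl, seq_rel) {
    if (length(seq_rel) > 0 &&
        (is.null(end_cluster) || node == end_cluster)) {
      paths[[length(paths) + 1L]] <<- list(
        clusters = seq_cl, relations = seq_rel,
        weights = unname(weights[seq_cl]))
    }
    if (length(seq_rel) >= max_len) return()
    nxt <- ed[ed$cluster_a == node & !(ed$cluster_b %in% seq_cl), ,
              drop = FALSE]
    for (k in seq_len(nrow(nxt)))
      walk(nxt$cluster_b[k], c(seq_cl, nxt$cluster_b[k]),
           c(seq_rel, nxt$relation[k]))
  }
  walk(seed_cluster, seed_cluster, character(0))
  paths
}
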