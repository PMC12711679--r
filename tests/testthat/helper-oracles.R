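# Independent brute-force oracles, kept deliberately naive and separate from
# the package's vectorized implementations.

# Exhaustive one-step scan: recompute segment means and SSE directly for
# every step position over the sorted series.
oracle_step <- function(values) {
  x <- sort(values)
  n <- length(x)
  best_k <- NA_integer_
  best_sse <- Inf
  for (k in 1:(n - 1)) {
    lm <- mean(x[1:k])
    hm <- mean(x[(k + 1):n])
    sse <- sum((x[1:k] - lm)^2) + sum((x[(k + 1):n] - hm)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_k <- k
    }
  }
  list(step_index = best_k, sse = best_sse)
}

# Direct evaluation of the quadrant equations for a single count table.
oracle_quad_stats <- function(a00, a01, a10, a11) {
  a00 <- unname(a00); a01 <- unname(a01)
  a10 <- unname(a10); a11 <- unname(a11)
  total <- a00 + a01 + a10 + a11
  row_m <- c(a00 + a01, a00 + a01, a10 + a11, a10 + a11)
  col_m <- c(a00 + a10, a01 + a11, a00 + a10, a01 + a11)
  a <- c(a00, a01, a10, a11)
  nhat <- (row_m / total) * (col_m / total) * total
  list(S = (nhat - a) / sqrt(nhat),
       p = 0.5 * (a / row_m + a / col_m),
       expected = nhat)
}

# All quadrant 4-tuples with entries 0..10 and valid marginals.
oracle_count_grid <- function(max_count = 10) {
  g <- expand.grid(a00 = 0:max_count, a01 = 0:max_count,
                   a10 = 0:max_count, a11 = 0:max_count)
  ok <- (g$a00 + g$a01) > 0 & (g$a10 + g$a11) > 0 &
    (g$a00 + g$a10) > 0 & (g$a01 + g$a11) > 0
  g[ok, , drop = FALSE]
}

# Reference relation classifier written straight from the sparse-pattern
# definition (no shared code with the package's vectorized classifier).
oracle_classify <- function(a00, a01, a10, a11, s_min, p_max) {
  st <- oracle_quad_stats(a00, a01, a10, a11)
  sparse <- st$S > s_min & st$p < p_max   # order: q00, q01, q10, q11
  ns <- sum(sparse)
  if (ns == 2 && sparse[2] && sparse[3]) return("EQUIVALENT")
  if (ns == 2 && sparse[1] && sparse[4]) return("OPPOSITE")
  if (ns == 1) {
    return(c("LOW_HIGH", "LOW_LOW", "HIGH_HIGH", "HIGH_LOW")[which(sparse)])
  }
  "NONE"
}

# Brute-force enumeration of simple directed paths from a seed over a typed
# edge list (data.frame cluster_a, cluster_b, relation).
oracle_paths <- function(edges, seed, max_len, end = NULL) {
  out <- list()
  recurse <- function(path) {
    node <- path[length(path)]
    if (length(path) > 1 && (is.null(end) || node == end))
      out[[length(out) + 1]] <<- path
    if (length(path) - 1 >= max_len) return()
    nxt <- sort(edges$cluster_b[edges$cluster_a == node &
                                  !(edges$cluster_b %in% path)])
    for (v in nxt) recurse(c(path, v))
  }
  recurse(seed)
  out
}

# Small planted dataset used by several suites: a chain DAG with
# alternating edge types over however many clusters are requested.
tiny_planted <- function(seed = 1, n = 500, sizes = c(10, 10, 10)) {
  k <- length(sizes)
  dag <- if (k < 2) {
    data.frame(from = integer(), to = integer(), type = character())
  } else {
    data.frame(from = 1:(k - 1), to = 2:k,
               type = rep(c("HIGH_HIGH", "HIGH_LOW"), length.out = k - 1),
               stringsAsFactors = FALSE)
  }
  generateDataset(simConfig(n_samples = n, cluster_sizes = sizes, dag = dag,
                            seed = seed))
}

# Threshold/discretize/filter/discover at a preset, returning all stages.
run_discovery <- function(mat, preset = "network") {
  thr <- thresholdMatrix(mat)
  usable <- thr$gene_id[!thr$degenerate]
  sub <- mat[usable, , drop = FALSE]
  states <- discretizeMatrix(sub, thr)
  kept <- filterGenes(sub, states)
  recs <- if (length(kept) >= 2) {
    discoverImplications(
      new("TrivalentMatrix",
          states = stateMatrix(states)[kept, , drop = FALSE]),
      discoveryParams(preset))
  } else {
    data.frame(gene_a = character(), gene_b = character(),
               relation = character())
  }
  list(thresholds = thr, states = states, kept = kept, records = recs)
}
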