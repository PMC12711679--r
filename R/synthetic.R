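## Synthetic data with planted Boolean-implication structure.
##
## Latent binary states are sampled per cluster per sample: root clusters
## draw Bernoulli(frac_high); each edge of the planted DAG forces the child
## state whenever its trigger fires (HIGH_HIGH: parent high forces child
## high, HIGH_LOW: parent high forces child low, LOW_LOW: parent low forces
## child low, LOW_HIGH: parent low forces child high), so every planted
## implication holds with zero latent violations.  Unforced samples draw
## from a free probability that is re-balanced toward frac_high given the
## realized forced counts, then clipped to [leak, 1 - leak]: the leak floor
## guarantees the relation stays a strict implication (never a hidden
## equivalence) and keeps the populated quadrants detectably non-sparse.
## Gene values are the state mean plus Gaussian log2 noise; members of the
## same cluster share the latent state and are therefore planted
## equivalents.

#' Simulation configuration
#'
#' Defaults describe a well-separated log2 bimodal world: modes 4 and 8
#' (16-fold apart), within-state noise SD 0.2, noise-margin clearance far
#' beyond 3 SD, and a 3-cluster chain (high => high, high => low) of 10
#' genes each observed in 500 samples — the scale at which Boolean
#' implication discovery at the stringent network preset is reliable.
#'
#' @param n_samples number of samples.
#' @param cluster_sizes genes per planted cluster.
#' @param dag data.frame with columns \code{from}, \code{to} (cluster
#'   indices) and \code{type} (asymmetric relation); must be acyclic.
#' @param mu_low,mu_high log2 segment means of the two states.
#' @param sigma within-state noise SD (log2).
#' @param mid_gap required clearance between each mode +/- 3 sigma and the
#'   noise band edge; violated configurations are rejected when sigma > 0.
#' @param frac_high marginal probability that a root cluster is high.
#' @param leak clipping floor/ceiling for the free-draw probability of
#'   constrained clusters (see the methods vignette for the detectability
#'   analysis behind the default 0.13).
#' @param n_responders extra treatment-responsive genes appended to the
#'   matrix (independent bimodal baseline shifted by
#'   \code{treatment_effect} in treated samples).
#' @param n_noise extra independent bimodal genes with no planted structure.
#' @param treatment_effect log2 shift added to responder genes of treated
#'   samples.
#' @param frac_treated probability a sample is treated.
#' @param surv_base_rate exponential event rate for the low survival group.
#' @param surv_log_hr log hazard ratio of the high group (first planted
#'   cluster defines the true group).
#' @param censor_rate target fraction of administratively censored samples.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return validated configuration list.
#' @export
simConfig <- function(n_samples = 500,
                      cluster_sizes = c(10, 10, 10),
                      dag = data.frame(from = c(1, 2), to = c(2, 3),
                                       type = c("HIGH_HIGH", "HIGH_LOW")),
                      mu_low = 4, mu_high = 8, sigma = 0.2, mid_gap = 0.5,
                      frac_high = 0.5, leak = 0.13,
                      n_responders = 0, n_noise = 0, treatment_effect = 2,
                      frac_treated = 0.5, surv_base_rate = 0.1,
                      surv_log_hr = 0, censor_rate = 0.2, seed = 1) {
  stopifnot(n_samples >= 1, all(cluster_sizes >= 1), mu_high > mu_low,
            sigma >= 0, frac_high > 0, frac_high < 1,
            leak > 0, leak < 0.5, surv_base_rate > 0,
            censor_rate >= 0, censor_rate < 1,
            frac_treated >= 0, frac_treated <= 1)
  if (nrow(dag)) {
    stopifnot(all(c("from", "to", "type") %in% names(dag)))
    if (!all(dag$type %in% ASYMMETRIC_TYPES))
      stop("dag edge types must be asymmetric implication types",
           call. = FALSE)
    k <- length(cluster_sizes)
    if (any(dag$from < 1 | dag$from > k | dag$to < 1 | dag$to > k))
      stop("dag refers to unknown cluster index", call. = FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = dag$from, to = dag$to), directed = TRUE,
      vertices = data.frame(name = seq_len(k)))
    if (!igraph::is_dag(g))
      stop("planted dag must be acyclic", call. = FALSE)
  }
  if (sigma > 0) {
    clearance <- (mu_high - mu_low) / 2 - 0.5 - 3 * sigma
    if (clearance < mid_gap)
      stop("modes too close: mode +/- 3 sigma must clear the noise band by ",
           mid_gap, " log2 units", call. = FALSE)
  }
  list(n_samples = n_samples, cluster_sizes = cluster_sizes, dag = dag,
       mu_low = mu_low, mu_high = mu_high, sigma = sigma, mid_gap = mid_gap,
       frac_high = frac_high, leak = leak, n_responders = n_responders,
       n_noise = n_noise, treatment_effect = treatment_effect,
       frac_treated = frac_treated, surv_base_rate = surv_base_rate,
       surv_log_hr = surv_log_hr, censor_rate = censor_rate, seed = seed)
}

## Uniform administrative censoring horizon giving the target censoring
## probability against an exponential(rate) event time:
## P(C < E) = (1 - exp(-rate T)) / (rate T) for C ~ Unif(0, T).
.censor_horizon <- function(rate, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(T) (1 - exp(-rate * T)) / (rate * T) - censor_rate
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a dataset with planted implication structure
#'
#' @param cfg configuration from \code{\link{simConfig}}.
#' @return list with \code{expr} (genes x samples log2 matrix),
#'   \code{truth} (latent cluster states, gene-to-cluster map, planted
#'   relations, responder genes, true survival group), \code{labels}
#'   (data.frame sample_id, treated) and \code{survival} (data.frame
#'   sample_id, time, event).
#' @export
generateDataset <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  k <- length(cfg$cluster_sizes)
  samples <- sprintf("s%04d", seq_len(n))
  # topological order of the planted DAG
  topo <- if (nrow(cfg$dag)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = cfg$dag$from, to = cfg$dag$to), directed = TRUE,
      vertices = data.frame(name = seq_len(k)))
    as.integer(igraph::topo_sort(g, mode = "out")$name)
  } else seq_len(k)
  latent <- matrix(NA_integer_, k, n)
  for (cl in topo) {
    inc <- cfg$dag[cfg$dag$to == cl, , drop = FALSE]
    force_high <- force_low <- rep(FALSE, n)
    for (e in seq_len(nrow(inc))) {
      p <- latent[inc$from[e], ]
      switch(inc$type[e],
             HIGH_HIGH = { force_high <- force_high | p == 1L },
             HIGH_LOW  = { force_low  <- force_low  | p == 1L },
             LOW_LOW   = { force_low  <- force_low  | p == 0L },
             LOW_HIGH  = { force_high <- force_high | p == 0L })
    }
    if (any(force_high & force_low))
      stop("infeasible dag: contradictory constraints on cluster ", cl,
           call. = FALSE)
    st <- integer(n)
    st[force_high] <- 1L
    free <- !(force_high | force_low)
    if (any(free)) {
      p_free <- (cfg$frac_high * n - sum(force_high)) / sum(free)
      p_free <- min(max(p_free, cfg$leak), 1 - cfg$leak)
      st[free] <- stats::rbinom(sum(free), 1, p_free)
    }
    latent[cl, ] <- st
  }
  gene_cluster <- rep(seq_len(k), cfg$cluster_sizes)
  genes <- sprintf("g%03d", seq_along(gene_cluster))
  mu <- ifelse(latent[gene_cluster, , drop = FALSE] == 1L,
               cfg$mu_high, cfg$mu_low)
  expr <- mu + stats::rnorm(length(mu), 0, cfg$sigma)
  dim(expr) <- dim(mu)
  # treatment labels and responder genes
  treated <- stats::rbinom(n, 1, cfg$frac_treated)
  responders <- character(0)
  extra <- NULL
  if (cfg$n_responders > 0) {
    responders <- sprintf("r%03d", seq_len(cfg$n_responders))
    rs <- matrix(stats::rbinom(cfg$n_responders * n, 1, 0.5),
                 cfg$n_responders, n)
    re <- ifelse(rs == 1L, cfg$mu_high, cfg$mu_low) +
      stats::rnorm(cfg$n_responders * n, 0, cfg$sigma)
    re <- re + cfg$treatment_effect * rep(treated, each = cfg$n_responders)
    extra <- rbind(extra, re)
  }
  noise_genes <- character(0)
  if (cfg$n_noise > 0) {
    noise_genes <- sprintf("x%03d", seq_len(cfg$n_noise))
    ns <- matrix(stats::rbinom(cfg$n_noise * n, 1, cfg$frac_high),
                 cfg$n_noise, n)
    ne <- ifelse(ns == 1L, cfg$mu_high, cfg$mu_low) +
      stats::rnorm(cfg$n_noise * n, 0, cfg$sigma)
    extra <- rbind(extra, ne)
  }
  expr <- rbind(expr, extra)
  rownames(expr) <- c(genes, responders, noise_genes)
  colnames(expr) <- samples
  # survival coupled to the first planted cluster's latent state
  group <- latent[1, ]
  rate <- cfg$surv_base_rate * exp(cfg$surv_log_hr * group)
  etime <- stats::rexp(n, rate)
  horizon <- .censor_horizon(cfg$surv_base_rate, cfg$censor_rate)
  ctime <- if (is.finite(horizon)) stats::runif(n, 0, horizon) else
    rep(Inf, n)
  time <- pmin(etime, ctime)
  event <- as.integer(etime <= ctime)
  rownames(latent) <- sprintf("C%02d", seq_len(k))
  list(
    expr = expr,
    truth = list(
      latent = `colnames<-`(latent, samples),
      gene_cluster = stats::setNames(gene_cluster, genes),
      dag = cfg$dag,
      responders = responders,
      noise_genes = noise_genes,
      surv_group = stats::setNames(group, samples),
      config = cfg),
    labels = data.frame(sample_id = samples, treated = treated,
                        stringsAsFactors = FALSE),
    survival = data.frame(sample_id = samples, time = time, event = event,
                          stringsAsFactors = FALSE))
}

#' Null dataset: independent bimodal genes
#'
#' Every gene draws an independent latent state per sample, so no
#' implication structure exists beyond chance.
#'
#' @param n_samples,n_genes dimensions.
#' @param seed RNG seed.
#' @param frac_high marginal probability of the high state.
#' @param mu_low,mu_high,sigma log2 mixture parameters.
#' @return genes x samples log2 matrix.
#' @export
nullDataset <- function(n_samples, n_genes, seed = 1, frac_high = 0.5,
                        mu_low = 4, mu_high = 8, sigma = 0.2) {
  stopifnot(n_samples >= 1, n_genes >= 1)
  set.seed(seed)
  st <- matrix(stats::rbinom(n_genes * n_samples, 1, frac_high),
               n_genes, n_samples)
  expr <- ifelse(st == 1L, mu_high, mu_low) +
    stats::rnorm(n_genes * n_samples, 0, sigma)
  dimnames(expr) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%04d", seq_len(n_samples)))
  expr
}
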