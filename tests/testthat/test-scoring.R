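toy_thresholds <- function(genes, threshold = 2, stddev = 1) {
  data.frame(gene_id = genes, threshold = threshold, margin = 0.5,
             stddev = stddev, degenerate = FALSE, stringsAsFactors = FALSE)
}

test_that("compositeScore evaluates the threshold-normalized formula", {
  m <- matrix(c(2, 3.5, 0.5), 1, dimnames = list("g1", c("s1", "s2", "s3")))
  thr <- toy_thresholds("g1")
  spec <- signatureSpec(list("g1"), 1)
  sc <- compositeScore(m, thr, spec)
  expect_equal(unname(sc), c(0, 0.5, -0.5))
  expect_identical(names(sc), c("s1", "s2", "s3"))
})

test_that("compositeScore averages within clusters and weights across", {
  m <- rbind(g1 = c(2, 5), g2 = c(8, 2), g3 = c(5, 5))
  colnames(m) <- c("s1", "s2")
  thr <- toy_thresholds(rownames(m))
  spec <- signatureSpec(list(c("g1", "g2"), "g3"), c(1, -1))
  sc <- compositeScore(m, thr, spec)
  manual <- colMeans((m[c("g1", "g2"), ] - 2) / 3) - (m["g3", ] - 2) / 3
  expect_equal(unname(sc), unname(manual))
})

test_that("negating weights negates scores exactly", {
  d <- tiny_planted(seed = 71, n = 60, sizes = c(4, 4))
  thr <- thresholdMatrix(d$expr)
  cl <- split(names(d$truth$gene_cluster), d$truth$gene_cluster)
  plus <- compositeScore(d$expr, thr, signatureSpec(cl, c(1, -1)))
  minus <- compositeScore(d$expr, thr, signatureSpec(cl, c(-1, 1)))
  expect_equal(plus, -minus)
})

test_that("composite z is invariant under a matched shift", {
  m <- rbind(g1 = c(2, 5, 7, 1), g2 = c(4, 4, 8, 8))
  colnames(m) <- paste0("s", 1:4)
  thr <- toy_thresholds(rownames(m), threshold = c(3, 5), stddev = c(1, 2))
  spec <- signatureSpec(list(c("g1", "g2")), 1)
  base <- compositeScore(m, thr, spec)
  m2 <- m; m2["g1", ] <- m2["g1", ] + 4
  thr2 <- thr; thr2$threshold[1] <- thr2$threshold[1] + 4
  expect_equal(compositeScore(m2, thr2, spec), base)
})

test_that("compositeScore rejects missing or degenerate genes", {
  m <- matrix(1:4, 1, dimnames = list("g1", paste0("s", 1:4)))
  storage.mode(m) <- "numeric"
  thr <- toy_thresholds("g1")
  expect_error(compositeScore(m, thr, signatureSpec(list("g9"), 1)),
               "absent")
  thr$stddev <- 0
  expect_error(compositeScore(m, thr, signatureSpec(list("g1"), 1)),
               "stddev")
  expect_error(signatureSpec(list(character(0)), 1), "empty")
  expect_error(signatureSpec(list("g1"), 2), "\\+1 or -1")
})

test_that("orderSamples sorts ascending with stable ties", {
  sc <- c(s1 = 0.3, s2 = -1, s3 = 2)
  expect_identical(orderSamples(sc), c("s2", "s1", "s3"))
  tied <- c(a = 1, b = 1, c = 1)
  expect_identical(orderSamples(tied), c("a", "b", "c"))
  set.seed(5)
  r <- setNames(rnorm(50), paste0("s", 1:50))
  expect_identical(orderSamples(r), names(sort(r)))
})

test_that("rocAuc equals the Mann-Whitney probability", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(1, 3, 2, 4), c(1, 1, 0, 0)), 0.25)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(8)
  for (i in 1:20) {
    sc <- rnorm(30)
    lb <- rbinom(30, 1, 0.5)
    if (sum(lb) %in% c(0, 30)) next
    w <- wilcox.test(sc[lb == 1], sc[lb == 0], exact = FALSE)$statistic
    expect_equal(rocAuc(sc, lb), unname(w) / (sum(lb) * sum(!lb)))
    expect_equal(rocAuc(-sc, lb), 1 - rocAuc(sc, lb))
  }
})

test_that("stratifySurvival is exact on identical groups and validates", {
  sc <- setNames(c(0, 0, 0, 10, 10, 10), paste0("s", 1:6))
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     time = c(1, 2, 3, 1, 2, 3),
                     event = c(1, 1, 0, 1, 1, 0))
  res <- stratifySurvival(sc, surv)
  expect_equal(res$chisq, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_identical(unname(res$group), rep(c("low", "high"), each = 3))
  expect_error(stratifySurvival(setNames(rep(1, 6), paste0("s", 1:6)), surv),
               "constant")
  expect_error(stratifySurvival(setNames(1:3 * 1.0, paste0("x", 1:3)), surv),
               "missing")
  # time-zero events are kept, not dropped
  surv0 <- surv; surv0$time[1] <- 0
  expect_no_error(stratifySurvival(sc, surv0))
})

test_that("log-rank is label-symmetric and p uniform under the null", {
  set.seed(33)
  sc <- setNames(c(rnorm(40, 0), rnorm(40, 3)), sprintf("s%02d", 1:80))
  surv <- data.frame(sample_id = sprintf("s%02d", 1:80),
                     time = rexp(80, 0.1), event = rbinom(80, 1, 0.8))
  res <- stratifySurvival(sc, surv)
  flipped <- stratifySurvival(-sc, surv)
  expect_equal(res$chisq, flipped$chisq, tolerance = 1e-6)
  ps <- replicate(500, {
    perm <- surv
    idx <- sample(nrow(surv))
    perm$time <- surv$time[idx]; perm$event <- surv$event[idx]
    stratifySurvival(sc, perm)$p_value
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.1)
})

test_that("refineSignature keeps exactly the planted responders", {
  d <- generateDataset(simConfig(n_samples = 120, cluster_sizes = c(5, 5),
                                 dag = data.frame(from = 1, to = 2,
                                                  type = "HIGH_HIGH"),
                                 n_responders = 10, n_noise = 30,
                                 treatment_effect = 6, seed = 12))
  resp <- d$truth$responders
  nulls <- d$truth$noise_genes
  deg <- function(jitter) {
    data.frame(
      gene = c(resp, nulls),
      log2fc = c(rep(12, length(resp)) + jitter,
                 runif(length(nulls), -1, 1)),
      padj = c(rep(1e-6, length(resp)), runif(length(nulls), 0.2, 1)),
      stringsAsFactors = FALSE)
  }
  set.seed(9)
  got <- refineSignature(deg(0.1), deg(-0.1), d$expr, d$labels$treated)
  expect_identical(got, sort(resp))
  # failing the padj gate in one list excludes a gene
  da <- deg(0); da$padj[1] <- 0.5
  got2 <- refineSignature(da, deg(0), d$expr, d$labels$treated)
  expect_identical(got2, sort(resp[-1]))
  # empty candidate set is allowed
  empty <- refineSignature(deg(0), deg(0), d$expr, d$labels$treated,
                           fc_min = 100)
  expect_identical(empty, character(0))
})

test_that("sampleSizeTTest reproduces the noncentral-t oracle", {
  # independent continuous-n solver as oracle on a d grid
  for (d in c(0.3, 0.5, 0.8, 1.0, 1.5, 2.5)) {
    oracle <- ceiling(power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                   power = 0.8)$n - 1e-9)
    expect_identical(sampleSizeTTest(d), as.integer(oracle))
  }
  expect_identical(sampleSizeTTest(0.5), 64L)
  # monotonicity: non-increasing in d, non-decreasing in power
  ns_d <- vapply(seq(0.4, 2.4, by = 0.4), sampleSizeTTest, integer(1))
  expect_true(all(diff(ns_d) <= 0))
  ns_p <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95),
                 function(p) sampleSizeTTest(1, power = p), integer(1))
  expect_true(all(diff(ns_p) >= 0))
  expect_error(sampleSizeTTest(-1), "effect_size")
})
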