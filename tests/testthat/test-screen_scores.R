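test_that("Poisson-Gamma posterior matches its closed forms and limits", {
  fp <- frequency_posterior(0, 1000)
  expect_equal(fp$mean_f, 1 / (1000 * 1.001))
  # posterior mean of lambda for c = 4: (alpha + c)/(1 + beta) = 5/1.001
  fp4 <- frequency_posterior(4, 1000)
  expect_equal(fp4$mean_lambda, 5 / 1.001)
  # alpha -> 0, beta = 0 limit: empirical frequency
  fp0 <- frequency_posterior(17, 500, alpha = 1e-12, beta = 0)
  expect_equal(fp0$mean_f, 17 / 500, tolerance = 1e-12)
  # closed form vs numerical integration of the Gamma density
  for (cc in c(0, 3, 50)) {
    f <- frequency_posterior(cc, 2000)
    num <- stats::integrate(function(l)
      l * stats::dgamma(l, shape = f$shape, rate = f$rate),
      0, Inf, rel.tol = 1e-12)$value / 2000
    expect_equal(f$mean_f, num, tolerance = 1e-10)
  }
  draws <- with_seed(3, draw_frequency(frequency_posterior(10, 1000),
                                       5000))
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 11 / (1000 * 1.001), tolerance = 0.01)
})

test_that("sort-seq scores are anchored and arithmetically correct", {
  # 4 bins, equal frequencies and equal cells: raw weighted mean bin 2.5
  reads <- rep(1e4, 4); cells <- rep(2500, 4)
  raw <- sortseq_raw(rep(2500, 4), reads, cells)
  expect_equal(raw, 2.5)
  # variant with the null's distribution scores 0; WT-like scores 1
  wt_counts <- c(0, 100, 800, 100); null_counts <- c(900, 100, 0, 0)
  raw_wt <- sortseq_raw(wt_counts, reads, cells)
  raw_null <- sortseq_raw(null_counts, reads, cells)
  s_null <- sortseq_score(null_counts, reads, cells, raw_wt, raw_null,
                          seed = 1)
  s_wt <- sortseq_score(wt_counts, reads, cells, raw_wt, raw_null,
                        seed = 2)
  expect_equal(s_null$score, 0)
  expect_equal(s_wt$score, 1)
  expect_gt(s_wt$error, 0)
  expect_error(sortseq_score(wt_counts, reads, cells, 2.5, 2.5),
               "degenerate")
})

test_that("random-effects merging matches its closed form and metafor", {
  # identical replicates pass through with zero between-replicate variance
  m <- merge_replicates(c(0.4, 0.4, 0.4), c(0.1, 0.1, 0.1))
  expect_equal(m$score, 0.4)
  expect_equal(m$tau2, 0)
  # two replicates (0, 1) with equal errors: mean 0.5, inflated error
  m2 <- merge_replicates(c(0, 1), c(0.1, 0.1))
  expect_equal(m2$score, 0.5)
  # DerSimonian-Laird by hand: w = 100 each, Q = 50, C = 100
  expect_equal(m2$tau2, (50 - 1) / 100)
  expect_equal(m2$error, sqrt(1 / (2 / (0.01 + 0.49))))
  expect_gt(m2$error, 0.1 / sqrt(2))
  # a wildly uncertain replicate barely moves the combination
  m3 <- merge_replicates(c(0.2, 5), c(0.01, 100))
  expect_equal(m3$score, 0.2, tolerance = 1e-3)
  # single replicate passes through
  m1 <- merge_replicates(0.7, 0.2)
  expect_equal(m1$score, 0.7)
  expect_equal(m1$error, 0.2)

  skip_if_not_installed("metafor")
  sc <- c(0.1, 0.5, 0.3, 0.9); se <- c(0.05, 0.2, 0.1, 0.3)
  mine <- merge_replicates(sc, se)
  rma <- metafor::rma(yi = sc, sei = se, method = "DL")
  expect_equal(mine$score, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(mine$error, rma$se, tolerance = 1e-8)
  expect_equal(mine$tau2, rma$tau2, tolerance = 1e-8)
})

test_that("log enrichment respects thresholds and the zero identity", {
  flat <- data.frame(
    variant = rep(c("a", "b"), each = 2),
    rep = rep(1:2, 2),
    pre = c(500, 500, 1500, 1500),
    post = c(500, 500, 1500, 1500))
  # pre and post frequencies identical: enrichment exactly 0
  le <- log_enrichment(flat, pre_threshold = 0, seed = 5)
  expect_equal(le$score, c(0, 0))
  counts <- data.frame(
    variant = rep(c("a", "b"), each = 2),
    rep = rep(1:2, 2),
    pre = c(500, 500, 10, 2000),
    post = c(500, 500, 900, 4000))
  # replicate below the pre-count threshold is dropped
  le2 <- log_enrichment(counts, pre_threshold = 50, seed = 5)
  expect_equal(le2$n_rep[le2$variant == "b"], 1L)
  # all replicates below threshold: missing, not zero
  le3 <- log_enrichment(counts, pre_threshold = 5000, seed = 5)
  expect_true(all(is.na(le3$score)))
  expect_true(all(le3$n_rep == 0L))
  expect_error(log_enrichment(counts, pre_threshold = -1), "threshold")
})

test_that("errors-in-variables merge is exact on clean data and unbiased", {
  n <- 60
  x <- seq(0, 1, length.out = n)
  A <- data.frame(variant = paste0("v", 1:n), score = x, se = 0.01)
  B <- data.frame(variant = paste0("v", 1:n), score = 2 * x + 1,
                  se = 0.01)
  om <- odr_merge(A, B, error_thresholds = c(1, 1))
  expect_equal(om$fit$m, 2, tolerance = 1e-4)
  expect_equal(om$fit$b, 1, tolerance = 1e-4)
  # rescaled-and-merged table returns to table A's scale
  expect_equal(om$merged$score[match("v1", om$merged$variant)], x[1],
               tolerance = 1e-3)
  # identical tables: slope 1, intercept 0
  om2 <- odr_merge(A, A, error_thresholds = c(1, 1))
  expect_equal(om2$fit$m, 1, tolerance = 1e-4)
  expect_equal(om2$fit$b, 0, tolerance = 1e-4)
  expect_error(odr_merge(A[1:2, ], B[1:2, ], c(1, 1)), "overlapping")
  # error filters drop noisy points before the regression
  A$se[1:10] <- 10
  om3 <- odr_merge(A, B, error_thresholds = c(0.15, 0.15))
  expect_equal(om3$fit$n, n - 10)
})

test_that("hit calling reproduces brute-force Benjamini-Hochberg", {
  # step-up definition computed directly
  bh_brute <- function(p) {
    m <- length(p); o <- order(p)
    adj <- numeric(m)
    prev <- Inf
    for (k in m:1) {
      prev <- min(prev, m * p[o[k]] / k)
      adj[o[k]] <- min(1, prev)
    }
    adj
  }
  p_toy <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(stats::p.adjust(p_toy, "BH"), bh_brute(p_toy))
  for (i in 1:5) {
    p <- with_seed(i, stats::runif(50)^2)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p))
  }
  # a variant at the null mean is not significant and has p ~ 0.5
  null_scores <- with_seed(7, stats::rnorm(50, 0, 0.1))
  hits <- call_hits(c(mean(null_scores), 1.5), c(0.01, 0.01),
                    null_scores, variants = c("atnull", "high"))
  expect_equal(hits$p[1], 0.5, tolerance = 0.01)
  expect_false(hits$significant[1])
  expect_true(hits$significant[2])
  expect_error(call_hits(1, 0.1, c(0, 0.1)), "null observations")
})

test_that("sort-seq pipeline recovers planted scores end to end", {
  tr <- random_landscape(n_mutations = 30, effect_sd = 2.5,
                         effect_mean = -0.5, noise_sd = 0.05, seed = 41)
  vs <- unique(c("WT", "null", names(tr$beta)[1:20],
                 with_seed(42, replicate(40, paste(
                   sample(names(tr$beta), 2), collapse = "+")))))
  sim <- simulate_sortseq_counts(
    tr, vs, sortsim_config(cells_per_variant = 500,
                           reads_per_bin = 5e4),
    replicates = 2, seed = 43)
  st <- score_sortseq_table(sim$counts, sim$cells, seed = 44)
  m <- merge(st, sim$truth, by = "variant")
  expect_gt(stats::cor(m$score, m$score_true, method = "spearman"), 0.9)
  expect_equal(st$score[st$variant == "WT"], 1)
  expect_equal(st$score[st$variant == "null"], 0)
})
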