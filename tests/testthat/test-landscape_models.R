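test_that("design matrix construction tokenizes and excludes correctly", {
  st <- data.frame(variant = c("WT", "M230A", "E134N", "E134N+M230A"),
                   score = c(1, 0.5, 0.8, 0.2), se = 0.05)
  gm <- build_design_matrix(st)
  expect_equal(ncol(gm$X), 2L)
  expect_equal(unname(rowSums(gm$X)), c(0, 1, 1, 2))
  expect_setequal(gm$vocabulary, c("M230A", "E134N"))

  # frameshift-bearing variants are excluded with a reason
  st2 <- rbind(st, data.frame(variant = "fs3", score = 0, se = 0.05))
  gm2 <- build_design_matrix(st2)
  expect_equal(nrow(gm2$X), 4L)
  expect_equal(gm2$excluded$variant, "fs3")

  # generator bookkeeping: all features appear, no empty columns
  ad <- additive_score_table(n_singles = 50, n_doubles = 400, seed = 3)
  gm3 <- build_design_matrix(ad$table)
  expect_equal(ncol(gm3$X), 50L)
  expect_true(all(colSums(gm3$X) > 0))
})

test_that("identity-link fit reproduces ordinary least squares", {
  ad <- additive_score_table(n_singles = 12, n_doubles = 50,
                             noise_sd = 0.02, seed = 7)
  gm <- build_design_matrix(ad$table)
  fit <- fit_global_epistasis(gm, link = "identity", prior_sd = 1e3)
  ols <- stats::lm(ad$table$score ~ gm$X)
  expect_equal(unname(fit$beta),
               unname(stats::coef(ols)[-1]), tolerance = 1e-3)
  expect_equal(fit$beta0, unname(stats::coef(ols)[1]), tolerance = 1e-3)
  # constant scores: flat landscape, intercept at the constant
  stc <- data.frame(variant = c("WT", "M230A", "E134N", "E134N+M230A"),
                    score = 0.42, se = 0.05)
  fitc <- fit_global_epistasis(build_design_matrix(stc),
                               link = "identity")
  expect_lt(max(abs(fitc$beta)), 1e-3)
  expect_equal(fitc$beta0, 0.42, tolerance = 1e-3)
})

test_that("sigmoid fit recovers planted effects and asymptotes", {
  tr <- random_landscape(n_mutations = 30, effect_sd = 2,
                         effect_mean = -1, noise_sd = 0.02, seed = 11)
  vs <- unique(c("WT", names(tr$beta),
                 with_seed(12, replicate(700, paste(
                   sample(names(tr$beta), sample(2:4, 1)),
                   collapse = "+")))))
  sc <- simulate_variant_scores(tr, vs, seed = 13)
  gm <- build_design_matrix(data.frame(variant = sc$variant,
                                       score = sc$score, se = sc$se))
  fit <- fit_global_epistasis(gm, link = "sigmoid")
  expect_gt(stats::cor(fit$beta[names(tr$beta)], tr$beta), 0.99)
  expect_lt(abs(fit$L - tr$L), 0.02)
  expect_lt(abs(fit$U - tr$U) / tr$U, 0.02)
  expect_true(all(fit$beta_sd > 0))
  ho <- fit_global_epistasis(gm, link = "sigmoid", holdout_frac = 0.2)
  expect_gt(ho$holdout_r2, 0.9)
})

test_that("cycle residuals flag planted interactions and only those", {
  ad <- additive_score_table(n_singles = 25, n_doubles = 250,
                             noise_sd = 0.05, seed = 17)
  tab <- ad$table
  gm <- build_design_matrix(tab)
  fit <- fit_global_epistasis(gm, link = "identity")
  cr <- cycle_residuals(fit, tab)
  expect_gt(nrow(cr), 100)
  # null additive data: flags at the nominal 0.5% rate, residuals small
  expect_lt(mean(cr$significant), 0.03)
  # observed equal to prediction: zero residual, not significant
  i <- which.min(abs(cr$residual))
  tab2 <- tab
  tab2$score[tab2$variant == cr$AB[i]] <- cr$predicted[i]
  cr2 <- cycle_residuals(fit, tab2, cycles = cr[i, 1:3])
  expect_equal(cr2$residual, 0, tolerance = 1e-12)
  expect_false(cr2$significant)

  # plant +0.8 interactions on 10 cycles: flagged, positive
  planted <- with_seed(18, sample(nrow(cr), 10))
  tab3 <- tab
  idx <- match(cr$AB[planted], tab3$variant)
  tab3$score[idx] <- tab3$score[idx] + 0.8
  fit3 <- fit_global_epistasis(build_design_matrix(tab3),
                               link = "identity")
  cr3 <- cycle_residuals(fit3, tab3)
  hit <- match(cr$AB[planted], cr3$AB)
  expect_gt(mean(cr3$significant[hit]), 0.9)
  expect_gt(mean(cr3$positive[hit]), 0.9)
})

test_that("reciprocal sign epistasis follows its definition with error gates", {
  # scores WT 0.5, A 0.8, B 0.8, AB 0.2 with tight errors: reciprocal
  r <- classify_sign_epistasis(0.5, 0.8, 0.8, 0.2, 0.01, 0.01, 0.01,
                               0.01)
  expect_true(r$reciprocal)
  expect_equal(r$sign_a_wt, 1)
  expect_equal(r$sign_a_b, -1)
  # perfectly additive quartet: no flag
  expect_false(classify_sign_epistasis(0.5, 0.6, 0.7, 0.8)$reciprocal)
  # differences inside the error gate: insufficient evidence, no flag
  rq <- classify_sign_epistasis(0.5, 0.8, 0.8, 0.2, 0.5, 0.5, 0.5, 0.5)
  expect_false(rq$reciprocal)
  expect_equal(rq$sign_a_wt, 0)
})

test_that("pairwise couplings predict triples generated without 3-way terms", {
  tr <- random_landscape(n_mutations = 10, effect_sd = 0.4,
                         effect_mean = 0, noise_sd = 0.01, seed = 23)
  singles <- names(tr$beta)
  pairs <- t(utils::combn(singles, 2))
  # sparse planted couplings, zero elsewhere
  omega_true <- stats::setNames(numeric(nrow(pairs)),
                                apply(pairs, 1, function(r)
                                  paste(sort(r), collapse = "|")))
  omega_true[with_seed(24, sample(length(omega_true), 6))] <-
    c(0.3, -0.3, 0.4, -0.4, 0.35, -0.25)
  z_of <- function(toks) {
    z <- sum(tr$beta[toks])
    if (length(toks) >= 2) {
      pp <- utils::combn(sort(toks), 2)
      z <- z + sum(omega_true[apply(pp, 2, paste, collapse = "|")])
    }
    z
  }
  trip <- t(utils::combn(singles, 3))
  mk <- function(toks) render_variant(parse_variant_string(
    paste(toks, collapse = "+")))
  vs <- c("WT", singles, apply(pairs, 1, mk), apply(trip, 1, mk))
  z <- vapply(vs, function(v) if (v == "WT") 0 else
    z_of(variant_tokens(v)), numeric(1))
  tab <- with_seed(25, data.frame(
    variant = vs, score = z + stats::rnorm(length(z), 0, 0.01),
    se = 0.01, stringsAsFactors = FALSE))
  # latent effects from the clean single-mutant block; couplings from the
  # double cycles of the full table
  fit <- fit_global_epistasis(build_design_matrix(tab[1:11, ]),
                              link = "identity", prior_sd = 100)
  pc <- fit_pairwise_couplings(fit, tab)
  tok <- lapply(pc$couplings$AB, variant_tokens)
  keys <- vapply(tok, function(t) paste(sort(t), collapse = "|"),
                 character(1))
  # recovered couplings track the planted ones; additive pairs stay ~ 0
  expect_gt(stats::cor(pc$couplings$omega, omega_true[keys]), 0.95)
  expect_lt(max(abs(pc$couplings$omega[omega_true[keys] == 0])), 0.06)
  # triples built from pairwise terms only: second-order residuals ~ 0
  expect_lt(max(abs(pc$triples$residual2)), 0.1)
  # plant a 3-way term on one triple and see it in the residual
  tab2 <- tab
  v3 <- pc$triples$ABC[1]
  tab2$score[tab2$variant == v3] <- tab2$score[tab2$variant == v3] + 0.5
  pc2 <- fit_pairwise_couplings(fit, tab2)
  expect_equal(pc2$triples$residual2[pc2$triples$ABC == v3], 0.5,
               tolerance = 0.1)
})

test_that("constrained specificity curve recovers planted biases", {
  # variants exactly on the curve: residuals ~ 0
  link1 <- list(L = 0, U = 1)
  set.seed(31)
  z <- stats::rnorm(80, 0, 2)
  y1 <- stats::plogis(z)
  d_true <- -1.5
  y2 <- 2 + 6 * stats::plogis(z + d_true)
  dat <- data.frame(variant = paste0("v", seq_along(z)), score1 = y1,
                    se1 = 0.02, score2 = y2, se2 = 0.05)
  fit <- fit_constrained_specificity_curve(dat, link1)
  expect_lt(max(abs(fit$residuals$epsilon)), 1e-4)
  expect_equal(fit$delta_spec, d_true, tolerance = 0.05)
  # planted secondary-substrate bias +s on 10 variants shows as epsilon > 0
  s <- 1.2
  dat2 <- dat
  dat2$score2[1:10] <- 2 + 6 * stats::plogis(z[1:10] + d_true + s)
  fit2 <- fit_constrained_specificity_curve(dat2, link1)
  expect_true(all(fit2$residuals$epsilon[1:10] > 0))
  # sign convention: a point above the curve has positive residual
  dat3 <- dat
  dat3$score2[5] <- dat3$score2[5] + 0.8
  fit3 <- fit_constrained_specificity_curve(dat3, link1)
  expect_gt(fit3$residuals$epsilon[5], 0)
})

test_that("sparse specificity shrinks null features and honors masks", {
  tr <- random_landscape(n_mutations = 40, effect_sd = 1.5,
                         effect_mean = -0.5, noise_sd = 0.1, seed = 37)
  vs <- unique(c("WT", names(tr$beta),
                 with_seed(38, replicate(400, paste(
                   sample(names(tr$beta), sample(1:3, 1)),
                   collapse = "+")))))
  y1 <- simulate_variant_scores(tr, vs, "primary", seed = 39)
  y2 <- simulate_variant_scores(tr, vs, "secondary", seed = 40)
  gm <- build_design_matrix(data.frame(variant = y1$variant,
                                       score = y1$score, se = y1$se))
  # beta_s identically zero in truth: fitted beta_s concentrate near 0
  sf <- fit_sparse_specificity(gm$X, y1$score, y1$se, y2$score, y2$se)
  expect_lt(max(abs(sf$beta_s)), 0.05)
  expect_gt(stats::cor(sf$beta_g[names(tr$beta)], tr$beta), 0.95)
  # masking one arm still completes; beta_g identified from the other
  y1m <- y1$score; y1m[seq(1, length(y1m), by = 3)] <- NA
  sf2 <- fit_sparse_specificity(gm$X, y1m, y1$se, y2$score, y2$se)
  expect_true(all(is.finite(sf2$beta_g)))
})

test_that("residual correlation and its bootstrap CI behave", {
  x <- with_seed(43, stats::rnorm(60))
  expect_equal(residual_correlation(x, x)$r, 1)
  # independent residuals: CI straddles zero
  y <- with_seed(44, stats::rnorm(60))
  rc <- residual_correlation(x, y, seed = 45)
  expect_true(rc$ci[1] < 0 && rc$ci[2] > 0)
  # anti-correlated construction: negative beyond the CI
  ya <- -x + with_seed(46, stats::rnorm(60, 0, 0.3))
  rca <- residual_correlation(x, ya, seed = 47)
  expect_lt(rca$r, 0)
  expect_lt(rca$ci[2], 0)
  expect_error(residual_correlation(1:2, 1:2), "3 pairs")
})
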