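# Global-epistasis regression on mutation features, double/triple
# mutant-cycle analysis, and two-substrate specificity models (shared
# latent effects plus a sparse specificity set).

#' Build a genotype design matrix from a score table
#'
#' One binary column per distinct mutation token across the parseable
#' variants. Variants carrying frameshift tokens (or otherwise unparseable
#' strings) are excluded and reported with a reason; features observed on
#' fewer than `min_backgrounds` variants are retained but flagged as
#' data-poor rather than silently dropped.
#'
#' @param score_table data.frame with columns variant, score, se
#' @param min_backgrounds flag threshold for rare features (default 2)
#' @return a `genotype_matrix`: `X` (n x p binary), `variants`, `score`,
#'   `se`, `vocabulary`, `rare_features`, `excluded` (variant, reason)
#' @export
build_design_matrix <- function(score_table, min_backgrounds = 2) {
  toks <- vector("list", nrow(score_table))
  excl <- character(0); excl_reason <- character(0)
  for (i in seq_len(nrow(score_table))) {
    v <- score_table$variant[i]
    toks[i] <- list(tryCatch({
      if (grepl("fs", v, fixed = TRUE)) stop("frameshift token")
      variant_tokens(v)
    }, error = function(e) {
      excl <<- c(excl, v); excl_reason <<- c(excl_reason, conditionMessage(e))
      NULL
    }))
  }
  keep <- !vapply(toks, is.null, logical(1))
  toks <- toks[keep]
  tab <- score_table[keep, , drop = FALSE]
  vocab <- sort(unique(unlist(toks)))
  X <- matrix(0, nrow(tab), length(vocab),
              dimnames = list(tab$variant, vocab))
  for (i in seq_along(toks))
    X[i, match(toks[[i]], vocab)] <- 1
  counts <- colSums(X)
  structure(list(X = X, variants = tab$variant, score = tab$score,
                 se = tab$se, vocabulary = vocab,
                 rare_features = vocab[counts < min_backgrounds],
                 excluded = data.frame(variant = excl,
                                       reason = excl_reason,
                                       stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

sigmoid_link <- function(z, L, span) L + span * stats::plogis(z)

inv_sigmoid_link <- function(y, L, span, eps = 1e-4) {
  u <- (y - L) / span
  clipped <- u <= eps | u >= 1 - eps
  list(z = stats::qlogis(pmin(pmax(u, eps), 1 - eps)), clipped = clipped)
}

#' Fit a global-epistasis regression
#'
#' Bayesian regression of observed scores on binary mutation features with
#' an additive latent phenotype and either an identity or a sigmoid link
#' g(z) = L + (U - L) logistic(z) (slope and midpoint are absorbed into the
#' intercept and the scale of beta, so the sigmoid adds exactly two
#' parameters). Experimental error enters the likelihood as known
#' per-variant variance added to a learned global model variance:
#' y_v ~ Normal(g(beta0 + X beta), se_v^2 + sigma_model^2). Normal priors
#' on the latent effects; the posterior is summarized by a Laplace
#' (quadratic) approximation at the MAP, which is exact for the
#' identity-link model.
#'
#' @param gm a [build_design_matrix()] object
#' @param link `"sigmoid"` or `"identity"`
#' @param prior_sd normal prior sd on latent effects
#' @param holdout_frac optional fraction held out for an out-of-sample R^2
#'   (0 = none)
#' @param seed seed for the holdout split
#' @return a `global_epistasis_fit`: `beta`, `beta_sd` (named), `beta0`,
#'   `link`, `L`, `U`, `sigma_model`, `cov` (Laplace posterior covariance
#'   over all parameters), `par_names`, `r2`, `holdout_r2`, `logLik`
#' @export
fit_global_epistasis <- function(gm, link = c("sigmoid", "identity"),
                                 prior_sd = 10, holdout_frac = 0,
                                 seed = 1L) {
  link <- match.arg(link)
  X <- gm$X; y <- gm$score; se <- gm$se
  n <- nrow(X); p <- ncol(X)
  test_idx <- integer(0)
  if (holdout_frac > 0) {
    test_idx <- with_seed(seed, sample.int(n, round(holdout_frac * n)))
    Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]
    X <- X[-test_idx, , drop = FALSE]; y <- y[-test_idx]
    se <- se[-test_idx]
    n <- nrow(X)
  }
  sig <- link == "sigmoid"
  # theta = (beta0, beta[1..p], [L, log span], log sigma_model)
  nll <- function(th) {
    b0 <- th[1L]; b <- th[2:(p + 1)]
    z <- b0 + drop(X %*% b)
    if (sig) {
      L <- th[p + 2L]; span <- exp(th[p + 3L])
      g <- sigmoid_link(z, L, span)
      lsig <- th[p + 4L]
    } else {
      g <- z; lsig <- th[p + 2L]
    }
    v <- se^2 + exp(2 * lsig)
    r <- y - g
    0.5 * sum(log(v) + r^2 / v) + 0.5 * sum(b^2) / prior_sd^2 +
      0.5 * b0^2 / 100^2
  }
  grad <- function(th) {
    b0 <- th[1L]; b <- th[2:(p + 1)]
    z <- b0 + drop(X %*% b)
    if (sig) {
      L <- th[p + 2L]; span <- exp(th[p + 3L])
      s <- stats::plogis(z)
      g <- L + span * s
      dgdz <- span * s * (1 - s)
      lsig <- th[p + 4L]
    } else {
      g <- z; dgdz <- rep(1, length(z)); lsig <- th[p + 2L]
    }
    v <- se^2 + exp(2 * lsig)
    r <- y - g
    common <- -r / v
    gb <- drop(crossprod(X, common * dgdz)) + b / prior_sd^2
    gb0 <- sum(common * dgdz) + b0 / 100^2
    gsig <- sum((0.5 / v - 0.5 * r^2 / v^2) * 2 * exp(2 * lsig))
    if (sig) {
      gL <- sum(common)
      gspan <- sum(common * s) * span
      c(gb0, gb, gL, gspan, gsig)
    } else c(gb0, gb, gsig)
  }
  if (sig) {
    init <- c(0, rep(0, p), min(y), log(max(stats::sd(y),
                                            diff(range(y)) / 2)),
              log(max(stats::sd(y) / 4, 0.05)))
  } else {
    init <- c(mean(y), rep(0, p), log(max(stats::sd(y) / 4, 0.05)))
  }
  op <- stats::nlminb(init, nll, grad,
                      control = list(iter.max = 2000, eval.max = 4000))
  if (!is.finite(op$objective))
    stop("optimizer diverged (non-finite loss)")
  th <- op$par
  H <- stats::optimHess(th, nll, grad)
  cv <- tryCatch(solve(H), error = function(e) {
    MASS::ginv(H)
  })
  par_names <- c("beta0", gm$vocabulary,
                 if (sig) c("L", "log_span"), "log_sigma")
  beta <- stats::setNames(th[2:(p + 1)], gm$vocabulary)
  beta_sd <- stats::setNames(sqrt(pmax(diag(cv)[2:(p + 1)], 0)),
                             gm$vocabulary)
  L <- if (sig) th[p + 2L] else -Inf
  U <- if (sig) th[p + 2L] + exp(th[p + 3L]) else Inf
  pred <- function(Xm) {
    z <- th[1L] + drop(Xm %*% beta)
    if (sig) sigmoid_link(z, L, U - L) else z
  }
  yhat <- pred(X)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  holdout_r2 <- if (length(test_idx))
    1 - sum((yte - pred(Xte))^2) / sum((yte - mean(yte))^2) else NA_real_
  structure(list(beta = beta, beta_sd = beta_sd, beta0 = th[1L],
                 link = link, L = L, U = U,
                 sigma_model = exp(th[length(th)]),
                 theta = th, cov = cv, par_names = par_names,
                 r2 = r2, holdout_r2 = holdout_r2,
                 logLik = -op$objective, vocabulary = gm$vocabulary),
            class = "global_epistasis_fit")
}

#' @export
print.global_epistasis_fit <- function(x, ...) {
  cat("<global_epistasis_fit> link = ", x$link, ", ",
      length(x$beta), " features, sigma_model = ",
      signif(x$sigma_model, 3), ", R^2 = ", signif(x$r2, 3), "\n",
      sep = "")
  invisible(x)
}

#' Predict scores (with latent and predictive sd) for feature rows
#'
#' @param fit a [fit_global_epistasis()] fit
#' @param features list of token vectors, or a binary matrix with columns
#'   matching the fit vocabulary
#' @param se experimental error of the predicted observation (enters the
#'   predictive sd; default 0)
#' @return data.frame (z, pred, pred_sd): latent, predicted score, and
#'   posterior-predictive sd (parameter + model + experimental variance)
#' @export
predict_landscape <- function(fit, features, se = 0) {
  p <- length(fit$beta)
  Xm <- if (is.matrix(features)) features else {
    m <- matrix(0, length(features), p,
                dimnames = list(NULL, fit$vocabulary))
    for (i in seq_along(features))
      m[i, match(features[[i]], fit$vocabulary)] <- 1
    m
  }
  sig <- fit$link == "sigmoid"
  z <- fit$beta0 + drop(Xm %*% fit$beta)
  if (sig) {
    s <- stats::plogis(z); span <- fit$U - fit$L
    pred <- fit$L + span * s
    dgdz <- span * s * (1 - s)
  } else {
    pred <- z; dgdz <- rep(1, length(z))
  }
  npar <- length(fit$theta)
  se <- rep_len(se, length(z))
  var_par <- vapply(seq_along(z), function(i) {
    gr <- numeric(npar)
    gr[1L] <- dgdz[i]
    gr[2:(p + 1)] <- dgdz[i] * Xm[i, ]
    if (sig) {
      gr[p + 2L] <- 1
      gr[p + 3L] <- (pred[i] - fit$L)  # d pred / d log span = span*s
    }
    drop(gr %*% fit$cov %*% gr)
  }, numeric(1))
  data.frame(z = z, pred = pred,
             pred_sd = sqrt(pmax(var_par, 0) + fit$sigma_model^2 + se^2))
}

#' Enumerate mutant cycles in a score table
#'
#' @param score_table data.frame (variant, score, se)
#' @param order 2 for double cycles \{WT, A, B, AB\}, 3 for triples
#' @return data.frame of cycles with member variant strings
#' @export
find_cycles <- function(score_table, order = 2) {
  vs <- score_table$variant
  tok <- lapply(vs, function(v) tryCatch(variant_tokens(v),
                                         error = function(e) NULL))
  nmut <- vapply(tok, function(t) if (is.null(t)) -1L else length(t),
                 integer(1))
  singles <- stats::setNames(vs[nmut == 1L],
                             unlist(tok[nmut == 1L], use.names = FALSE))
  if (!"WT" %in% vs) stop("score table must contain WT")
  idx <- which(nmut == order)
  rows <- lapply(idx, function(i) {
    t <- tok[[i]]
    if (!all(t %in% names(singles))) return(NULL)
    if (order == 2L)
      data.frame(A = singles[t[1]], B = singles[t[2]], AB = vs[i],
                 stringsAsFactors = FALSE)
    else
      data.frame(A = singles[t[1]], B = singles[t[2]], C = singles[t[3]],
                 ABC = vs[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- if (order == 2L)
      data.frame(A = character(), B = character(), AB = character())
    else data.frame(A = character(), B = character(), C = character(),
                    ABC = character())
  rownames(out) <- NULL
  out
}

#' Double-mutant cycle residuals against the global-epistasis model
#'
#' For each cycle \{WT, A, B, AB\}, the double mutant's score is predicted
#' as g(beta0 + beta_A + beta_B) and compared with observation; the
#' 99.5% posterior-predictive interval (parameter covariance + model
#' variance + the double's experimental error) defines significance, with
#' positive/negative calls from the residual sign and reciprocal-sign calls
#' from [classify_sign_epistasis()] on the observed quartet.
#'
#' @param fit a [fit_global_epistasis()] fit
#' @param score_table data.frame (variant, score, se) containing the cycles
#' @param cycles optional precomputed [find_cycles()] table
#' @param level posterior-predictive coverage (default 0.995)
#' @param sign_k error multiple for the sign-epistasis gate
#' @return data.frame: cycle members, observed, predicted, `residual`,
#'   `pred_sd`, `lower`, `upper`, `significant`, `positive`, `negative`,
#'   `reciprocal_sign`
#' @export
cycle_residuals <- function(fit, score_table, cycles = NULL,
                            level = 0.995, sign_k = 2) {
  if (is.null(cycles)) cycles <- find_cycles(score_table, order = 2)
  if (nrow(cycles) == 0L) return(cbind(cycles))
  st <- score_table
  sc <- function(v) st$score[match(v, st$variant)]
  er <- function(v) st$se[match(v, st$variant)]
  feats <- lapply(seq_len(nrow(cycles)), function(i)
    variant_tokens(cycles$AB[i]))
  pr <- predict_landscape(fit, feats, se = er(cycles$AB))
  q <- stats::qnorm(1 - (1 - level) / 2)
  obs <- sc(cycles$AB)
  resid <- obs - pr$pred
  lower <- pr$pred - q * pr$pred_sd
  upper <- pr$pred + q * pr$pred_sd
  signif_ <- obs < lower | obs > upper
  recip <- vapply(seq_len(nrow(cycles)), function(i)
    classify_sign_epistasis(sc("WT"), sc(cycles$A[i]), sc(cycles$B[i]),
                            obs[i], er("WT"), er(cycles$A[i]),
                            er(cycles$B[i]), er(cycles$AB[i]),
                            k = sign_k)$reciprocal,
    logical(1))
  cbind(cycles,
        data.frame(observed = obs, predicted = pr$pred, residual = resid,
                   pred_sd = pr$pred_sd, lower = lower, upper = upper,
                   significant = signif_,
                   positive = signif_ & resid > 0,
                   negative = signif_ & resid < 0,
                   reciprocal_sign = recip))
}

#' Classify sign epistasis from an observed quartet
#'
#' Reciprocal sign epistasis: the effect of A changes sign between the WT
#' and B backgrounds AND the effect of B changes sign between the WT and A
#' backgrounds, with every one of the four background effects exceeding
#' `k` times its propagated error (differences within error are never
#' flagged).
#'
#' @param wt,a,b,ab observed scores of the quartet
#' @param se_wt,se_a,se_b,se_ab their standard errors
#' @param k error multiple each effect must exceed
#' @return list: `reciprocal`, `sign_a_wt`, `sign_a_b`, `sign_b_wt`,
#'   `sign_b_a` (signs of the four background effects, 0 if within error)
#' @export
classify_sign_epistasis <- function(wt, a, b, ab, se_wt = 0, se_a = 0,
                                    se_b = 0, se_ab = 0, k = 2) {
  eff <- function(x, y, sx, sy) {
    d <- x - y
    if (abs(d) <= k * sqrt(sx^2 + sy^2)) 0 else sign(d)
  }
  s_a_wt <- eff(a, wt, se_a, se_wt)   # effect of A on WT background
  s_a_b <- eff(ab, b, se_ab, se_b)    # effect of A on B background
  s_b_wt <- eff(b, wt, se_b, se_wt)
  s_b_a <- eff(ab, a, se_ab, se_a)
  recip <- s_a_wt != 0 && s_a_b != 0 && s_b_wt != 0 && s_b_a != 0 &&
    s_a_wt != s_a_b && s_b_wt != s_b_a
  list(reciprocal = recip, sign_a_wt = s_a_wt, sign_a_b = s_a_b,
       sign_b_wt = s_b_wt, sign_b_a = s_b_a)
}

#' Pairwise couplings from double cycles; triple-cycle predictions
#'
#' The coupling of a pair is the latent-scale discrepancy of its double
#' mutant: omega_AB = g^-1(y_AB) - (beta0 + beta_A + beta_B). Scores
#' outside the invertible range of the link are clipped and flagged.
#' Triples are predicted by plugging in the three pairwise couplings:
#' g(beta0 + sum beta + sum omega); the second-order residual is
#' observed - predicted.
#'
#' @param fit a [fit_global_epistasis()] fit
#' @param score_table data.frame (variant, score, se)
#' @return list: `couplings` (A, B, AB, omega, clipped), `triples`
#'   (members, observed, predicted, residual2) for triples whose three
#'   pairs all have couplings
#' @export
fit_pairwise_couplings <- function(fit, score_table) {
  dbl <- find_cycles(score_table, order = 2)
  st <- score_table
  sc <- function(v) st$score[match(v, st$variant)]
  latent <- function(v) {
    y <- sc(v)
    if (fit$link == "sigmoid") inv_sigmoid_link(y, fit$L, fit$U - fit$L)
    else list(z = y, clipped = rep(FALSE, length(y)))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  tokA <- vapply(dbl$A, function(v) variant_tokens(v)[1], character(1))
  tokB <- vapply(dbl$B, function(v) variant_tokens(v)[1], character(1))
  li <- latent(dbl$AB)
  omega <- li$z - (fit$beta0 + fit$beta[tokA] + fit$beta[tokB])
  couplings <- data.frame(A = dbl$A, B = dbl$B, AB = dbl$AB,
                          omega = as.numeric(omega),
                          clipped = li$clipped,
                          stringsAsFactors = FALSE)
  omap <- stats::setNames(couplings$omega, key(tokA, tokB))
  tri <- find_cycles(score_table, order = 3)
  triples <- NULL
  if (nrow(tri) > 0L) {
    rows <- lapply(seq_len(nrow(tri)), function(i) {
      t <- variant_tokens(tri$ABC[i])
      kk <- c(key(t[1], t[2]), key(t[1], t[3]), key(t[2], t[3]))
      if (!all(kk %in% names(omap))) return(NULL)
      z <- fit$beta0 + sum(fit$beta[t]) + sum(omap[kk])
      pred <- if (fit$link == "sigmoid")
        sigmoid_link(z, fit$L, fit$U - fit$L) else z
      data.frame(tri[i, , drop = FALSE], observed = sc(tri$ABC[i]),
                 predicted = pred,
                 residual2 = sc(tri$ABC[i]) - pred,
                 stringsAsFactors = FALSE)
    })
    triples <- do.call(rbind, rows)
  }
  if (is.null(triples))
    triples <- data.frame(A = character(), B = character(),
                          C = character(), ABC = character(),
                          observed = numeric(), predicted = numeric(),
                          residual2 = numeric())
  rownames(couplings) <- rownames(triples) <- NULL
  list(couplings = couplings, triples = triples)
}

#' Constrained two-substrate specificity curve
#'
#' Fits the expected relationship between a variant's primary-substrate and
#' secondary-substrate scores under the assumption that only the focal
#' mutation (present in every variant considered) shifts the latent
#' specificity: the shared latent is read off the primary score through the
#' inverse primary link, and the secondary score is modeled as
#' g2(z + delta_spec). The residual is measured vertically in the
#' secondary-substrate direction, so a variant above the curve (more
#' secondary activity than expected) has epsilon > 0.
#'
#' @param data data.frame (variant, score1, se1, score2, se2): paired
#'   scores of focal-containing variants
#' @param link1 list `L`, `U` of the primary-substrate sigmoid (e.g. from a
#'   [fit_global_epistasis()] fit)
#' @param position_of optional function(variant) -> integer position used
#'   for the per-position residual export
#' @return list: `delta_spec`, `link2` (L, U), `residuals` data.frame
#'   (variant, epsilon, clipped), `position_residuals` (position,
#'   mean_residual) when `position_of` is given
#' @export
fit_constrained_specificity_curve <- function(data, link1,
                                              position_of = NULL) {
  inv <- inv_sigmoid_link(data$score1, link1$L, link1$U - link1$L)
  z <- inv$z
  y <- data$score2
  w <- 1 / pmax(data$se2, 1e-3)^2
  fit <- minpack.lm::nlsLM(
    y ~ L2 + (U2 - L2) * stats::plogis(z + d),
    start = list(L2 = min(y), U2 = max(y) + 1e-3, d = 0),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  pred <- cf[["L2"]] + (cf[["U2"]] - cf[["L2"]]) *
    stats::plogis(z + cf[["d"]])
  res <- data.frame(variant = data$variant, epsilon = y - pred,
                    clipped = inv$clipped, stringsAsFactors = FALSE)
  out <- list(delta_spec = cf[["d"]],
              link2 = list(L = cf[["L2"]], U = cf[["U2"]]),
              residuals = res)
  if (!is.null(position_of)) {
    pos <- vapply(data$variant, position_of, numeric(1))
    agg <- stats::aggregate(res$epsilon, list(position = pos), mean)
    names(agg)[2] <- "mean_residual"
    out$position_residuals <- agg
  }
  out
}

#' Sparse two-substrate specificity regression
#'
#' Joint model of two substrate score sets sharing global latent effects:
#' z1 = beta0_1 + X beta_g, z2 = beta0_2 + X (beta_g + beta_s), each mapped
#' through its own sigmoid. beta_g carries a normal prior; beta_s carries a
#' sparse Laplace prior so only the essential specificity determinants stay
#' nonzero. MAP fit (smoothed L1) with a Laplace-approximate posterior for
#' the dense parameters.
#'
#' @param X binary feature matrix (n x p, columns named by mutation token)
#' @param y1,se1 primary-substrate scores and errors (NA allowed; masked)
#' @param y2,se2 secondary-substrate scores and errors (NA allowed)
#' @param prior_sd_g normal prior sd on beta_g
#' @param lambda_s Laplace penalty rate on beta_s (per unit beta)
#' @param link `"sigmoid"` or `"identity"` per-substrate links
#' @return a `specificity_fit`: `beta_g`, `beta_s` (named), `beta_s_rank`
#'   (features by decreasing |beta_s|), intercepts, links, sigmas
#' @export
fit_sparse_specificity <- function(X, y1, se1, y2, se2, prior_sd_g = 10,
                                   lambda_s = 20,
                                   link = c("sigmoid", "identity")) {
  link <- match.arg(link)
  sig <- link == "sigmoid"
  p <- ncol(X)
  m1 <- is.finite(y1); m2 <- is.finite(y2)
  eps <- 1e-8
  # theta: b01, b02, bg (p), bs (p), [L1, lspan1, L2, lspan2], lsig1, lsig2
  unpack <- function(th) {
    out <- list(b01 = th[1L], b02 = th[2L], bg = th[3:(p + 2)],
                bs = th[(p + 3):(2 * p + 2)])
    i <- 2 * p + 2L
    if (sig) {
      out$L1 <- th[i + 1]; out$sp1 <- exp(th[i + 2])
      out$L2 <- th[i + 3]; out$sp2 <- exp(th[i + 4])
      i <- i + 4L
    }
    out$ls1 <- th[i + 1]; out$ls2 <- th[i + 2]
    out
  }
  arm_nll <- function(y, se, mask, z, L, sp, ls) {
    g <- if (sig) L + sp * stats::plogis(z) else z
    v <- se^2 + exp(2 * ls)
    r <- (y - g)[mask]
    0.5 * sum(log(v[mask]) + r^2 / v[mask])
  }
  nll <- function(th) {
    u <- unpack(th)
    z1 <- u$b01 + drop(X %*% u$bg)
    z2 <- u$b02 + drop(X %*% (u$bg + u$bs))
    arm_nll(y1, se1, m1, z1, u$L1, u$sp1, u$ls1) +
      arm_nll(y2, se2, m2, z2, u$L2, u$sp2, u$ls2) +
      0.5 * sum(u$bg^2) / prior_sd_g^2 +
      lambda_s * sum(sqrt(u$bs^2 + eps)) +
      0.5 * (u$b01^2 + u$b02^2) / 100^2
  }
  grad <- function(th) {
    u <- unpack(th)
    z1 <- u$b01 + drop(X %*% u$bg)
    z2 <- u$b02 + drop(X %*% (u$bg + u$bs))
    arm <- function(y, se, mask, z, L, sp, ls) {
      if (sig) {
        s <- stats::plogis(z); g <- L + sp * s; dgdz <- sp * s * (1 - s)
      } else { g <- z; dgdz <- rep(1, length(z)); s <- NULL }
      v <- se^2 + exp(2 * ls)
      r <- ifelse(mask, y - g, 0)
      common <- ifelse(mask, -r / v, 0)
      list(dz = common * dgdz,
           dL = if (sig) sum(common) else 0,
           dlsp = if (sig) sum(common * s) * sp else 0,
           dls = sum(ifelse(mask, (0.5 / v - 0.5 * r^2 / v^2), 0) *
                       2 * exp(2 * ls)))
    }
    a1 <- arm(y1, se1, m1, z1, u$L1, u$sp1, u$ls1)
    a2 <- arm(y2, se2, m2, z2, u$L2, u$sp2, u$ls2)
    gb01 <- sum(a1$dz) + u$b01 / 100^2
    gb02 <- sum(a2$dz) + u$b02 / 100^2
    gbg <- drop(crossprod(X, a1$dz + a2$dz)) + u$bg / prior_sd_g^2
    gbs <- drop(crossprod(X, a2$dz)) +
      lambda_s * u$bs / sqrt(u$bs^2 + eps)
    c(gb01, gb02, gbg, gbs,
      if (sig) c(a1$dL, a1$dlsp, a2$dL, a2$dlsp),
      a1$dls, a2$dls)
  }
  init <- c(0, 0, rep(0, 2 * p))
  if (sig) {
    rng1 <- range(y1[m1]); rng2 <- range(y2[m2])
    init <- c(init, rng1[1], log(max(diff(rng1), 0.1)),
              rng2[1], log(max(diff(rng2), 0.1)))
  }
  init <- c(init, log(0.1), log(0.1))
  op <- stats::nlminb(init, nll, grad,
                      control = list(iter.max = 3000, eval.max = 6000))
  if (!is.finite(op$objective)) stop("optimizer diverged")
  u <- unpack(op$par)
  beta_g <- stats::setNames(u$bg, colnames(X))
  beta_s <- stats::setNames(u$bs, colnames(X))
  ord <- order(-abs(beta_s))
  structure(list(beta_g = beta_g, beta_s = beta_s,
                 beta_s_rank = colnames(X)[ord],
                 beta0 = c(u$b01, u$b02),
                 link = link,
                 link1 = if (sig) list(L = u$L1, U = u$L1 + u$sp1),
                 link2 = if (sig) list(L = u$L2, U = u$L2 + u$sp2),
                 sigma = exp(c(u$ls1, u$ls2)),
                 lambda_s = lambda_s, objective = op$objective),
            class = "specificity_fit")
}

#' @export
print.specificity_fit <- function(x, ...) {
  cat("<specificity_fit> ", length(x$beta_g), " features; top |beta_s|: ",
      paste(utils::head(x$beta_s_rank, 5), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Correlation between residual sets with a bootstrap CI
#'
#' @param x,y paired residual vectors (>= 3 pairs)
#' @param n_boot bootstrap resamples
#' @param conf confidence level
#' @param seed RNG seed
#' @return list `r`, `ci` (length 2), `n`
#' @export
residual_correlation <- function(x, y, n_boot = 2000, conf = 0.95,
                                 seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  r <- stats::cor(x, y)
  bs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(stats::cor(x[idx], y[idx]))
  }, numeric(1)))
  ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(r = r, ci = ci, n = n)
}
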