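# Per-sample phenotype estimation: anchored two-component Gaussian mixture
# for flow-cytometry events, dose-response normalization with
# Michaelis-Menten fitting, and nested growth-model selection.

as_event_matrix <- function(events) {
  if (is.data.frame(events)) {
    cols <- intersect(c("fitc", "ssc"), names(events))
    events <- if (length(cols) == 2L) as.matrix(events[, cols])
              else as.matrix(events[, 1:2])
  }
  storage.mode(events) <- "double"
  events
}

#' Fit the reference (inactive) Gaussian
#'
#' Maximum-likelihood mean and covariance of the 2-D (log-fluorescence,
#' scatter) events of a negative-control sample; used as the anchor for the
#' regularized mixture.
#'
#' @param events matrix or data.frame of events (columns fitc, ssc)
#' @return list `mu` (length 2), `sigma` (2x2)
#' @export
fit_reference_gaussian <- function(events) {
  x <- as_event_matrix(events)
  if (nrow(x) < 10L) stop("need at least 10 events")
  mu <- colMeans(x)
  sigma <- stats::cov(x) * (nrow(x) - 1) / nrow(x)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <=
        1e-12)
    stop("degenerate covariance: events are (nearly) identical")
  list(mu = mu, sigma = sigma)
}

dmvnorm2 <- function(x, mu, sigma, log = TRUE) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  out <- -sum(log(diag(ch))) - log(2 * pi) - 0.5 * colSums(z^2)
  if (log) out else exp(out)
}

anchored_objective <- function(x, pi1, mu1, s1, mu2, s2, anchors,
                               lambda_mu, lambda_sigma, lambda_pi) {
  l1 <- dmvnorm2(x, mu1, s1) + log(pi1)
  l2 <- dmvnorm2(x, mu2, s2) + log(1 - pi1)
  m <- pmax(l1, l2)
  ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
  ll - lambda_mu * sum((mu1 - anchors$mu)^2) -
    lambda_sigma * sum((s1 - anchors$sigma)^2) -
    lambda_pi * pi1
}

#' Anchored two-component Gaussian mixture (regularized EM)
#'
#' EM for a two-component 2-D Gaussian mixture in which the first
#' ("inactive") component is regularized toward a reference fit: the M-step
#' maximizes the log-likelihood minus
#' `lambda_mu * ||mu1 - mu_inactive||^2 + lambda_sigma * ||Sigma1 -
#' Sigma_inactive||^2 + lambda_pi * pi1`. The mean and weight penalties have
#' closed-form penalized updates; the covariance penalty is handled by a
#' convex shrinkage of the weighted covariance toward the anchor with weight
#' `lambda_sigma / (lambda_sigma + N1)`, a fixed-point surrogate sharing the
#' penalty's limits (no penalty at lambda = 0, pinned as lambda -> Inf).
#' The fitted active-component mean log-fluorescence (`active_mean`) is the
#' per-sample score used downstream.
#'
#' @param events matrix or data.frame of events (columns fitc, ssc)
#' @param anchors list `mu`, `sigma` from [fit_reference_gaussian()]
#' @param lambda_mu,lambda_sigma,lambda_pi regularization weights (>= 0);
#'   defaults 0.3, 0.3, 0.1
#' @param init optional list (pi1, mu1, sigma1, mu2, sigma2)
#' @param tol absolute convergence tolerance on the objective
#' @param max_iter iteration cap (non-convergence is reported on the
#'   returned object; the best iterate is still returned)
#' @return a `mixture_fit`: `pi` (length 2), `mu`, `sigma` (lists,
#'   component 1 = inactive, 2 = active), `active_mean`, `responsibilities`,
#'   `objective` (trace, non-decreasing), `converged`, `iterations`
#' @export
fit_anchored_gmm <- function(events, anchors, lambda_mu = 0.3,
                             lambda_sigma = 0.3, lambda_pi = 0.1,
                             init = NULL, tol = 1e-8, max_iter = 500L) {
  if (any(c(lambda_mu, lambda_sigma, lambda_pi) < 0))
    stop("regularization weights must be >= 0")
  x <- as_event_matrix(events)
  n <- nrow(x)
  if (is.null(init)) {
    init <- list(pi1 = 0.25, mu1 = anchors$mu, sigma1 = anchors$sigma,
                 mu2 = colMeans(x) + c(1, 0) * stats::sd(x[, 1]),
                 sigma2 = stats::cov(x))
  }
  pi1 <- init$pi1; mu1 <- init$mu1; s1 <- init$sigma1
  mu2 <- init$mu2; s2 <- init$sigma2
  ridge <- diag(1e-8, 2)
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    l1 <- dmvnorm2(x, mu1, s1) + log(pi1)
    l2 <- dmvnorm2(x, mu2, s2) + log(1 - pi1)
    m <- pmax(l1, l2)
    g1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    n1 <- sum(g1); n2 <- n - n1
    # M-step: penalized weight (quadratic root in (0,1))
    if (lambda_pi > 0) {
      a <- lambda_pi; b <- -(n + lambda_pi); cc <- n1
      pi1 <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
    } else pi1 <- n1 / n
    pi1 <- min(max(pi1, 1e-8), 1 - 1e-8)
    # penalized mean: (N1 S1^-1 + 2 lambda_mu I) mu1 =
    #                 S1^-1 sum(g x) + 2 lambda_mu mu_anchor
    s1inv <- solve(s1 + ridge)
    A <- n1 * s1inv + 2 * lambda_mu * diag(2)
    bvec <- s1inv %*% colSums(x * g1) + 2 * lambda_mu * anchors$mu
    mu1 <- drop(solve(A, bvec))
    # shrunk covariance
    xc <- t(x) - mu1
    s1hat <- (xc %*% (t(xc) * g1)) / max(n1, 1e-8)
    rho <- if (lambda_sigma + n1 > 0) lambda_sigma / (lambda_sigma + n1)
           else 0
    s1 <- (1 - rho) * s1hat + rho * anchors$sigma + ridge
    # free active component
    mu2 <- colSums(x * (1 - g1)) / max(n2, 1e-8)
    xc2 <- t(x) - mu2
    s2 <- (xc2 %*% (t(xc2) * (1 - g1))) / max(n2, 1e-8) + ridge
    obj <- c(obj, anchored_objective(x, pi1, mu1, s1, mu2, s2, anchors,
                                     lambda_mu, lambda_sigma, lambda_pi))
    if (it > 1L && abs(obj[it] - obj[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(pi = c(pi1, 1 - pi1), mu = list(mu1, mu2),
                 sigma = list(s1, s2), active_mean = mu2[1L],
                 anchors = anchors,
                 lambda = c(mu = lambda_mu, sigma = lambda_sigma,
                            pi = lambda_pi),
                 responsibilities = cbind(inactive = g1, active = 1 - g1),
                 objective = obj, converged = converged,
                 iterations = length(obj)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> pi_inactive = ", signif(x$pi[1], 3),
      ", active mean log-fluorescence = ", signif(x$active_mean, 4),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Baseline-subtract a dose response
#'
#' Subtracts the negative-control active-mean at each concentration from
#' the sample's, pointwise on a shared concentration grid.
#'
#' @param sample,control data.frames (concentration, response) on matching
#'   grids
#' @return data.frame (concentration, response) of baseline-subtracted
#'   responses
#' @export
normalize_dose_response <- function(sample, control) {
  if (!isTRUE(all.equal(sort(sample$concentration),
                        sort(control$concentration))))
    stop("sample and control concentration grids differ")
  s <- sample[order(sample$concentration), ]
  k <- control[order(control$concentration), ]
  data.frame(concentration = s$concentration,
             response = s$response - k$response)
}

#' Fit a Michaelis-Menten dose response
#'
#' Least-squares fit of response = Vmax * c / (Km + c), from the standard
#' initial guesses Vmax = 0.1, Km = 25 (concentration units of the assay).
#'
#' @param dose data.frame (concentration, response), >= 3 concentrations
#' @param init named initial guesses
#' @return list `vmax`, `km`, `cov` (2x2 parameter covariance), `fitted`,
#'   `flag` ("ok", "km_nonpositive", or "vmax_zero_km_unidentifiable")
#' @export
fit_michaelis_menten <- function(dose, init = c(vmax = 0.1, km = 25)) {
  if (nrow(dose) < 3L) stop("need at least 3 concentrations")
  conc <- dose$concentration; y <- dose$response
  fit <- minpack.lm::nlsLM(
    y ~ vmax * conc / (km + conc),
    start = list(vmax = init[["vmax"]], km = init[["km"]]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 2, 2))
  flag <- "ok"
  if (abs(cf[["vmax"]]) < 1e-8) flag <- "vmax_zero_km_unidentifiable"
  else if (cf[["km"]] <= 0) flag <- "km_nonpositive"
  list(vmax = cf[["vmax"]], km = cf[["km"]], cov = vc,
       fitted = stats::fitted(fit), flag = flag)
}

# nested growth family ------------------------------------------------------
# logistic(y0, K, r) c Richards(+v) c Baranyi-Roberts(+q0, m); Richards is
# Baranyi-Roberts with infinite initial physiological state (A(t) = t).
baranyi_curve <- function(t, y0, K, r, v = 1, q0 = Inf, m = 1) {
  At <- if (is.finite(q0)) t + log((exp(-m * t) + q0) / (1 + q0)) / m else t
  K / (1 + ((K / y0)^v - 1) * exp(-r * v * At))^(1 / v)
}

growth_models <- function() {
  list(
    logistic = list(
      pars = c("y0", "K", "r"),
      fn = function(t, p) baranyi_curve(t, p[1], p[2], p[3]),
      lower = c(1e-6, 0.4, 1e-6), upper = c(0.05, 10, 20),
      start = function(od) c(min(max(min(od), 1e-3), 0.049),
                             min(max(max(od), 0.41), 9.9), 0.5)),
    richards = list(
      pars = c("y0", "K", "r", "v"),
      fn = function(t, p) baranyi_curve(t, p[1], p[2], p[3], p[4]),
      lower = c(1e-6, 0.4, 1e-6, 1), upper = c(0.05, 10, 20, 10),
      start = function(od) c(min(max(min(od), 1e-3), 0.049),
                             min(max(max(od), 0.41), 9.9), 0.5, 1.5)),
    baranyi = list(
      pars = c("y0", "K", "r", "v", "q0", "m"),
      fn = function(t, p) baranyi_curve(t, p[1], p[2], p[3], p[4], p[5],
                                        p[6]),
      lower = c(1e-6, 0.4, 1e-6, 0.01, 0.01, 0.01),
      upper = c(0.05, 10, 20, 10, 1e3, 20),
      start = function(od) c(min(max(min(od), 1e-3), 0.049),
                             min(max(max(od), 0.41), 9.9), 0.5, 1, 0.1, 1))
  )
}

#' Fit and select a growth model
#'
#' Fits the nested growth family — 3-parameter logistic, 4-parameter
#' Richards, 6-parameter Baranyi-Roberts (which adds a lag governed by the
#' initial physiological state q0) — by bounded least squares on the
#' truncated window, and selects the minimum-BIC candidate. Bounds follow
#' plate-reader practice for OD600 curves: y0 in [0, 0.05], K in [0.4, 10],
#' r > 0, v >= 1 (Richards) or v, q0 >= 0.01 (Baranyi-Roberts).
#'
#' @param time,od numeric vectors (time in hours, OD600)
#' @param window fit only time <= window hours (default 8; later biphasic
#'   growth is excluded)
#' @param no_growth_delta OD span below which the curve is flagged
#'   no-growth
#' @return a `growth_fit`: `model` (selected id), `parameters` (named),
#'   `r` (growth rate of the winner), `bic` (per candidate), `fits`,
#'   `no_growth`, `window`
#' @export
fit_growth_rate <- function(time, od, window = 8, no_growth_delta = 0.05) {
  keep <- time <= window
  t <- time[keep]; y <- od[keep]
  if (length(t) < 10L) stop("need >= 10 timepoints within the window")
  cands <- growth_models()
  fits <- list(); bic <- stats::setNames(rep(NA_real_, length(cands)),
                                         names(cands))
  for (nm in names(cands)) {
    cand <- cands[[nm]]
    res <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = cand$start(y),
        fn = function(p) y - cand$fn(t, p),
        lower = cand$lower, upper = cand$upper,
        control = minpack.lm::nls.lm.control(maxiter = 300))
      rss <- sum(fit$fvec^2)
      list(par = stats::setNames(fit$par, cand$pars), rss = rss,
           bic = length(t) * log(rss / length(t)) +
             length(cand$pars) * log(length(t)))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      fits[[nm]] <- res
      bic[nm] <- res$bic
    }
  }
  if (all(is.na(bic))) stop("all growth-model candidates failed to fit")
  best <- names(which.min(bic))
  par <- fits[[best]]$par
  no_growth <- (max(y) - min(y)) < no_growth_delta
  structure(list(model = best, parameters = par, r = par[["r"]],
                 bic = bic, fits = fits, no_growth = no_growth,
                 window = window),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> model = ", x$model, ", r = ", signif(x$r, 4),
      if (x$no_growth) " (no growth)", "\n", sep = "")
  invisible(x)
}
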