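# Turning barcode counts into calibrated activity scores: Poisson-Gamma
# read-count posteriors, weighted-mean-bin sort-seq scores, growth
# log-enrichment, random-effects replicate merging, errors-in-variables
# cross-library calibration, and null-based hit calling.

#' Poisson-Gamma posterior over a variant's read rate
#'
#' Counts c are modeled as Poisson(lambda) with lambda = f * N_reads and a
#' Gamma(alpha, beta) prior on lambda, giving the conjugate posterior
#' Gamma(alpha + c, 1 + beta). With the default nearly-uninformative prior
#' (alpha = 1, beta = 0.001) the posterior-mean frequency is
#' (c + 1) / (N_reads * 1.001), which still assigns sensible (larger)
#' relative errors to low-count variants.
#'
#' @param c observed read count (>= 0)
#' @param n_reads total reads in the sample (>= 1)
#' @param alpha,beta Gamma prior shape and rate
#' @return a `frequency_posterior`: `shape`, `rate`, `mean_lambda`,
#'   `mean_f`, and `n_reads`
#' @export
frequency_posterior <- function(c, n_reads, alpha = 1, beta = 0.001) {
  stopifnot(all(c >= 0), all(n_reads >= 1))
  structure(list(shape = alpha + c, rate = 1 + beta,
                 mean_lambda = (alpha + c) / (1 + beta),
                 mean_f = (c + alpha) / (n_reads * (1 + beta)),
                 n_reads = n_reads),
            class = "frequency_posterior")
}

#' Draw posterior frequency samples
#'
#' @param fp a [frequency_posterior()]
#' @param n number of draws
#' @return numeric draws of f = lambda / N_reads
#' @export
draw_frequency <- function(fp, n = 100) {
  stats::rgamma(n * length(fp$shape), shape = fp$shape,
                rate = fp$rate) / fp$n_reads
}

#' Raw weighted mean bin of a sort-seq variant
#'
#' Posterior-mean read frequencies per bin are converted to estimated
#' sorted-cell weights (frequency within the bin sample times the number of
#' cells sorted into that bin) and summarized as the weighted mean bin index
#' (bins 1..B).
#'
#' @param counts reads for the variant in each bin (length B)
#' @param reads total reads of each bin sample
#' @param cells cells sorted into each bin (C_b)
#' @param alpha,beta Gamma prior parameters
#' @return weighted mean bin (numeric in [1, B])
#' @export
sortseq_raw <- function(counts, reads, cells, alpha = 1, beta = 0.001) {
  f <- (counts + alpha) / (reads * (1 + beta))
  w <- f * cells
  sum(seq_along(counts) * w) / sum(w)
}

#' Normalized sort-seq score with resampling error
#'
#' The raw weighted mean bin is anchored so the WT raw value maps to 1 and
#' the inactive-null raw value to 0. The error is the standard deviation of
#' the score over `n_resample` posterior draws of the variant's per-bin
#' frequencies (anchor raw values are held fixed).
#'
#' @inheritParams sortseq_raw
#' @param raw_wt,raw_null anchor raw values (distinct)
#' @param n_resample posterior draws for the error (default 100)
#' @param seed RNG seed for the resampling stream
#' @return list `score`, `error`, `raw`
#' @export
sortseq_score <- function(counts, reads, cells, raw_wt, raw_null,
                          alpha = 1, beta = 0.001, n_resample = 100,
                          seed = NULL) {
  if (length(counts) < 2L) stop("need at least 2 bins")
  if (!is.finite(raw_wt) || !is.finite(raw_null) ||
        abs(raw_wt - raw_null) < 1e-12)
    stop("degenerate anchors: WT and null raw values must differ")
  raw <- sortseq_raw(counts, reads, cells, alpha, beta)
  score <- (raw - raw_null) / (raw_wt - raw_null)
  B <- length(counts)
  draws <- with_seed(seed, matrix(stats::rgamma(n_resample * B,
    shape = rep(alpha + counts, each = n_resample),
    rate = 1 + beta), n_resample, B))
  fmat <- sweep(draws, 2L, reads, "/")
  wmat <- sweep(fmat, 2L, cells, "*")
  raws <- (wmat %*% seq_len(B)) / rowSums(wmat)
  scores <- (raws - raw_null) / (raw_wt - raw_null)
  list(score = score, error = stats::sd(scores), raw = raw)
}

#' Score a sort-seq count table
#'
#' Runs the full sort-seq scoring path on a long count table (columns
#' variant, bin, rep, count) with per-(bin, rep) sorted-cell counts:
#' per-replicate raw weighted mean bins, WT/null anchoring, 100-draw
#' resampling errors, and random-effects merging across replicates.
#'
#' @param counts data.frame (variant, bin, rep, count), e.g. from
#'   [simulate_sortseq_counts()]
#' @param cells data.frame (bin, rep, cells)
#' @param wt,null variant ids of the anchors
#' @param alpha,beta prior parameters
#' @param n_resample posterior draws per variant and replicate
#' @param seed base seed; each variant gets a dedicated derived stream
#' @return data.frame (variant, score, se, n_rep): the merged score table
#' @export
score_sortseq_table <- function(counts, cells, wt = "WT", null = "null",
                                alpha = 1, beta = 0.001, n_resample = 100,
                                seed = 1L) {
  reps <- sort(unique(counts$rep))
  variants <- unique(counts$variant)
  per_rep <- list()
  for (r in reps) {
    cr <- counts[counts$rep == r, ]
    wide <- stats::xtabs(count ~ variant + bin, cr)
    bins <- as.integer(colnames(wide))
    reads <- colSums(wide)
    cl <- cells[cells$rep == r, ]
    C_b <- cl$cells[match(bins, cl$bin)]
    raw_wt <- sortseq_raw(wide[wt, ], reads, C_b, alpha, beta)
    raw_null <- sortseq_raw(wide[null, ], reads, C_b, alpha, beta)
    res <- lapply(seq_len(nrow(wide)), function(i)
      sortseq_score(wide[i, ], reads, C_b, raw_wt, raw_null, alpha, beta,
                    n_resample,
                    seed = seed + 7919L * i + as.integer(r)))
    per_rep[[as.character(r)]] <- data.frame(
      variant = rownames(wide), rep = r,
      score = vapply(res, `[[`, numeric(1), "score"),
      se = vapply(res, `[[`, numeric(1), "error"),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, per_rep)
  out <- do.call(rbind, lapply(split(long, long$variant), function(d) {
    m <- merge_replicates(d$score, d$se)
    data.frame(variant = d$variant[1L], score = m$score, se = m$error,
               n_rep = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[match(variants, out$variant), , drop = FALSE]
}

#' Random-effects merge of replicate scores
#'
#' DerSimonian-Laird-type meta-analysis: the between-replicate variance is
#' estimated by method of moments (truncated at zero), and replicates are
#' combined by inverse-variance weights 1 / (se_i^2 + tau^2).
#'
#' @param scores per-replicate scores
#' @param errors per-replicate standard errors (finite, >= 1 replicate)
#' @return list `score`, `error`, `tau2` (between-replicate variance),
#'   `n`
#' @export
merge_replicates <- function(scores, errors) {
  keep <- is.finite(scores) & is.finite(errors)
  scores <- scores[keep]; errors <- pmax(errors[keep], 1e-12)
  k <- length(scores)
  if (k == 0L) return(list(score = NA_real_, error = NA_real_,
                           tau2 = NA_real_, n = 0L))
  if (k == 1L) return(list(score = scores, error = errors, tau2 = 0,
                           n = 1L))
  w <- 1 / errors^2
  xbar <- sum(w * scores) / sum(w)
  Q <- sum(w * (scores - xbar)^2)
  Cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / Cc)
  wstar <- 1 / (errors^2 + tau2)
  list(score = sum(wstar * scores) / sum(wstar),
       error = sqrt(1 / sum(wstar)), tau2 = tau2, n = k)
}

#' Log enrichment from pre/post selection counts
#'
#' Per replicate, log(f_post / f_pre) with posterior-mean frequencies;
#' replicates whose pre-selection count falls below the threshold are
#' excluded (variants failing in every replicate are reported missing, not
#' zero); per-replicate errors come from posterior resampling of both
#' frequencies; surviving replicates merge via [merge_replicates()].
#'
#' @param counts data.frame (variant, rep, pre, post), e.g. from
#'   [simulate_selection_counts()]
#' @param pre_threshold minimum pre-selection count per replicate (>= 0)
#' @param alpha,beta prior parameters
#' @param n_resample posterior draws per replicate
#' @param seed base RNG seed
#' @return data.frame (variant, score, se, n_rep); missing variants carry
#'   NA score with n_rep = 0
#' @export
log_enrichment <- function(counts, pre_threshold = 50, alpha = 1,
                           beta = 0.001, n_resample = 100, seed = 1L) {
  if (pre_threshold < 0) stop("pre_threshold must be >= 0")
  N_pre <- stats::aggregate(pre ~ rep, counts, sum)
  N_post <- stats::aggregate(post ~ rep, counts, sum)
  counts$Npre <- N_pre$pre[match(counts$rep, N_pre$rep)]
  counts$Npost <- N_post$post[match(counts$rep, N_post$rep)]
  out <- lapply(split(counts, counts$variant), function(d) {
    d <- d[d$pre >= pre_threshold, , drop = FALSE]
    if (nrow(d) == 0L)
      return(data.frame(variant = NA_character_, score = NA_real_,
                        se = NA_real_, n_rep = 0L))
    le <- log(((d$post + alpha) / (d$Npost * (1 + beta))) /
                ((d$pre + alpha) / (d$Npre * (1 + beta))))
    se <- vapply(seq_len(nrow(d)), function(i) {
      with_seed(seed + 17L * d$rep[i], {
        fpre <- stats::rgamma(n_resample, alpha + d$pre[i], 1 + beta) /
          d$Npre[i]
        fpost <- stats::rgamma(n_resample, alpha + d$post[i], 1 + beta) /
          d$Npost[i]
        stats::sd(log(fpost / fpre))
      })
    }, numeric(1))
    m <- merge_replicates(le, se)
    data.frame(variant = d$variant[1L], score = m$score, se = m$error,
               n_rep = m$n, stringsAsFactors = FALSE)
  })
  variants <- unique(counts$variant)
  out <- do.call(rbind, out)
  out$variant[is.na(out$variant)] <-
    setdiff(variants, out$variant)[seq_len(sum(is.na(out$variant)))]
  rownames(out) <- NULL
  out[match(variants, out$variant), , drop = FALSE]
}

#' Orthogonal-distance merge of two score tables
#'
#' Fits scoreB = m * scoreA + b on error-filtered overlapping variants by
#' errors-in-variables least squares (each point weighted by
#' 1 / (seB^2 + m^2 seA^2), so noise on both axes is modeled — unlike
#' ordinary least squares, whose slope attenuates), rescales table B onto
#' table A's scale via (scoreB - b) / m, and merges per-variant with the
#' random-effects model.
#'
#' @param tableA,tableB data.frames (variant, score, se)
#' @param error_thresholds length-2 maximum se for tables A and B
#' @return list: `fit` (m, b, se_m, se_b, n), `merged` data.frame
#'   (variant, score, se, n_rep) over the union of variants
#' @export
odr_merge <- function(tableA, tableB, error_thresholds = c(0.15, 0.15)) {
  a <- tableA[is.finite(tableA$score) & tableA$se <= error_thresholds[1], ]
  b <- tableB[is.finite(tableB$score) & tableB$se <= error_thresholds[2], ]
  ov <- merge(a, b, by = "variant", suffixes = c("_a", "_b"))
  if (nrow(ov) < 3L) stop("fewer than 3 overlapping variants after filters")
  obj <- function(p) {
    v <- ov$se_b^2 + p[1]^2 * ov$se_a^2
    sum((ov$score_b - p[1] * ov$score_a - p[2])^2 / v)
  }
  init <- stats::coef(stats::lm(score_b ~ score_a, data = ov))[c(2, 1)]
  op <- stats::optim(as.numeric(init), obj, method = "BFGS",
                     hessian = TRUE)
  m <- op$par[1]; bb <- op$par[2]
  s2 <- op$value / (nrow(ov) - 2)
  cv <- tryCatch(2 * s2 * solve(op$hessian),
                 error = function(e) matrix(NA_real_, 2, 2))
  fit <- list(m = m, b = bb, se_m = sqrt(cv[1, 1]), se_b = sqrt(cv[2, 2]),
              n = nrow(ov), thresholds = error_thresholds)
  resc <- data.frame(variant = tableB$variant,
                     score = (tableB$score - bb) / m,
                     se = tableB$se / abs(m), stringsAsFactors = FALSE)
  allv <- union(tableA$variant, tableB$variant)
  merged <- do.call(rbind, lapply(allv, function(v) {
    s <- c(tableA$score[tableA$variant == v], resc$score[resc$variant == v])
    e <- c(tableA$se[tableA$variant == v], resc$se[resc$variant == v])
    mm <- merge_replicates(s, e)
    data.frame(variant = v, score = mm$score, se = mm$error, n_rep = mm$n,
               stringsAsFactors = FALSE)
  }))
  list(fit = fit, merged = merged)
}

#' Call significant hits against a WT-barcode null
#'
#' The null distribution comes from scores of barcodes mapping to the WT
#' protein: z = (score - mu_null) / sqrt(var_null + se^2), one-sided upper
#' p-values by default (enrichment above WT is the alternative), adjusted
#' by Benjamini-Hochberg step-up FDR.
#'
#' @param scores,errors per-variant merged scores and standard errors
#' @param null_scores >= 5 scores of WT-mapping barcodes
#' @param level FDR level for the significance flag
#' @param one_sided test only for scores above the null (default TRUE)
#' @param variants optional variant ids carried through
#' @return data.frame (variant, score, p, fdr, significant)
#' @export
call_hits <- function(scores, errors, null_scores, level = 0.05,
                      one_sided = TRUE, variants = NULL) {
  if (length(null_scores) < 5L) stop("need >= 5 null observations")
  mu0 <- mean(null_scores); v0 <- stats::var(null_scores)
  z <- (scores - mu0) / sqrt(v0 + errors^2)
  p <- if (one_sided) stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(variant = if (is.null(variants)) seq_along(scores)
                       else variants,
             score = scores, p = p, fdr = fdr,
             significant = fdr < level, stringsAsFactors = FALSE)
}
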