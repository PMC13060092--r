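# Synthetic-data generators. Every downstream stage is exercised against
# data produced here, with the generating ground truth carried alongside so
# recovery can be checked exactly.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state so simulations are reproducible without clobbering the session.
#'
#' @param seed integer seed, or NULL for no seeding
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Ground-truth fitness landscape
#'
#' The latent additive-plus-sigmoid landscape the generators draw from: each
#' mutation token carries a true latent effect `beta`; a variant's latent
#' phenotype is the sum over its mutations, mapped through the sigmoid
#' L + (U - L) * logistic(z). Per-substrate specificity shifts `beta_s`
#' move the latent phenotype for the second substrate:
#' z_second = z + sum(beta_s).
#'
#' @param beta named numeric vector of true latent effects; names are
#'   canonical mutation tokens (e.g. "M230A")
#' @param L,U lower and upper sigmoid asymptotes (L < U)
#' @param beta_s named numeric vector of specificity shifts (defaults to 0
#'   for every mutation)
#' @param noise_sd per-variant measurement noise sd
#' @param seed generator seed stored with the truth
#' @return a `ground_truth_landscape`
#' @export
ground_truth_landscape <- function(beta, L = 0, U = 1, beta_s = NULL,
                                   noise_sd = 0.05, seed = 1L) {
  stopifnot(is.numeric(beta), !is.null(names(beta)), all(is.finite(beta)))
  if (!(L < U)) stop("L must be < U")
  if (is.null(beta_s)) beta_s <- stats::setNames(numeric(length(beta)),
                                                 names(beta))
  structure(list(beta = beta, L = L, U = U, beta_s = beta_s,
                 noise_sd = noise_sd, seed = seed),
            class = "ground_truth_landscape")
}

#' Random ground-truth landscape over substitution tokens
#'
#' Draws `n_mutations` substitution tokens at distinct residue positions and
#' normal latent effects, a convenient starting point for recovery tests.
#'
#' @param n_mutations number of distinct mutations
#' @param effect_sd sd of the normal distribution of true latent effects
#' @param effect_mean mean latent effect (negative values emulate mostly
#'   deleterious mutations)
#' @param seed RNG seed
#' @inheritParams ground_truth_landscape
#' @return a [ground_truth_landscape()]
#' @export
random_landscape <- function(n_mutations = 50, effect_sd = 2,
                             effect_mean = -1, L = 0, U = 1,
                             noise_sd = 0.05, seed = 1L) {
  with_seed(seed, {
    aa <- aa_alphabet()
    pos <- sample(seq_len(10L * n_mutations), n_mutations)
    wt <- sample(aa, n_mutations, replace = TRUE)
    new <- vapply(wt, function(a) sample(setdiff(aa, a), 1L), character(1))
    tokens <- paste0(wt, pos, new)
    beta <- stats::setNames(stats::rnorm(n_mutations, effect_mean,
                                         effect_sd), tokens)
    ground_truth_landscape(beta, L = L, U = U, noise_sd = noise_sd,
                           seed = seed)
  })
}

#' Latent phenotype and expected score of variants under a truth
#'
#' @param truth a [ground_truth_landscape()]
#' @param variants character vector of variant strings; `"WT"` has z = 0 and
#'   the designated `null` variant sits at the lower asymptote
#' @param substrate `"primary"` uses `beta` alone; `"secondary"` adds
#'   `beta_s`
#' @param null name of the null (inactive anchor) variant, if present
#' @return data.frame (variant, z, mean) where mean = L + (U-L) logistic(z)
#' @export
truth_phenotype <- function(truth, variants, substrate = "primary",
                            null = "null") {
  z <- vapply(variants, function(v) {
    if (identical(v, null)) return(-Inf)
    toks <- variant_tokens(v)
    if (!all(toks %in% names(truth$beta)))
      stop("variant '", v, "' contains mutations absent from the truth")
    s <- sum(truth$beta[toks])
    if (substrate == "secondary") s <- s + sum(truth$beta_s[toks])
    s
  }, numeric(1))
  data.frame(variant = variants, z = z,
             mean = truth$L + (truth$U - truth$L) * stats::plogis(z),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a clade-structured alignment
#'
#' Generates per-clade consensus sequences that differ from a shared root at
#' a controlled fraction of positions (`divergence`), then adds i.i.d.
#' within-clade substitution noise. Clade labels are retained so latent-space
#' separation can be validated.
#'
#' @param n_clades,seqs_per_clade counts (>= 1)
#' @param length alignment length
#' @param divergence fraction of positions at which clade consensuses differ
#'   from the root, in [0, 1]
#' @param within_noise per-position substitution probability within a clade
#' @param seed RNG seed
#' @return an [aa_alignment()] with `clade` labels and attribute
#'   `clade_positions` (the diverged positions)
#' @export
simulate_msa <- function(n_clades, seqs_per_clade, length, divergence,
                         within_noise = 0.05, seed = 1L) {
  if (n_clades < 1 || seqs_per_clade < 1 || length < 1)
    stop("all counts must be >= 1")
  if (divergence < 0 || divergence > 1)
    stop("divergence must be in [0, 1]")
  with_seed(seed, {
    aa <- aa_alphabet()
    root <- sample(aa, length, replace = TRUE)
    n_div <- round(divergence * length)
    div_pos <- if (n_div > 0) sort(sample.int(length, n_div)) else integer()
    seqs <- character(0); clade <- integer(0)
    for (cl in seq_len(n_clades)) {
      cons <- root
      for (p in div_pos) cons[p] <- sample(setdiff(aa, root[p]), 1L)
      for (s in seq_len(seqs_per_clade)) {
        sq <- cons
        hit <- which(stats::runif(length) < within_noise)
        for (p in hit) sq[p] <- sample(setdiff(aa, cons[p]), 1L)
        seqs <- c(seqs, paste(sq, collapse = ""))
        clade <- c(clade, cl)
      }
    }
    aln <- aa_alignment(seqs, ids = sprintf("clade%d_seq%d", clade,
                                            stats::ave(clade, clade,
                                                       FUN = seq_along)),
                        clade = clade)
    attr(aln, "clade_positions") <- div_pos
    aln
  })
}

#' Sort-seq simulation configuration
#'
#' @param n_bins number of sort bins (default 4)
#' @param gates internal gate boundaries on log-fluorescence (length
#'   n_bins - 1, strictly increasing); default: evenly spaced between the
#'   truth's asymptotes
#' @param cells_per_variant cells of each variant entering the sorter
#' @param reads_per_bin sequencing reads per bin sample
#' @param noise_sd per-cell log-fluorescence noise sd
#' @return a `sortsim_config`
#' @export
sortsim_config <- function(n_bins = 4, gates = NULL,
                           cells_per_variant = 1000,
                           reads_per_bin = 2e5, noise_sd = 0.25) {
  if (!is.null(gates)) {
    if (length(gates) != n_bins - 1 || is.unsorted(gates, strictly = TRUE))
      stop("gates must be strictly increasing with length n_bins - 1")
  }
  if (cells_per_variant <= 0) stop("cells per variant must be > 0")
  structure(list(n_bins = n_bins, gates = gates,
                 cells_per_variant = cells_per_variant,
                 reads_per_bin = reads_per_bin, noise_sd = noise_sd),
            class = "sortsim_config")
}

#' Simulate sort-seq barcode counts
#'
#' Cells of each variant draw log-fluorescence from
#' Normal(L + (U-L) logistic(z), noise_sd), fall into gated bins, and reads
#' per (variant, bin) are Poisson with mean proportional to the variant's
#' cell fraction in that bin times the bin's read depth — mirroring
#' Poisson sequencing sampling of sorted cells. True normalized scores (the
#' expected weighted mean bin, anchored so WT is 1 and the null variant 0)
#' are returned alongside.
#'
#' @param truth a [ground_truth_landscape()]
#' @param variants variant strings; must include `"WT"`; a variant named
#'   `"null"` is pinned to the lower asymptote (an inactive frameshift
#'   stand-in)
#' @param cfg a [sortsim_config()]
#' @param replicates number of independent sort replicates
#' @param seed RNG seed (default: the truth's seed)
#' @return list: `counts` (variant, bin, rep, count), `cells` (bin, rep,
#'   cells) sorted-cell counts, `reads` per (bin, rep) totals, `truth`
#'   (variant, z, mean, raw_true, score_true), `cfg`
#' @export
simulate_sortseq_counts <- function(truth, variants, cfg = sortsim_config(),
                                    replicates = 3, seed = NULL) {
  if (cfg$reads_per_bin <= 0) stop("reads per sample must be positive")
  if (!"WT" %in% variants) stop("variants must include WT")
  if (is.null(seed)) seed <- truth$seed
  ph <- truth_phenotype(truth, variants)
  gates <- cfg$gates
  if (is.null(gates))
    gates <- truth$L + (truth$U - truth$L) *
      seq_len(cfg$n_bins - 1) / cfg$n_bins
  B <- cfg$n_bins
  brk <- c(-Inf, gates, Inf)
  # exact per-bin probabilities -> ground-truth raw weighted mean bin
  pb <- t(vapply(ph$mean, function(m) {
    p <- diff(stats::pnorm(brk, mean = m, sd = cfg$noise_sd))
    if (!is.finite(m)) { p <- numeric(B); p[1L] <- 1 }  # null at -Inf
    p
  }, numeric(B)))
  raw_true <- as.vector(pb %*% seq_len(B))
  raw_wt <- raw_true[variants == "WT"][1L]
  raw_null <- if ("null" %in% variants) raw_true[variants == "null"][1L]
              else 1
  score_true <- (raw_true - raw_null) / (raw_wt - raw_null)
  counts <- NULL; cells <- NULL
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      ncell <- matrix(0L, length(variants), B)
      for (i in seq_along(variants)) {
        if (is.finite(ph$mean[i])) {
          fl <- stats::rnorm(cfg$cells_per_variant, ph$mean[i],
                             cfg$noise_sd)
          ncell[i, ] <- tabulate(findInterval(fl, gates) + 1L, B)
        } else {
          ncell[i, 1L] <- cfg$cells_per_variant
        }
      }
      C_b <- colSums(ncell)
      for (b in seq_len(B)) {
        lam <- if (C_b[b] > 0) cfg$reads_per_bin * ncell[, b] / C_b[b]
               else numeric(length(variants))
        cnt <- stats::rpois(length(variants), lam)
        counts <- rbind(counts, data.frame(
          variant = variants, bin = b, rep = r, count = cnt,
          stringsAsFactors = FALSE))
      }
      cells <- rbind(cells, data.frame(bin = seq_len(B), rep = r,
                                       cells = C_b))
    }
  })
  reads <- stats::aggregate(count ~ bin + rep, counts, sum)
  names(reads)[names(reads) == "count"] <- "reads"
  list(counts = counts, cells = cells, reads = reads,
       truth = cbind(ph, raw_true = raw_true, score_true = score_true),
       cfg = cfg)
}

#' Simulate growth-selection counts
#'
#' Pre-selection frequencies are uniform over the variants present in a
#' replicate (each variant independently drops out of the pre-selection
#' culture with probability `dropout_rate`, emulating stochastic overnight
#' growth). Post-selection frequencies are proportional to
#' pre * exp(activity * growth_time); reads are Poisson at the stated depth.
#'
#' @param activity named numeric vector: per-variant growth-rate advantage
#' @param growth_time selection duration (same units as 1/activity)
#' @param read_depth expected total reads per sample
#' @param replicates number of replicates
#' @param dropout_rate probability a variant is absent pre-selection,
#'   in [0, 1)
#' @param seed RNG seed
#' @return list: `counts` (variant, rep, pre, post), `present` logical
#'   matrix, `activity`, `growth_time`
#' @export
simulate_selection_counts <- function(activity, growth_time = 5,
                                      read_depth = 1e6, replicates = 3,
                                      dropout_rate = 0, seed = 1L) {
  if (growth_time <= 0) stop("growth_time must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  variants <- names(activity)
  n <- length(variants)
  with_seed(seed, {
    present <- matrix(stats::runif(n * replicates) >= dropout_rate, n,
                      replicates, dimnames = list(variants, NULL))
    counts <- NULL
    for (r in seq_len(replicates)) {
      keep <- present[, r]
      f_pre <- ifelse(keep, 1, 0); f_pre <- f_pre / sum(f_pre)
      f_post <- f_pre * exp(activity * growth_time)
      f_post <- f_post / sum(f_post)
      counts <- rbind(counts, data.frame(
        variant = variants, rep = r,
        pre = stats::rpois(n, read_depth * f_pre),
        post = stats::rpois(n, read_depth * f_post),
        stringsAsFactors = FALSE))
    }
    list(counts = counts, present = present, activity = activity,
         growth_time = growth_time)
  })
}

#' Simulate two-component flow-cytometry events
#'
#' Draws n 2-D events (log-fluorescence `fitc`, scatter `ssc`) from a
#' mixture of an active and an inactive Gaussian component, keeping the
#' component labels — the planted mixture used to validate the anchored
#' mixture fitter.
#'
#' @param active,inactive lists with `mean` (length 2) and `cov` (2x2
#'   positive-definite)
#' @param frac_inactive mixture weight of the inactive component, in [0, 1]
#' @param n number of events
#' @param seed RNG seed
#' @return data.frame (fitc, ssc, component) with component in
#'   {"active", "inactive"}
#' @export
simulate_flow_events <- function(active, inactive, frac_inactive, n,
                                 seed = 1L) {
  if (frac_inactive < 0 || frac_inactive > 1)
    stop("frac_inactive must be in [0, 1]")
  for (comp in list(active, inactive)) {
    ev <- eigen(comp$cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariances must be positive-definite")
  }
  with_seed(seed, {
    lab <- ifelse(stats::runif(n) < frac_inactive, "inactive", "active")
    out <- matrix(NA_real_, n, 2)
    n_in <- sum(lab == "inactive")
    if (n_in > 0)
      out[lab == "inactive", ] <- MASS::mvrnorm(n_in, inactive$mean,
                                                inactive$cov)
    if (n - n_in > 0)
      out[lab == "active", ] <- MASS::mvrnorm(n - n_in, active$mean,
                                              active$cov)
    data.frame(fitc = out[, 1], ssc = out[, 2], component = lab,
               stringsAsFactors = FALSE)
  })
}

#' Simulate observed variant scores directly from a landscape
#'
#' Shortcut past the sequencing layer: observed score = sigmoid(z) + noise
#' with known per-variant error, for regression-model recovery tests. An
#' optional mis-specified softplus link probes robustness to the assumed
#' sigmoid.
#'
#' @param truth a [ground_truth_landscape()]
#' @param variants variant strings
#' @param substrate `"primary"` or `"secondary"` (adds `beta_s`)
#' @param link `"sigmoid"` (matched to the fitter) or `"softplus"`
#'   (mis-specified)
#' @param seed RNG seed
#' @return data.frame (variant, score, se, z_true, mean_true)
#' @export
simulate_variant_scores <- function(truth, variants, substrate = "primary",
                                    link = c("sigmoid", "softplus"),
                                    seed = NULL) {
  link <- match.arg(link)
  if (is.null(seed)) seed <- truth$seed
  ph <- truth_phenotype(truth, variants, substrate = substrate)
  mu <- if (link == "sigmoid") ph$mean
        else truth$L + (truth$U - truth$L) * log1p(exp(ph$z)) / 4
  with_seed(seed, {
    data.frame(variant = variants,
               score = mu + stats::rnorm(length(variants), 0,
                                         truth$noise_sd),
               se = rep(truth$noise_sd, length(variants)),
               z_true = ph$z, mean_true = mu,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
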