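# Energy-based Gibbs sampling with distance and latent-exploration
# restraints, restraint calibration, binding-site shell enumeration, and
# conversion of model samples into an independent per-position synthesis
# design.

#' Energy models over sequences
#'
#' An energy model assigns a computational energy U(x) to a full sequence;
#' the sampler draws letters proportional to exp(-U'/T). Two constructors
#' are provided: a site-independent model from a [build_pssm()] PSSM
#' (U(x) = -sum log p), and an arbitrary tabulated/functional model for
#' enumerable toys and external energy tables.
#'
#' @param pssm a [build_pssm()] object
#' @return an `energy_model`
#' @export
pssm_energy_model <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  structure(list(type = "pssm", logp = pssm$logp,
                 alphabet = pssm$alphabet, L = ncol(pssm$logp)),
            class = "energy_model")
}

#' @rdname pssm_energy_model
#' @param energy_fn function taking an integer state vector (alphabet
#'   indices, length L) and returning U(x)
#' @param alphabet letter vector
#' @param L sequence length
#' @export
custom_energy_model <- function(energy_fn, alphabet, L) {
  structure(list(type = "custom", energy_fn = energy_fn,
                 alphabet = alphabet, L = as.integer(L)),
            class = "energy_model")
}

#' Unbiased energy of a sequence
#'
#' @param model an `energy_model`
#' @param state integer state vector (alphabet indices) or letter vector
#' @return U(x)
#' @export
model_energy <- function(model, state) {
  state <- as_state(model, state)
  if (model$type == "pssm")
    -sum(model$logp[cbind(state, seq_len(model$L))])
  else model$energy_fn(state)
}

as_state <- function(model, seq) {
  if (is.character(seq)) {
    if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1L]]
    seq <- match(seq, model$alphabet)
    if (anyNA(seq)) stop("letter outside the model alphabet")
  }
  as.integer(seq)
}

# conditional energies at one position: U of the full sequence with each
# alphabet letter substituted at `pos` (consistent with model_energy by
# construction)
cond_energies <- function(model, state, pos) {
  A <- length(model$alphabet)
  if (model$type == "pssm") {
    base <- -sum(model$logp[cbind(state, seq_len(model$L))]) +
      model$logp[state[pos], pos]
    base - model$logp[, pos]
  } else {
    vapply(seq_len(A), function(a) {
      s <- state; s[pos] <- a; model$energy_fn(s)
    }, numeric(1))
  }
}

#' Sampler configuration
#'
#' Holds the computational temperature, the restraint weights, the
#' reference sequence and the latent decomposition used by the exploration
#' term, plus sweep counts and the seed.
#'
#' @param temperature computational temperature T > 0
#' @param w_d distance-restraint weight (>= 0); each position differing from
#'   the reference adds `w_d` to the energy, a linear pull toward the
#'   reference that approximately cancels the entropy of distant sequences
#' @param w_pca exploration weight (>= 0); the latent displacement
#'   ||u(x) - u0|| is *rewarded*, i.e. enters the effective energy with a
#'   negative sign (see [biased_energy()])
#' @param ref reference sequence (letters or state indices)
#' @param dec optional [fit_latent()] decomposition (required when
#'   `w_pca > 0`)
#' @param sweeps number of full Gibbs sweeps
#' @param burn_in sweeps discarded before recording samples
#' @param seed RNG seed
#' @return a `sampler_config`
#' @export
sampler_config <- function(temperature = 1, w_d = 0, w_pca = 0, ref,
                           dec = NULL, sweeps = 1000, burn_in = 100,
                           seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (w_d < 0 || w_pca < 0) stop("restraint weights must be >= 0")
  if (w_pca > 0 && is.null(dec))
    stop("latent decomposition required when w_pca > 0")
  structure(list(temperature = temperature, w_d = w_d, w_pca = w_pca,
                 ref = ref, dec = dec, sweeps = as.integer(sweeps),
                 burn_in = as.integer(burn_in), seed = seed),
            class = "sampler_config")
}

#' Biased (restrained) energy U'(x)
#'
#' U'(x) = U(x) + w_d * Hamming(x, ref) - w_pca * ||u(x) - u0||.
#' The exploration term is written with a negative sign because larger
#' latent displacement is rewarded — sequences that move their embedding
#' away from the reference become *more* probable under exp(-U'/T).
#'
#' @param model an `energy_model`
#' @param cfg a [sampler_config()]
#' @param seq sequence (letters or state indices)
#' @return U'(x)
#' @export
biased_energy <- function(model, cfg, seq) {
  state <- as_state(model, seq)
  ref <- as_state(model, cfg$ref)
  u <- model_energy(model, state) + cfg$w_d * sum(state != ref)
  if (cfg$w_pca > 0) {
    letters <- model$alphabet[state]
    u <- u - cfg$w_pca * latent_distance(cfg$dec, letters)
  }
  u
}

#' Gibbs sampling from a restrained energy model
#'
#' Per sweep, positions are visited in a freshly drawn random order; at each
#' position a letter is drawn from the conditional Boltzmann distribution
#' proportional to exp(-U'(.)/T). One sample is recorded per sweep after
#' burn-in. Fully reproducible under the configuration seed.
#'
#' @param model an `energy_model`
#' @param cfg a [sampler_config()]
#' @param init initial state (default: the reference)
#' @return list: `states` integer matrix (samples x L), `letters` character
#'   matrix, `energies` unbiased U of each sample, `hamming` distance to
#'   the reference per sample
#' @export
gibbs_sample <- function(model, cfg, init = NULL) {
  if (cfg$sweeps < 1) stop("sweeps must be >= 1")
  A <- length(model$alphabet); L <- model$L
  ref <- as_state(model, cfg$ref)
  state <- if (is.null(init)) ref else as_state(model, init)
  use_pca <- cfg$w_pca > 0
  if (use_pca) {
    dec <- cfg$dec
    if (!identical(dec$alphabet, model$alphabet))
      stop("latent decomposition alphabet must match the model alphabet")
    # cached V rows: row (pos-1)*A + letter
    u <- drop((one_hot_seq(model$alphabet[state], dec$alphabet) -
                 dec$center) %*% dec$v)
    u0 <- dec$u0
  }
  n_keep <- cfg$sweeps - cfg$burn_in
  if (n_keep < 1) stop("burn_in must leave at least one sweep")
  out <- matrix(NA_integer_, n_keep, L)
  with_seed(cfg$seed, {
    for (sw in seq_len(cfg$sweeps)) {
      for (pos in sample.int(L)) {
        e <- cond_energies(model, state, pos)
        e <- e + cfg$w_d * (seq_len(A) != ref[pos])
        if (use_pca) {
          cur_row <- dec$v[(pos - 1L) * A + state[pos], ]
          base <- u - cur_row
          rows <- dec$v[(pos - 1L) * A + seq_len(A), , drop = FALSE]
          # candidate displacement = (base + row_a) - u0
          cand <- rows + matrix(base - u0, A, length(u0), byrow = TRUE)
          e <- e - cfg$w_pca * sqrt(rowSums(cand^2))
        }
        p <- exp(-(e - min(e)) / cfg$temperature)
        if (!all(is.finite(p))) stop("non-finite conditional energies")
        new_letter <- sample.int(A, 1L, prob = p)
        if (use_pca && new_letter != state[pos])
          u <- u - dec$v[(pos - 1L) * A + state[pos], ] +
            dec$v[(pos - 1L) * A + new_letter, ]
        state[pos] <- new_letter
      }
      if (sw > cfg$burn_in) out[sw - cfg$burn_in, ] <- state
    }
  })
  letters <- matrix(model$alphabet[out], n_keep, L)
  energies <- apply(out, 1L, function(s) model_energy(model, s))
  list(states = out, letters = letters, energies = energies,
       hamming = rowSums(out != matrix(ref, n_keep, L, byrow = TRUE)))
}

#' Calibrate the sampling temperature
#'
#' Screens a grid of temperatures and returns the one whose samples have
#' average (unbiased) energy closest to the reference sequence's energy.
#'
#' @param model an `energy_model`
#' @param ref reference sequence
#' @param T_grid temperatures to screen (non-empty)
#' @param sweeps,burn_in sweep counts per grid point
#' @param seed RNG seed
#' @return list: `temperature` (selected), `mean_energy` per grid point,
#'   `target` U(ref)
#' @export
calibrate_temperature <- function(model, ref, T_grid, sweeps = 500,
                                  burn_in = 100, seed = 1L) {
  if (length(T_grid) == 0) stop("empty temperature grid")
  target <- model_energy(model, ref)
  me <- vapply(seq_along(T_grid), function(i) {
    cfg <- sampler_config(temperature = T_grid[i], ref = ref,
                          sweeps = sweeps, burn_in = burn_in,
                          seed = seed + i)
    mean(gibbs_sample(model, cfg)$energies)
  }, numeric(1))
  list(temperature = T_grid[which.min(abs(me - target))],
       mean_energy = me, target = target)
}

token_state <- function(tokens, alphabet) {
  m <- do.call(rbind, lapply(tokens, function(tk) {
    v <- parse_variant_string(tk)$mutations
    data.frame(pos = v$pos, letter = match(v$new, alphabet))
  }))
  m
}

#' Calibrate distance and exploration weights
#'
#' For each exploration weight on the grid, solves (by bisection, using the
#' monotone decrease of sampled Hamming distance in `w_d`) for the distance
#' restraint that hits the target mean Hamming distance, then measures how
#' often samples carry the positive-control mutations and the capped
#' mutation. Returns the exploration weight that maximizes the control
#' frequency subject to the cap (e.g. the most latent-weighted mutation held
#' below one-third of the library).
#'
#' @param model an `energy_model`
#' @param dec a [fit_latent()] decomposition
#' @param ref reference sequence
#' @param target_distance desired mean Hamming distance to the reference
#'   (> 0)
#' @param control_mutations character tokens counted as positive controls
#' @param cap_mutation token whose sampled frequency is capped
#' @param cap_fraction maximum allowed cap-mutation frequency, in (0, 1]
#' @param w_pca_grid exploration weights to screen
#' @param w_d_range bisection bracket for the distance weight
#' @param sweeps,burn_in sweep counts per evaluation
#' @param tol relative tolerance on the target distance
#' @param seed RNG seed
#' @return list: `w_d`, `w_pca`, `grid` (per-grid-point diagnostics)
#' @export
calibrate_bias_weights <- function(model, dec, ref, target_distance,
                                   control_mutations, cap_mutation,
                                   cap_fraction = 1 / 3,
                                   w_pca_grid = c(0, 10, 20, 40),
                                   w_d_range = c(0, 60), sweeps = 400,
                                   burn_in = 100, tol = 0.02, seed = 1L) {
  if (target_distance <= 0) stop("target_distance must be > 0")
  if (cap_fraction <= 0 || cap_fraction > 1)
    stop("cap_fraction must be in (0, 1]")
  ctrl <- token_state(control_mutations, model$alphabet)
  cap <- token_state(cap_mutation, model$alphabet)
  eval_point <- function(w_pca, w_d, sd) {
    cfg <- sampler_config(w_d = w_d, w_pca = w_pca, ref = ref, dec = dec,
                          sweeps = sweeps, burn_in = burn_in, seed = sd)
    s <- gibbs_sample(model, cfg)
    has <- function(tok) mean(apply(s$states, 1L, function(st)
      any(st[tok$pos] == tok$letter)))
    list(mean_dist = mean(s$hamming), ctrl = has(ctrl), cap = has(cap))
  }
  grid <- vector("list", length(w_pca_grid))
  for (i in seq_along(w_pca_grid)) {
    lo <- w_d_range[1]; hi <- w_d_range[2]
    wd <- NA_real_; res <- NULL
    for (it in seq_len(20L)) {
      mid <- (lo + hi) / 2
      res <- eval_point(w_pca_grid[i], mid, seed + 13L * i + it)
      if (abs(res$mean_dist - target_distance) <=
            tol * target_distance) { wd <- mid; break }
      if (res$mean_dist > target_distance) lo <- mid else hi <- mid
      wd <- mid
    }
    grid[[i]] <- data.frame(w_pca = w_pca_grid[i], w_d = wd,
                            mean_dist = res$mean_dist,
                            control_freq = res$ctrl, cap_freq = res$cap)
  }
  grid <- do.call(rbind, grid)
  feasible <- grid$cap_freq <= cap_fraction
  if (!any(feasible))
    stop("no exploration weight satisfies the cap constraint")
  best <- which(grid$control_freq == max(grid$control_freq[feasible]) &
                  feasible)[1L]
  list(w_d = grid$w_d[best], w_pca = grid$w_pca[best], grid = grid)
}

#' Binding-site shell specification
#'
#' @param structures list of bio3d `pdb` objects or PDB file paths
#' @param metal_element element symbol of the central metal (default "MN");
#'   its coordinates are taken from each structure's HETATM records, or
#'   supplied directly via `metal_xyz` (list of length-3 vectors)
#' @param metal_xyz optional explicit metal coordinates per structure
#' @param radius shell radius in Angstroms (> 0)
#' @param backgrounds variant backgrounds each design is emitted for
#' @return a `binding_site_spec`
#' @export
binding_site_spec <- function(structures, metal_element = "MN",
                              metal_xyz = NULL, radius = 12,
                              backgrounds = c("WT", "M230A")) {
  if (radius <= 0) stop("radius must be > 0")
  structures <- lapply(structures, function(s)
    if (is.character(s)) bio3d::read.pdb(s, verbose = FALSE) else s)
  if (is.null(metal_xyz)) {
    metal_xyz <- lapply(structures, function(p) {
      sel <- toupper(trimws(p$atom$elesy)) == toupper(metal_element)
      if (!any(sel)) stop("structure supplies no ", metal_element, " atom")
      unlist(p$atom[which(sel)[1L], c("x", "y", "z")])
    })
  }
  structure(list(structures = structures, metal_xyz = metal_xyz,
                 radius = radius, backgrounds = backgrounds),
            class = "binding_site_spec")
}

#' Load the bundled codon-usage table
#'
#' The packaged E. coli codon-usage table (codon, amino acid, frequency per
#' thousand) used to pick the most abundant codon for each amino acid.
#'
#' @return data.frame (codon, aa, per_thousand)
#' @export
codon_usage_table <- function() {
  utils::read.delim(system.file("extdata", "ecoli_codon_usage.tsv",
                                package = "dmscan"),
                    stringsAsFactors = FALSE)
}

#' Positions within the metal shell
#'
#' A position is in the shell if any non-hydrogen atom of its residue lies
#' within `radius` of the metal in any of the listed structures.
#'
#' @param spec a [binding_site_spec()]
#' @return sorted integer residue numbers
#' @export
shell_positions <- function(spec) {
  hits <- integer()
  for (i in seq_along(spec$structures)) {
    p <- spec$structures[[i]]
    at <- p$atom[p$atom$type == "ATOM" &
                   toupper(trimws(p$atom$elesy)) != "H", , drop = FALSE]
    m <- spec$metal_xyz[[i]]
    d <- sqrt((at$x - m[1])^2 + (at$y - m[2])^2 + (at$z - m[3])^2)
    hits <- union(hits, at$resno[d <= spec$radius])
  }
  sort(hits)
}

#' Enumerate the binding-site variant library
#'
#' For every shell position and every background: 19 missense variants
#' (each coded by the organism's most abundant codon for the target amino
#' acid), one synonymous variant when the WT amino acid has more than one
#' codon (its most abundant non-WT synonymous codon), and one codon
#' deletion.
#'
#' @param spec a [binding_site_spec()]
#' @param sequence protein sequence (string or letters), 1-based frame
#'   matching the structures' residue numbering
#' @param cds coding DNA string, length 3 * protein length (a trailing stop
#'   codon is tolerated)
#' @param usage codon-usage data.frame; default [codon_usage_table()]
#' @return data.frame (background, pos, type, wt_aa, new_aa, codon, variant)
#' @export
enumerate_binding_site_library <- function(spec, sequence, cds,
                                           usage = codon_usage_table()) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  cds <- toupper(cds)
  nres <- length(sequence)
  if (!(nchar(cds) == 3L * nres || nchar(cds) == 3L * (nres + 1L)))
    stop("CDS length must be 3 x protein length (+ optional stop)")
  usage <- usage[usage$aa %in% aa_alphabet(), , drop = FALSE]
  best <- do.call(rbind, lapply(split(usage, usage$aa), function(d)
    d[which.max(d$per_thousand), ]))
  pos_set <- shell_positions(spec)
  if (length(pos_set) && max(pos_set) > nres)
    stop("structure residue numbering exceeds the sequence length")
  rows <- list()
  for (bg in spec$backgrounds) for (p in pos_set) {
    wt_aa <- sequence[p]
    if (bg != "WT") {
      bm <- parse_variant_string(bg)$mutations
      hit <- bm$type == "sub" & bm$pos == p
      if (any(hit)) wt_aa <- bm$new[hit][1L]
    }
    wt_codon <- substr(cds, 3L * p - 2L, 3L * p)
    for (a in setdiff(aa_alphabet(), wt_aa)) {
      rows[[length(rows) + 1L]] <- data.frame(
        background = bg, pos = p, type = "missense",
        wt_aa = wt_aa, new_aa = a, codon = best$codon[best$aa == a],
        variant = paste0(wt_aa, p, a), stringsAsFactors = FALSE)
    }
    syn <- usage[usage$aa == wt_aa & usage$codon != wt_codon, ,
                 drop = FALSE]
    if (nrow(syn) > 0L) {
      sc <- syn$codon[which.max(syn$per_thousand)]
      rows[[length(rows) + 1L]] <- data.frame(
        background = bg, pos = p, type = "synonymous",
        wt_aa = wt_aa, new_aa = wt_aa, codon = sc,
        variant = "WT", stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      background = bg, pos = p, type = "deletion",
      wt_aa = wt_aa, new_aa = NA_character_, codon = NA_character_,
      variant = paste0("Δ", p), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(background = character(), pos = integer(),
                         type = character(), wt_aa = character(),
                         new_aa = character(), codon = character(),
                         variant = character())
  rownames(out) <- NULL
  out
}

#' Select the most-mutated positions of a sample set
#'
#' Ranks positions by their total non-reference frequency among sampled
#' sequences and returns the top K; ties break by position index, matching
#' a synthesis constraint of a bounded number of variable positions.
#'
#' @param samples integer or character matrix of sampled sequences
#'   (samples x L), e.g. `gibbs_sample()$states`
#' @param ref reference sequence (same representation as `samples`)
#' @param K number of positions (<= L); default 59
#' @return integer vector of selected positions, ascending
#' @export
select_design_positions <- function(samples, ref, K = 59) {
  L <- ncol(samples)
  if (K > L) stop("K must be <= L")
  if (is.character(ref) && length(ref) == 1L && nchar(ref) > 1L)
    ref <- strsplit(ref, "")[[1L]]
  freq <- colMeans(samples != matrix(ref, nrow(samples), L, byrow = TRUE))
  ord <- order(-freq, seq_len(L))
  sort(ord[seq_len(K)])
}

#' Per-position synthesis frequencies from model samples
#'
#' The independent-product distribution over the selected positions that
#' minimizes KL divergence to the sampled sequence distribution is simply
#' the per-position marginal; all other positions are fixed to the
#' reference. Correlations between positions are necessarily lost — a
#' documented limitation of per-position stochastic synthesis.
#'
#' @param samples matrix of sampled sequences (samples x L)
#' @param positions positions to leave variable
#' @param ref reference sequence
#' @param alphabet letters (default: the 20 amino acids plus gap)
#' @return a `synthesis_design`: list with `positions`, `freq` (list of
#'   named per-position frequency vectors summing to 1), `ref`
#' @export
fit_position_frequencies <- function(samples, positions, ref,
                                     alphabet = aa_alphabet(gap = TRUE)) {
  if (is.character(ref) && length(ref) == 1L && nchar(ref) > 1L)
    ref <- strsplit(ref, "")[[1L]]
  freq <- lapply(positions, function(p) {
    col <- samples[, p]
    if (is.numeric(col)) col <- alphabet[col]
    if (all(is.na(col)) || length(col) == 0L)
      stop("position ", p, " has no sample coverage")
    tab <- table(factor(col, levels = alphabet))
    stats::setNames(as.numeric(tab) / sum(tab), alphabet)
  })
  structure(list(positions = positions,
                 freq = stats::setNames(freq, positions), ref = ref),
            class = "synthesis_design")
}

#' Export a synthesis design as an order-sheet table
#'
#' @param design a [fit_position_frequencies()] design
#' @return data.frame (pos, aa, frequency), nonzero rows only
#' @export
design_table <- function(design) {
  out <- do.call(rbind, lapply(seq_along(design$positions), function(i) {
    f <- design$freq[[i]]
    f <- f[f > 0]
    data.frame(pos = design$positions[i], aa = names(f),
               frequency = as.numeric(f), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
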