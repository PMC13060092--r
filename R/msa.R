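# Alignment handling, sequence reweighting, site-independent (PSSM) model
# construction, and the PCA latent space used to bias library sampling.

#' Construct an amino-acid alignment
#'
#' @param seqs character vector of equal-length aligned sequences over the 20
#'   amino acids plus gap `-` (A2M dots and lowercase are normalized)
#' @param ids sequence identifiers
#' @param clade optional clade labels (kept by [simulate_msa()] for
#'   validation)
#' @return an `aa_alignment`: list with `ids`, character matrix `seqs`
#'   (n x L), and per-column `coverage` (fraction non-gap)
#' @export
aa_alignment <- function(seqs, ids = NULL, clade = NULL) {
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  n <- length(seqs)
  if (n == 0L) stop("empty alignment")
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("aligned sequences must have equal length")
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  bad <- !(mat %in% aa_alphabet(gap = TRUE))
  if (any(bad)) {
    mat[bad] <- "-"  # treat nonstandard letters (X, B, Z) as gaps
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  structure(list(ids = ids, seqs = mat,
                 coverage = colMeans(mat != "-"),
                 clade = clade),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " columns\n", sep = "")
  invisible(x)
}

#' Read an alignment from FASTA/A2M
#'
#' @param path FASTA or A2M file
#' @return an [aa_alignment()]
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  aa_alignment(as.character(ss), ids = names(ss))
}

#' Write an alignment to FASTA
#'
#' @param aln an [aa_alignment()]
#' @param path output path
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$ids, "\n", seqs), path)
  invisible(path)
}

#' One-hot encode an alignment
#'
#' Each column expands into 21 indicator columns (20 amino acids + gap),
#' giving an n x (L*21) matrix. Column ordering is position-major:
#' `(pos-1)*21 + letter`.
#'
#' @param aln an [aa_alignment()] or character matrix
#' @return numeric 0/1 matrix
#' @export
one_hot <- function(aln) {
  mat <- if (inherits(aln, "aa_alignment")) aln$seqs else aln
  alpha <- aa_alphabet(gap = TRUE)
  n <- nrow(mat); L <- ncol(mat); A <- length(alpha)
  idx <- matrix(match(mat, alpha), n, L)
  X <- matrix(0, n, L * A)
  off <- (col(idx) - 1L) * A + idx
  X[cbind(rep(seq_len(n), L), as.vector(off))] <- 1
  X
}

one_hot_seq <- function(seq, alpha = aa_alphabet(gap = TRUE)) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1L]]
  idx <- match(seq, alpha)
  if (anyNA(idx)) stop("sequence letter outside the amino-acid alphabet")
  A <- length(alpha)
  x <- numeric(length(seq) * A)
  x[(seq_along(seq) - 1L) * A + idx] <- 1
  x
}

#' Identity-threshold sequence reweighting
#'
#' Standard redundancy correction for alignments: each sequence receives
#' weight 1 / (number of sequences, itself included, with pairwise identity
#' >= theta). The effective number of sequences Meff is the sum of weights.
#'
#' @param aln an [aa_alignment()]
#' @param theta identity threshold in (0, 1]; default 0.8
#' @return list with `weights` (in (0,1]), `theta`, `meff`
#' @export
sequence_weights <- function(aln, theta = 0.8) {
  if (!(theta > 0 && theta <= 1)) stop("theta must be in (0, 1]")
  mat <- aln$seqs
  n <- nrow(mat); L <- ncol(mat)
  if (n == 0L) stop("empty alignment")
  # pairwise identity via one-hot inner products (gap treated as a letter)
  X <- one_hot(aln)
  id <- tcrossprod(X) / L
  neighbors <- rowSums(id >= theta)
  w <- 1 / neighbors
  list(weights = w, theta = theta, meff = sum(w))
}

#' Build a site-independent PSSM
#'
#' Weighted per-position amino-acid frequencies with a pseudocount,
#' renormalized over the 21-letter alphabet (20 amino acids + gap). Columns
#' below the coverage threshold are excluded from the model (mask `keep`)
#' but retain uniform probabilities so full-length energies stay finite.
#'
#' @param aln an [aa_alignment()]
#' @param weights optional [sequence_weights()] result (or numeric vector);
#'   default: unweighted
#' @param pseudocount pseudocount lambda added per letter (> 0)
#' @param min_coverage minimum column coverage retained in the model
#' @return a `pssm`: list with `prob` (21 x L), `logp`, `keep`, `alphabet`
#' @export
build_pssm <- function(aln, weights = NULL, pseudocount = 0.01,
                       min_coverage = 0.7) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  mat <- aln$seqs
  alpha <- aa_alphabet(gap = TRUE)
  A <- length(alpha); L <- ncol(mat)
  w <- if (is.null(weights)) rep(1, nrow(mat))
       else if (is.list(weights)) weights$weights else weights
  prob <- matrix(NA_real_, A, L, dimnames = list(alpha, NULL))
  for (j in seq_len(L)) {
    f <- vapply(alpha, function(a) sum(w[mat[, j] == a]), numeric(1))
    prob[, j] <- (f + pseudocount) / (sum(f) + A * pseudocount)
  }
  keep <- aln$coverage >= min_coverage
  prob[, !keep] <- 1 / A
  structure(list(prob = prob, logp = log(prob), keep = keep,
                 alphabet = alpha, pseudocount = pseudocount),
            class = "pssm")
}

#' PCA latent decomposition of an alignment
#'
#' Truncated SVD of the (column-centered) one-hot alignment matrix
#' X = U D V'. Rows of U*D are per-sequence embeddings; V columns are
#' directions in mutation space. The reference sequence's embedding `u0`
#' anchors latent-displacement calculations.
#'
#' @param aln an [aa_alignment()]
#' @param k number of components (default 2, where the design signal lives)
#' @param ref reference sequence (string or letter vector); default the first
#'   alignment row
#' @param weights optional [sequence_weights()] for a weighted PCA variant
#'   (sequences are scaled by sqrt(weight) before the SVD); default
#'   unweighted
#' @param center center columns before the SVD (default TRUE)
#' @return a `latent_decomposition`: list with `center`, `v` (L*21 x k),
#'   `d` (non-increasing singular values), `u`, `embeddings` (U*D), `u0`,
#'   `ref`
#' @export
fit_latent <- function(aln, k = 2, ref = NULL, weights = NULL,
                       center = TRUE) {
  if (k <= 0) stop("k must be positive")
  X <- one_hot(aln)
  if (k > min(dim(X))) stop("k exceeds min(n_seq, L*21)")
  if (!is.null(weights)) {
    w <- if (is.list(weights)) weights$weights else weights
    Xw <- X * sqrt(w)
  } else Xw <- X
  ctr <- if (center) colMeans(Xw) else numeric(ncol(X))
  Xc <- sweep(Xw, 2L, ctr)
  sv <- svd(Xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  dec <- structure(list(center = ctr, v = sv$v, d = d, u = sv$u,
                        embeddings = sv$u %*% diag(d, k, k),
                        L = ncol(aln$seqs), k = k,
                        alphabet = aa_alphabet(gap = TRUE)),
                   class = "latent_decomposition")
  if (is.null(ref)) ref <- aln$seqs[1L, ]
  if (length(ref) == 1L && nchar(ref) > 1L) ref <- strsplit(ref, "")[[1L]]
  dec$ref <- ref
  dec$u0 <- embed_sequence(dec, ref)
  dec
}

#' @export
print.latent_decomposition <- function(x, ...) {
  cat("<latent_decomposition> k = ", x$k, ", L = ", x$L,
      ", singular values: ", paste(signif(x$d, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Embed a sequence in the latent space
#'
#' Projects a full-length sequence onto the decomposition:
#' u = (onehot(seq) - center) V. The latent displacement from the reference
#' is `sqrt(sum((u - u0)^2))` (see [latent_distance()]).
#'
#' @param dec a [fit_latent()] decomposition
#' @param seq sequence (string or letter vector) of alignment length
#' @return numeric embedding of length k
#' @export
embed_sequence <- function(dec, seq) {
  x <- one_hot_seq(seq, dec$alphabet)
  if (length(x) != length(dec$center))
    stop("sequence length does not match alignment columns")
  drop((x - dec$center) %*% dec$v)
}

#' Latent displacement of a sequence from the reference
#'
#' @param dec a [fit_latent()] decomposition
#' @param seq sequence of alignment length
#' @return Euclidean distance between the sequence's embedding and `u0`
#' @export
latent_distance <- function(dec, seq) {
  sqrt(sum((embed_sequence(dec, seq) - dec$u0)^2))
}

#' Rank mutations by latent-component weight
#'
#' For each position and non-reference letter, the mutation's weight is the
#' Euclidean norm (over the first two components, or all components when
#' k < 2) of the difference between the letter's and the reference letter's
#' rows of V — exactly the latent displacement a single substitution causes.
#' Ties break by position then alphabet order.
#'
#' @param dec a [fit_latent()] decomposition
#' @param n number of top mutations to return (truncated to what exists)
#' @return data.frame (pos, aa, weight), sorted by decreasing weight
#' @export
top_latent_mutations <- function(dec, n = 50) {
  if (n < 1) stop("n must be >= 1")
  A <- length(dec$alphabet)
  comp <- seq_len(min(2L, dec$k))
  out <- vector("list", dec$L)
  for (pos in seq_len(dec$L)) {
    ref_letter <- dec$ref[pos]
    ref_row <- dec$v[(pos - 1L) * A + match(ref_letter, dec$alphabet),
                     comp, drop = FALSE]
    others <- setdiff(dec$alphabet, ref_letter)
    rows <- dec$v[(pos - 1L) * A + match(others, dec$alphabet),
                  comp, drop = FALSE]
    w <- sqrt(rowSums((rows - ref_row[rep(1L, length(others)), ,
                                      drop = FALSE])^2))
    out[[pos]] <- data.frame(pos = pos, aa = others, weight = w,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(-tab$weight, tab$pos, tab$aa), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, n)
}
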