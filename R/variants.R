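# Variant notation: substitutions "M230A", deletions "Δ230" (alias
# "del230"), insertions "ins230A"; multi-mutation variants joined with "+".
# Residue numbering is 1-based in the protein frame.

#' Amino-acid alphabet
#'
#' The 20 standard amino acids, optionally with the gap character `-` used as
#' a 21st state when encoding alignments.
#'
#' @param gap include the gap character as a 21st letter
#' @return character vector of single-letter codes
#' @export
aa_alphabet <- function(gap = FALSE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (gap) c(aa, "-") else aa
}

new_variant_id <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  if (nrow(mutations) > 1) {
    mutations <- mutations[order(mutations$pos), , drop = FALSE]
    rownames(mutations) <- NULL
  }
  sub_pos <- mutations$pos[mutations$type == "sub"]
  if (anyDuplicated(sub_pos))
    stop("duplicate substitution indices: ",
         paste(sub_pos[duplicated(sub_pos)], collapse = ", "))
  structure(list(mutations = mutations), class = "variant_id")
}

empty_mutation_df <- function() {
  data.frame(type = character(), wt = character(), pos = integer(),
             new = character(), stringsAsFactors = FALSE)
}

#' Parse a variant string
#'
#' Parses the compact mutation notation used throughout the package
#' ("M230A", "Y54F+E134N", "Δ230"/"del230", "ins230A", "WT") into a
#' `variant_id` object. Tokens are canonically ordered by residue index, so
#' `render_variant(parse_variant_string(s))` is the identity on canonical
#' strings.
#'
#' @param s variant string (non-empty); `"WT"` denotes the identity variant
#' @param length optional protein length used to validate residue indices
#' @return a `variant_id`: list with a `mutations` data frame
#'   (columns `type` in sub/del/ins, `wt`, `pos`, `new`)
#' @export
parse_variant_string <- function(s, length = NULL) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("variant string must be a single non-empty string")
  if (identical(s, "WT")) return(new_variant_id(empty_mutation_df()))
  tokens <- strsplit(s, "+", fixed = TRUE)[[1L]]
  aa <- aa_alphabet()
  rows <- lapply(tokens, function(tok) {
    if (grepl("^[A-Z][0-9]+[A-Z]$", tok)) {
      wt <- substr(tok, 1L, 1L)
      new <- substr(tok, nchar(tok), nchar(tok))
      pos <- as.integer(substr(tok, 2L, nchar(tok) - 1L))
      if (!(wt %in% aa) || !(new %in% aa))
        stop("unknown amino-acid letter in token '", tok, "'")
      data.frame(type = "sub", wt = wt, pos = pos, new = new,
                 stringsAsFactors = FALSE)
    } else if (grepl("^(Δ|del)[0-9]+$", tok)) {
      pos <- as.integer(sub("^(Δ|del)", "", tok))
      data.frame(type = "del", wt = NA_character_, pos = pos,
                 new = NA_character_, stringsAsFactors = FALSE)
    } else if (grepl("^ins[0-9]+[A-Z]$", tok)) {
      new <- substr(tok, nchar(tok), nchar(tok))
      pos <- as.integer(substr(tok, 4L, nchar(tok) - 1L))
      if (!(new %in% aa))
        stop("unknown amino-acid letter in token '", tok, "'")
      data.frame(type = "ins", wt = NA_character_, pos = pos, new = new,
                 stringsAsFactors = FALSE)
    } else {
      stop("malformed variant token '", tok, "'")
    }
  })
  mut <- do.call(rbind, rows)
  if (!is.null(length) && any(mut$pos < 1L | mut$pos > length))
    stop("residue index outside protein length in '", s, "'")
  new_variant_id(mut)
}

#' Render a variant to its canonical string
#'
#' @param v a `variant_id`
#' @return canonical string; the WT (empty) variant renders as `"WT"`
#' @export
render_variant <- function(v) {
  stopifnot(inherits(v, "variant_id"))
  m <- v$mutations
  if (nrow(m) == 0L) return("WT")
  tok <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    tok[i] <- switch(m$type[i],
      sub = paste0(m$wt[i], m$pos[i], m$new[i]),
      del = paste0("Δ", m$pos[i]),
      ins = paste0("ins", m$pos[i], m$new[i]))
  }
  paste(tok, collapse = "+")
}

#' @export
print.variant_id <- function(x, ...) {
  cat("<variant_id> ", render_variant(x), "\n", sep = "")
  invisible(x)
}

#' Mutation tokens of a variant
#'
#' @param v a `variant_id` or variant string
#' @return character vector of canonical single-mutation tokens (empty for WT)
#' @export
variant_tokens <- function(v) {
  if (is.character(v)) v <- parse_variant_string(v)
  m <- v$mutations
  if (nrow(m) == 0L) return(character())
  vapply(seq_len(nrow(m)), function(i)
    render_variant(new_variant_id(m[i, , drop = FALSE])), character(1))
}

#' Apply substitutions to a sequence
#'
#' Applies the substitution tokens of a variant to a wild-type sequence
#' (deletions and insertions change coordinates and are not supported here).
#'
#' @param seq character vector of single letters, or a single string
#' @param v `variant_id` or variant string
#' @return mutated sequence as a character vector of single letters
#' @export
apply_substitutions <- function(seq, v) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1L]]
  if (is.character(v)) v <- parse_variant_string(v)
  m <- v$mutations
  if (any(m$type != "sub")) stop("only substitution tokens can be applied")
  for (i in seq_len(nrow(m))) {
    if (m$pos[i] > length(seq)) stop("substitution index beyond sequence end")
    seq[m$pos[i]] <- m$new[i]
  }
  seq
}
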