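# Barcode extraction/counting and count-table I/O shared by all stages.

#' Barcode pattern
#'
#' Describes the degenerate barcode inserted next to the coding sequence: an
#' 18-nt IUPAC template restricted to the codes N (any), S (G/C) and W (A/T),
#' flanked by fixed sequences used to locate it in a read.
#'
#' @param template IUPAC string, length 18, letters in \{A,C,G,T,N,S,W\}
#' @param flank5,flank3 fixed DNA immediately 5' and 3' of the barcode
#' @return a `barcode_pattern` object
#' @export
barcode_pattern <- function(template = "NNNNSWNNNNSWNNNNSW",
                            flank5 = "", flank3 = "") {
  if (nchar(template) != 18L)
    stop("barcode template must have length 18")
  letters <- strsplit(template, "")[[1L]]
  if (!all(letters %in% c("A", "C", "G", "T", "N", "S", "W")))
    stop("template degenerate codes restricted to N, S, W (plus fixed ACGT)")
  structure(list(template = template, flank5 = toupper(flank5),
                 flank3 = toupper(flank3)),
            class = "barcode_pattern")
}

#' Check barcodes against a template
#'
#' @param barcodes character vector of candidate barcodes
#' @param pattern a [barcode_pattern()]
#' @return logical vector: does each barcode satisfy the template
#'   (S matches only G/C, W only A/T, N any base)?
#' @export
matches_template <- function(barcodes, pattern) {
  tmpl <- strsplit(pattern$template, "")[[1L]]
  re <- paste0("^", paste(vapply(tmpl, function(ch) switch(ch,
    N = "[ACGT]", S = "[GC]", W = "[AT]", ch), character(1)),
    collapse = ""), "$")
  grepl(re, barcodes)
}

#' Count barcodes in merged reads
#'
#' Extracts the barcode between the two fixed flanks of each read (exact
#' match, no mismatch tolerance), validates it against the degenerate
#' template, and tallies reads per mapped variant. Reads without both flanks
#' are counted as unparsed; template-violating and unmapped barcodes are
#' tallied separately, so mapped + unmapped + template_violating + unparsed
#' always equals the number of input reads.
#'
#' @param reads character vector of merged read sequences (or a FASTQ/FASTA
#'   path, read with Biostrings when available)
#' @param pattern a [barcode_pattern()]
#' @param map named character vector: barcode -> variant string
#' @return list with `counts` (data.frame variant/count), `unmapped`,
#'   `template_violating`, `unparsed`, `n_reads`
#' @export
count_barcodes <- function(reads, pattern, map) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  if (length(map) && any(nchar(names(map)) != nchar(pattern$template)))
    stop("map keys must match template length")
  if (length(reads) == 1L && file.exists(reads)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTQ/FASTA files requires the Biostrings package")
    fmt <- if (grepl("\\.(fq|fastq)$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  reads <- toupper(reads)
  blen <- nchar(pattern$template)
  i5 <- regexpr(pattern$flank5, reads, fixed = TRUE)
  start <- i5 + attr(i5, "match.length")
  bc <- substr(reads, start, start + blen - 1L)
  has3 <- substr(reads, start + blen,
                 start + blen + nchar(pattern$flank3) - 1L) == pattern$flank3
  parsed <- i5 > 0L & nchar(bc) == blen & has3
  bc <- bc[parsed]
  ok_tmpl <- matches_template(bc, pattern)
  mapped_variant <- map[bc[ok_tmpl]]
  is_mapped <- !is.na(mapped_variant)
  counts <- if (any(is_mapped)) {
    tab <- table(mapped_variant[is_mapped])
    data.frame(variant = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(variant = character(), count = integer())
  }
  list(counts = counts,
       unmapped = sum(!is_mapped),
       template_violating = sum(!ok_tmpl),
       unparsed = sum(!parsed),
       n_reads = length(reads))
}

#' Read / write count tables
#'
#' Count tables are long-format TSV with columns `id`, `sample`, `count`
#' (non-negative integers); sample metadata (total reads, sorted cells per
#' bin) travels alongside as attributes when present.
#'
#' @param path file path
#' @return data.frame with columns id, sample, count
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sample", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns id, sample, count")
  if (any(df$count < 0)) stop("counts must be non-negative")
  df
}

#' @rdname read_count_table
#' @param df count table data.frame
#' @export
write_count_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
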