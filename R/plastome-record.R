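#' Construct a plastome record
#'
#' The unit every downstream stage consumes: a (usually circular) nucleotide
#' sequence over \code{{A,C,G,T,N}} plus typed gene features. Sequences are
#' case-normalized to upper case at construction.
#'
#' @param identifier Record identifier (accession or name).
#' @param sequence Nucleotide string.
#' @param is_circular Is the molecule circular?
#' @param features List of \code{\link{gene_feature}} objects.
#' @param source Provenance (file path or accession); free text.
#' @return Object of class \code{plastome_record}.
#' @export
plastome_record <- function(identifier, sequence, is_circular = TRUE,
                            features = list(), source = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence of '", identifier, "' contains non-nucleotide characters")
  for (f in features) {
    for (p in f$parts) {
      if (p$end > n && !p$wraps)
        stop("feature '", f$name, "' extends beyond sequence length ", n)
    }
  }
  structure(list(identifier = identifier, sequence = sequence,
                 is_circular = isTRUE(is_circular), features = features,
                 source = source),
            class = "plastome_record")
}

#' Construct a gene feature
#'
#' @param name Gene symbol (tRNAs canonicalized as \code{trnX_ANTICODON}).
#' @param kind One of \code{"CDS"}, \code{"tRNA"}, \code{"rRNA"}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param parts List of \code{\link{interval}}s (exons) in biological order.
#' @param is_pseudo Pseudogene flag.
#' @return Object of class \code{gene_feature}.
#' @export
gene_feature <- function(name, kind = c("CDS", "tRNA", "rRNA"),
                         strand = c("+", "-"), parts, is_pseudo = FALSE) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (inherits(parts, "interval")) parts <- list(parts)
  stopifnot(length(parts) >= 1L)
  structure(list(name = name, kind = kind, strand = strand, parts = parts,
                 is_pseudo = isTRUE(is_pseudo)),
            class = "gene_feature")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d feature(s)\n",
              x$identifier, format(nchar(x$sequence), big.mark = ","),
              if (x$is_circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

# span of a feature across its parts (non-wrapping features only)
.feature_span <- function(f) {
  s <- min(vapply(f$parts, function(p) p$start, integer(1)))
  e <- max(vapply(f$parts, function(p) p$end, integer(1)))
  c(start = s, end = e)
}

#' Extract a region of a record
#'
#' Returns the bases covered by \code{iv}; wrapping intervals (allowed only on
#' circular records) concatenate the suffix from \code{start} with the prefix
#' up to \code{end}.
#'
#' @param record A \code{plastome_record}.
#' @param iv An \code{\link{interval}}.
#' @return Nucleotide string of length \code{interval_length(iv, n)}.
#' @export
extract_region <- function(record, iv) {
  n <- nchar(record$sequence)
  if (iv$wraps) {
    if (!record$is_circular)
      stop("wrapping interval on a non-circular record")
    paste0(substr(record$sequence, iv$start + 1L, n),
           substr(record$sequence, 1L, iv$end))
  } else {
    if (iv$end > n) stop("interval exceeds sequence length")
    substr(record$sequence, iv$start + 1L, iv$end)
  }
}

# reverse complement of a plain character string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
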