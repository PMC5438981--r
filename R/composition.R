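# round half away from zero, matching how printed tables round
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Base composition of a sequence
#'
#' AT and GC percentages over the unambiguous bases; ambiguous bases (N) are
#' excluded from both tallies and from the denominator, and reported
#' separately. Percentages are rounded half-up to \code{digits} decimals
#' (1 by default, matching the precision most comparative tables print).
#'
#' @param seq Nucleotide string.
#' @param digits Decimals to round to.
#' @return Object of class \code{composition_summary} with fields
#'   \code{at_percent}, \code{gc_percent}, \code{length_bp},
#'   \code{ambiguous_bp}.
#' @export
composition <- function(seq, digits = 1) {
  stopifnot(nchar(seq) > 0)
  seq <- toupper(seq)
  counts <- table(factor(strsplit(seq, "")[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  unamb <- sum(counts[c("A", "C", "G", "T")])
  if (unamb == 0) stop("composition undefined: sequence is all ambiguous")
  gc <- 100 * sum(counts[c("G", "C")]) / unamb
  at <- 100 * sum(counts[c("A", "T")]) / unamb
  structure(list(at_percent = round_half_up(at, digits),
                 gc_percent = round_half_up(gc, digits),
                 length_bp = nchar(seq),
                 ambiguous_bp = as.integer(counts["N"])),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("%s bp: AT %.*f%%, GC %.*f%% (%d ambiguous)\n",
              format(x$length_bp, big.mark = ","), 2, x$at_percent, 2,
              x$gc_percent, x$ambiguous_bp))
  invisible(x)
}

#' Fraction of reads assigned to the plastome
#'
#' Percentage of sequencing reads mapping to the chloroplast genome, rounded
#' half-up to two decimals as printed in assembly summaries.
#'
#' @param cp_reads Reads assigned to the plastome.
#' @param total_reads Total reads generated.
#' @return Percentage (2 decimals).
#' @export
read_fraction <- function(cp_reads, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (cp_reads < 0 || cp_reads > total_reads)
    stop("cp_reads must lie in [0, total_reads]")
  round_half_up(100 * cp_reads / total_reads, 2)
}
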