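#' Construct a primer pair
#'
#' @param forward,reverse Primer sequences, 5'->3', unambiguous, >= 15 nt.
#' @param name Pair name.
#' @return Object of class \code{primer_pair}.
#' @export
primer_pair <- function(forward, reverse, name = "primer_pair") {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15) stop("primers must be at least 15 nt")
    if (grepl("[^ACGT]", p)) stop("primers must be unambiguous A/C/G/T")
  }
  structure(list(forward = forward, reverse = reverse, name = name),
            class = "primer_pair")
}

# best local alignment of a reference exon against a region (both strands);
# returns reference bases covered when identity clears the threshold.
# The raw local alignment is trimmed to its best-scoring core under a
# stricter column score (+1 match / -3 otherwise) so lucky low-identity
# extensions into flanking sequence do not inflate the retained length.
.exon_retention <- function(region_seq, ref_exon, min_identity) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE, type = "DNA")
  best <- 0L
  for (subj in c(region_seq, revcomp(region_seq))) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(ref_exon),
      subject = Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    if (Biostrings::score(al) <= 0) next
    pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    su <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    colmatch <- pa == su & pa != "-" & su != "-"
    # maximal-scoring window (Kadane) under the trim score
    sc <- ifelse(colmatch, 1, -3)
    bi <- 0L; bj <- -1L; bs <- 0
    cur <- 0; ci <- 1L
    for (j in seq_along(sc)) {
      cur <- cur + sc[j]
      if (cur > bs) { bs <- cur; bi <- ci; bj <- j }
      if (cur < 0) { cur <- 0; ci <- j + 1L }
    }
    if (bj < bi) next
    win <- bi:bj
    idn <- sum(colmatch[win]) / length(win)
    cov <- sum(pa[win] != "-")
    if (idn >= min_identity && cov > best) best <- as.integer(cov)
  }
  best
}

#' Classify the integrity of the rps16 locus
#'
#' Searches a region (the trnK_UUU--trnQ_UUG neighbourhood, or a whole
#' genome) for each of the two rps16 exons by affine-gap local alignment
#' (match 1 / mismatch -1 / gap open -2 / extend -1) and derives a
#' five-state integrity class from how much of each reference exon is
#' recovered at \code{min_identity} or better:
#' \itemize{
#'   \item \code{INTACT}: both exons essentially full length
#'     (>= \code{full_frac} of the reference);
#'   \item \code{EXON2_PARTIAL}: exon 2 anchored (>= \code{anchor_bp}) but
#'     truncated below \code{full_frac};
#'   \item \code{EXON2_LOST}: exon 1 retained, exon 2 below the anchor;
#'   \item \code{EXON1_LOST}: exon 2 essentially full, exon 1 below the
#'     anchor;
#'   \item \code{COMPLETE_LOSS}: neither exon anchored.
#' }
#' The anchor and full-length thresholds make the loss spectrum decidable
#' between its endpoint states and are exposed for tuning.
#'
#' @param region_seq Nucleotide string to search.
#' @param ref_exon1,ref_exon2 Reference exon sequences from an intact
#'   relative (defaults: \code{\link{rps16_reference_exons}}).
#' @param min_identity Minimum alignment identity (default 0.8).
#' @param anchor_bp Minimum aligned reference bases to call an exon present
#'   at all (default 20).
#' @param full_frac Fraction of the reference that must align to call an
#'   exon full length (default 0.9).
#' @return Object of class \code{rps16_status}: \code{class} plus
#'   \code{retained_bp} per exon.
#' @export
classify_rps16 <- function(region_seq,
                           ref_exon1 = rps16_reference_exons()$exon1,
                           ref_exon2 = rps16_reference_exons()$exon2,
                           min_identity = 0.8, anchor_bp = 20,
                           full_frac = 0.9) {
  if (is.null(ref_exon1) || is.null(ref_exon2) ||
      !nzchar(ref_exon1) || !nzchar(ref_exon2))
    stop("reference exons must be non-empty")
  r1 <- .exon_retention(region_seq, ref_exon1, min_identity)
  r2 <- .exon_retention(region_seq, ref_exon2, min_identity)
  full1 <- r1 >= full_frac * nchar(ref_exon1)
  full2 <- r2 >= full_frac * nchar(ref_exon2)
  pres1 <- r1 >= anchor_bp
  pres2 <- r2 >= anchor_bp
  cls <- if (full1 && full2) "INTACT"
    else if (pres2 && !full2) "EXON2_PARTIAL"
    else if (!pres1 && !pres2) "COMPLETE_LOSS"
    else if (pres1 && !pres2) "EXON2_LOST"
    else "EXON1_LOST"  # exon 2 retained, exon 1 below anchor
  structure(list(class = cls,
                 retained_bp = c(exon1 = r1, exon2 = r2)),
            class = "rps16_status")
}

#' @export
print.rps16_status <- function(x, ...) {
  cat(sprintf("rps16: %s (exon1 %d bp, exon2 %d bp retained)\n",
              x$class, x$retained_bp["exon1"], x$retained_bp["exon2"]))
  invisible(x)
}

# plus-strand binding sites of a primer on template string s:
# list of (start, end) 1-based footprints with an exact 3'-terminal base
.primer_sites <- function(s, primer, max_mismatch, minus = FALSE) {
  pat <- if (minus) revcomp(primer) else primer
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                Biostrings::DNAString(s),
                                max.mismatch = max_mismatch)
  st <- Biostrings::start(m); en <- Biostrings::end(m)
  if (length(st) == 0) return(data.frame(start = integer(0), end = integer(0)))
  # 3' end of the primer: last plus-strand base for "+", first for "-"
  keep <- if (minus) substring(s, st, st) == substr(pat, 1, 1)
          else substring(s, en, en) == substr(pat, nchar(pat), nchar(pat))
  data.frame(start = st[keep], end = en[keep])
}

#' Predict PCR amplicons in silico
#'
#' Finds every template site where one primer binds the plus strand and the
#' other binds the minus strand downstream, with at most \code{max_mismatch}
#' mismatches per primer, an exact 3'-terminal base, non-overlapping
#' footprints, and a product no longer than \code{max_amplicon}. Product
#' length is the distance between the outer primer ends, inclusive of both
#' footprints (standard PCR sizing). Circular templates are scanned across
#' the origin.
#'
#' @param template A \code{\link{plastome_record}} or nucleotide string.
#' @param primers A \code{\link{primer_pair}}.
#' @param max_amplicon Maximum product length (bp, default 3000).
#' @param max_mismatch Mismatches tolerated per primer (default 0).
#' @return List of amplicons, each with \code{start}, \code{end} (0-based
#'   half-open template interval), \code{length_bp},
#'   \code{strand_of_forward}; empty list when there is no product.
#' @export
insilico_pcr <- function(template, primers, max_amplicon = 3000,
                         max_mismatch = 0) {
  s <- if (inherits(template, "plastome_record")) template$sequence
       else toupper(template)
  circular <- inherits(template, "plastome_record") && template$is_circular
  n <- nchar(s)
  if (n < max(nchar(primers$forward), nchar(primers$reverse))) return(list())
  ext <- if (circular) min(max_amplicon, n) else 0L
  s2 <- if (ext > 0) paste0(s, substr(s, 1L, ext)) else s
  configs <- list(
    list(plus = primers$forward, minus = primers$reverse, fwd_strand = "+"),
    list(plus = primers$reverse, minus = primers$forward, fwd_strand = "-"))
  out <- list()
  for (cf in configs) {
    a <- .primer_sites(s2, cf$plus, max_mismatch, minus = FALSE)
    b <- .primer_sites(s2, cf$minus, max_mismatch, minus = TRUE)
    if (nrow(a) == 0 || nrow(b) == 0) next
    for (i in seq_len(nrow(a))) {
      if (a$start[i] > n) next  # origin-shifted duplicate
      hit <- which(b$start > a$end[i] &
                   (b$end - a$start[i] + 1L) <= max_amplicon)
      for (j in hit) {
        out[[length(out) + 1L]] <- list(
          start = a$start[i] - 1L,
          end = b$end[j],           # half-open
          length_bp = b$end[j] - a$start[i] + 1L,
          strand_of_forward = cf$fwd_strand)
      }
    }
  }
  out[order(vapply(out, `[[`, 0L, "start"),
            vapply(out, `[[`, 0L, "length_bp"))]
}

#' Call the Veratrum section from rps16 amplicon sizes
#'
#' Pure size-based rule on products of the rps16 primer pair: a single
#' product of 1200--1800 bp (exon 1 retained) calls sect. Veratrum; a single
#' product of 300--500 bp (whole locus deleted) calls sect. Fuscoveratrum;
#' anything else is indeterminate.
#'
#' @param amplicons List of amplicons from \code{\link{insilico_pcr}}.
#' @return \code{"sect. Veratrum"}, \code{"sect. Fuscoveratrum"} or
#'   \code{"indeterminate"}.
#' @export
veratrum_section_call <- function(amplicons) {
  if (length(amplicons) != 1) return("indeterminate")
  len <- amplicons[[1]]$length_bp
  if (len >= 1200 && len <= 1800) return("sect. Veratrum")
  if (len >= 300 && len <= 500) return("sect. Fuscoveratrum")
  "indeterminate"
}
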