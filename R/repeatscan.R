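#' Count trnI_CAU copies by sequence similarity
#'
#' Ungapped similarity scan for copies of a reference trnI_CAU on either
#' strand: full-length windows whose identity to the reference reaches
#' \code{min_identity} qualify (truncated terminal copies covering at least
#' 95\% of the reference also qualify). Hits are selected greedily,
#' best-first (fewest mismatches, then leftmost), without overlap.
#' Detection is sequence-based rather than annotation-based so that
#' under-annotated records still count their duplicated copies.
#'
#' @param seq Nucleotide string to scan.
#' @param ref_trnI Reference trnI_CAU sequence (60--100 nt;
#'   default \code{\link{trnI_reference}}).
#' @param min_identity Minimum identity (default 0.95).
#' @return List of hits, each an \code{\link{interval}} (0-based half-open)
#'   with attributes \code{strand} and \code{mismatches}; empty list when
#'   there is no copy.
#' @export
count_trnI <- function(seq, ref_trnI = trnI_reference(), min_identity = 0.95) {
  L <- nchar(ref_trnI)
  if (L < 60 || L > 100) stop("ref_trnI must be 60-100 nt")
  seq <- toupper(seq)
  n <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  allowed <- floor(L * (1 - min_identity))
  cands <- data.frame(start = integer(0), len = integer(0), mm = integer(0),
                      strand = character(0))
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") ref_trnI else revcomp(ref_trnI)
    pv <- strsplit(pat, "")[[1]]
    if (n >= L) {
      mm <- integer(n - L + 1L)
      for (j in seq_len(L)) mm <- mm + (x[j:(n - L + j)] != pv[j])
      hit <- which(mm <= allowed)
      if (length(hit))
        cands <- rbind(cands, data.frame(start = hit, len = L, mm = mm[hit],
                                         strand = strand))
    }
    # truncated terminal copies covering >= 95% of the reference
    Lmin <- ceiling(0.95 * L)
    Lts <- if (min(L - 1L, n) >= Lmin) seq(Lmin, min(L - 1L, n)) else integer(0)
    for (Lt in Lts) {
      al <- floor(Lt * (1 - min_identity))
      # suffix of pattern at sequence start
      if (sum(x[1:Lt] != pv[(L - Lt + 1L):L]) <= al)
        cands <- rbind(cands, data.frame(start = 1L, len = Lt,
                                         mm = sum(x[1:Lt] != pv[(L - Lt + 1L):L]),
                                         strand = strand))
      # prefix of pattern at sequence end
      if (sum(x[(n - Lt + 1L):n] != pv[1:Lt]) <= al)
        cands <- rbind(cands, data.frame(start = n - Lt + 1L, len = Lt,
                                         mm = sum(x[(n - Lt + 1L):n] != pv[1:Lt]),
                                         strand = strand))
    }
  }
  if (nrow(cands) == 0) return(list())
  cands <- cands[order(cands$mm, cands$start), , drop = FALSE]
  taken <- logical(n)
  hits <- list()
  for (i in seq_len(nrow(cands))) {
    span <- cands$start[i]:(cands$start[i] + cands$len[i] - 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    h <- interval(cands$start[i] - 1L, cands$start[i] - 1L + cands$len[i])
    attr(h, "strand") <- cands$strand[i]
    attr(h, "mismatches") <- cands$mm[i]
    hits[[length(hits) + 1L]] <- h
  }
  hits[order(vapply(hits, `[[`, 0L, "start"))]
}

#' Construct a tandem repeat array record
#'
#' @param unit_seq Sequence of the first (consensus) copy.
#' @param unit_len Unit length in bp.
#' @param copies Integer copy count.
#' @param start 0-based start of the tract.
#' @param identity Mean per-copy identity to the first copy.
#' @param tail_bp Length of a partial trailing copy (reported separately).
#' @return Object of class \code{tandem_repeat_array}.
#' @export
tandem_repeat_array <- function(unit_seq, unit_len, copies, start,
                                identity = 1, tail_bp = 0L) {
  structure(list(unit_seq = unit_seq, unit_len = as.integer(unit_len),
                 copies = as.integer(copies), start = as.integer(start),
                 identity = identity, tail_bp = as.integer(tail_bp)),
            class = "tandem_repeat_array")
}

#' @export
print.tandem_repeat_array <- function(x, ...) {
  cat(sprintf("tandem repeat: %d bp x %d @%d (id %.3f%s)\n", x$unit_len,
              x$copies, x$start, x$identity,
              if (x$tail_bp > 0) paste0(", +", x$tail_bp, " bp tail") else ""))
  invisible(x)
}

#' Detect tandem repeat arrays
#'
#' Reports maximal tandem tracts: for every start and period in
#' \code{[min_unit, max_unit]}, the run of consecutive copies whose
#' per-copy Hamming identity to the first copy (the consensus) is at least
#' \code{1 - max_mismatch_frac}. Overlapping reports are collapsed to the
#' tract with the most copies, ties broken by higher copy identity, then
#' smaller period, then smaller start, so each genomic segment is reported
#' once and an exact tract is preferred over a mismatch-tolerated shift of
#' itself. A partial trailing copy is reported as \code{tail_bp}, never as
#' an extra unit.
#'
#' @param seq Nucleotide string.
#' @param min_unit,max_unit Period bounds in bp (defaults 18 and 250; the
#'   18 bp floor matches the unit-size threshold comparative tables use).
#' @param min_copies Minimum integer copies to report (default 2).
#' @param max_mismatch_frac Tolerated per-copy mismatch fraction vs. the
#'   first copy (default 0.1).
#' @return List of \code{\link{tandem_repeat_array}}s, ordered by start.
#' @export
find_tandem_repeats <- function(seq, min_unit = 18, max_unit = 250,
                                min_copies = 2, max_mismatch_frac = 0.1) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * min_unit) return(list())
  x <- strsplit(seq, "")[[1]]
  cands <- list()
  for (p in min_unit:min(max_unit, n %/% 2L)) {
    allowed <- floor(p * max_mismatch_frac)
    d <- x[1:(n - p)] != x[(p + 1L):n]
    cs <- c(0L, cumsum(d))
    # adjacent-block mismatches for a head at s (1-based): sum d[s..s+p-1]
    smax <- n - 2L * p + 1L
    if (smax < 1L) next
    heads <- which((cs[(1:smax) + p] - cs[1:smax]) <= allowed)
    if (length(heads) == 0) next
    for (s in heads) {
      unit <- x[s:(s + p - 1L)]
      copies <- 1L
      idsum <- 0
      repeat {
        b0 <- s + copies * p
        if (b0 + p - 1L > n) break
        mm <- sum(x[b0:(b0 + p - 1L)] != unit)
        if (mm > allowed) break
        copies <- copies + 1L
        idsum <- idsum + (1 - mm / p)
      }
      if (copies < min_copies) next
      # partial trailing copy: longest prefix within per-length tolerance
      tail_bp <- 0L
      t0 <- s + copies * p
      tmax <- min(p - 1L, n - t0 + 1L)
      if (tmax > 0L) {
        tm <- cumsum(x[t0:(t0 + tmax - 1L)] != unit[1:tmax])
        ok <- which(tm <= floor(seq_len(tmax) * max_mismatch_frac))
        if (length(ok)) tail_bp <- max(ok)
      }
      idn <- if (copies > 1) (1 + idsum) / copies else 1
      cands[[length(cands) + 1L]] <- tandem_repeat_array(
        paste(unit, collapse = ""), p, copies, s - 1L, idn, tail_bp)
    }
  }
  if (length(cands) == 0) return(list())
  ord <- order(-vapply(cands, `[[`, 0L, "copies"),
               -vapply(cands, `[[`, 0, "identity"),
               vapply(cands, `[[`, 0L, "unit_len"),
               vapply(cands, `[[`, 0L, "start"))
  taken <- logical(n)
  kept <- list()
  for (i in ord) {
    a <- cands[[i]]
    span <- (a$start + 1L):(a$start + a$copies * a$unit_len + a$tail_bp)
    if (any(taken[span])) next
    taken[span] <- TRUE
    kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, `[[`, 0L, "start"))]
}

#' Total repeat units across arrays
#'
#' Sums integer copy counts over arrays whose unit length reaches
#' \code{min_unit} -- the per-record unit count that comparative spacer
#' tables report.
#'
#' @param arrays List of \code{\link{tandem_repeat_array}}s.
#' @param min_unit Unit-length floor (default 18 bp).
#' @return Integer total.
#' @export
total_repeat_units <- function(arrays, min_unit = 18) {
  if (length(arrays) == 0) return(0L)
  keep <- vapply(arrays, function(a) a$unit_len >= min_unit, logical(1))
  sum(vapply(arrays[keep], `[[`, 0L, "copies"))
}

#' Scan for conserved spacer motifs
#'
#' Exact substring search for every catalog motif; all (possibly
#' overlapping) occurrences are reported, so a U16 hit always co-occurs with
#' a D7 hit at the same position. Forward strand by default.
#'
#' @param seq Nucleotide string.
#' @param catalog Named motif vector (default \code{\link{motif_catalog}}).
#' @param both_strands Also scan the reverse strand?
#' @return List of hits, each with \code{motif_name}, \code{position}
#'   (0-based), \code{strand}, ordered by position.
#' @export
scan_motifs <- function(seq, catalog = motif_catalog(), both_strands = FALSE) {
  seq <- toupper(seq)
  hits <- list()
  add <- function(nm, pos, strand) {
    for (p in pos) {
      hits[[length(hits) + 1L]] <<- list(motif_name = nm, position = p - 1L,
                                         strand = strand)
    }
  }
  subj <- Biostrings::DNAString(seq)
  for (nm in names(catalog)) {
    # matchPattern reports overlapping occurrences, which gregexpr would miss
    add(nm, Biostrings::start(Biostrings::matchPattern(catalog[[nm]], subj)),
        "+")
    if (both_strands) {
      add(nm, Biostrings::start(
        Biostrings::matchPattern(revcomp(catalog[[nm]]), subj)), "-")
    }
  }
  hits[order(vapply(hits, `[[`, 0L, "position"))]
}

#' Build an IGS architecture profile from a spacer sequence
#'
#' Fills the full profile of an rpl23--ycf2 intergenic spacer: trnI_CAU
#' copies (by similarity), the two sub-spacer lengths (rpl23 end to first
#' trnI start; last trnI end to ycf2 start), tandem repeat arrays and motif
#' hits. With no internal trnI copy the whole spacer is reported on the
#' rpl23 side and the trnI--ycf2 gap is 0 by convention.
#'
#' @param igs_seq The spacer sequence (exclusive of both flanking CDSs).
#' @param record_id Identifier for reporting.
#' @param ref_trnI Reference trnI_CAU sequence.
#' @param ... Passed to \code{\link{find_tandem_repeats}}.
#' @return Object of class \code{igs_profile}.
#' @export
profile_igs <- function(igs_seq, record_id = NA_character_,
                        ref_trnI = trnI_reference(), ...) {
  igs_seq <- toupper(igs_seq)
  total <- nchar(igs_seq)
  trnI_hits <- count_trnI(igs_seq, ref_trnI)
  k <- length(trnI_hits)
  if (k == 0) {
    up <- total; down <- 0L
  } else {
    up <- trnI_hits[[1]]$start
    down <- total - trnI_hits[[k]]$end
  }
  structure(list(record_id = record_id, igs_seq = igs_seq,
                 total_len = total,
                 rpl23_trnI_len = as.integer(up),
                 trnI_ycf2_len = as.integer(down),
                 trnI_copies = k,
                 trnI_hits = trnI_hits,
                 repeat_arrays = find_tandem_repeats(igs_seq, ...),
                 motif_hits = scan_motifs(igs_seq)),
            class = "igs_profile")
}

#' @export
print.igs_profile <- function(x, ...) {
  cat(sprintf("<igs_profile> %s: %d bp, %d trnI copy(ies), sub-IGS %d/%d, %d repeat unit(s)\n",
              x$record_id, x$total_len, x$trnI_copies, x$rpl23_trnI_len,
              x$trnI_ycf2_len, total_repeat_units(x$repeat_arrays)))
  invisible(x)
}

#' Extract and profile the rpl23--ycf2 intergenic spacer
#'
#' Locates the annotated cassette copy where \code{left_gene} immediately
#' precedes \code{right_gene} reading 5'->3' (the other IR copy is its
#' reverse complement and is skipped to avoid double counting), extracts
#' the spacer between them, and profiles it with \code{\link{profile_igs}}.
#'
#' @param record A \code{\link{plastome_record}} with both flanking genes
#'   annotated.
#' @param left_gene,right_gene Flanking gene symbols (defaults
#'   \code{"rpl23"}, \code{"ycf2"}).
#' @param ref_trnI Reference trnI_CAU for copy counting.
#' @param ... Passed to \code{\link{find_tandem_repeats}}.
#' @return An \code{igs_profile}.
#' @export
extract_igs <- function(record, left_gene = "rpl23", right_gene = "ycf2",
                        ref_trnI = trnI_reference(), ...) {
  n <- nchar(record$sequence)
  lefts <- Filter(function(f) f$name == left_gene, record$features)
  rights <- Filter(function(f) f$name == right_gene, record$features)
  if (length(lefts) == 0) stop("record lacks an annotated ", left_gene)
  if (length(rights) == 0) stop("record lacks an annotated ", right_gene)
  best <- NULL
  for (lf in lefts) {
    for (rf in rights) {
      if (lf$strand != rf$strand) next  # a cassette copy shares one strand
      ls <- .feature_span(lf); rs <- .feature_span(rf)
      if (lf$strand == "+") {
        gap <- (rs["start"] - ls["end"]) %% n    # rpl23 -> ycf2 on plus
        cand <- list(gap = gap, from = ls["end"], dir = "+")
      } else {
        gap <- (ls["start"] - rs["end"]) %% n    # minus-strand copy
        cand <- list(gap = gap, from = rs["end"], dir = "-")
      }
      if (is.null(best) || cand$gap < best$gap) best <- cand
    }
  }
  if (is.null(best)) stop("no same-strand ", left_gene, "/", right_gene,
                          " cassette pair found")
  iv <- if (best$from + best$gap <= n) interval(best$from, best$from + best$gap)
        else interval(best$from, (best$from + best$gap) %% n, wraps = TRUE)
  igs <- extract_region(record, iv)
  if (best$dir == "-") igs <- revcomp(igs)
  profile_igs(igs, record_id = record$identifier, ref_trnI = ref_trnI, ...)
}
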