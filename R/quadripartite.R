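#' Locate the inverted repeat pair of a circular plastome
#'
#' Finds the maximal-length pair of disjoint intervals whose sequences are
#' exact reverse complements of each other (mismatch-tolerant extension is
#' available via \code{max_mismatch_frac} but the default is exact matching:
#' plastome IR arms are near-identical, and exactness makes maximality
#' testable). The search is k-mer seeded (k = 25) between the sequence and
#' its reverse complement, chained along anti-diagonals and extended to
#' maximal runs, so extending either boundary by one base breaks the
#' reverse-complement identity.
#'
#' Detection operates on the deposited linearization; an IR arm split by the
#' chosen origin is not rejoined (plastome deposits conventionally start in
#' the LSC, so in practice neither arm wraps).
#'
#' @param record Circular \code{\link{plastome_record}}.
#' @param min_len Minimum acceptable IR length (bp); default 10000.
#' @param max_mismatch_frac Tolerated mismatch fraction during run extension
#'   (default 0 = exact).
#' @return List with elements \code{irb} and \code{ira}
#'   (\code{\link{interval}}s; \code{irb} is the arm with the smaller start
#'   coordinate).
#' @export
find_inverted_repeat <- function(record, min_len = 10000,
                                 max_mismatch_frac = 0) {
  if (!record$is_circular) stop("record must be circular")
  s <- record$sequence
  n <- nchar(s)
  if (n < 2 * min_len)
    stop("no inverted repeat pair of length >= ", min_len, " (sequence too short)")
  rc <- revcomp(s)
  k <- 25L
  sv <- strsplit(s, "")[[1]]
  rv <- strsplit(rc, "")[[1]]
  kS <- substring(s, 1:(n - k + 1L), k:n)
  kR <- substring(rc, 1:(n - k + 1L), k:n)
  iS <- which(kS %in% kR)
  if (length(iS) == 0)
    stop("no inverted repeat pair of length >= ", min_len, " found")
  shared <- unique(kS[iS])
  jR <- which(kR %in% shared)
  lut <- split(jR, kR[jR])
  js_list <- lut[kS[iS]]
  pairs_i <- rep(iS, lengths(js_list))
  pairs_j <- unlist(js_list, use.names = FALSE)
  offs <- pairs_j - pairs_i
  cand_offs <- as.integer(names(sort(table(offs), decreasing = TRUE)))
  # keep offsets with enough seed support to possibly reach min_len
  cand_offs <- utils::head(cand_offs, 40L)

  best <- NULL
  allowed_frac <- max_mismatch_frac
  for (co in cand_offs) {
    i0 <- max(1L, 1L - co)
    i1 <- min(n, n - co)
    if (i1 - i0 + 1L < min_len) next
    idx <- i0:i1
    eq <- sv[idx] == rv[idx + co]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], len = r$lengths[r$values])
    if (allowed_frac > 0 && nrow(runs) > 1) {
      # greedily merge neighbouring exact runs while the merged span keeps
      # its mismatch fraction within tolerance
      merged <- runs[order(-runs$len), , drop = FALSE]
      base <- runs
      repeat {
        did <- FALSE
        if (nrow(base) < 2) break
        for (q in seq_len(nrow(base) - 1L)) {
          a <- base[q, ]; b <- base[q + 1L, ]
          span <- (b$start + b$len) - a$start
          mism <- span - (a$len + b$len)
          if (mism / span <= allowed_frac) {
            base$len[q] <- span
            base <- base[-(q + 1L), , drop = FALSE]
            did <- TRUE
            break
          }
        }
        if (!did) break
      }
      runs <- base
    }
    for (q in seq_len(nrow(runs))) {
      L <- runs$len[q]
      if (L < min_len) next
      a <- idx[1] + runs$start[q] - 1L
      b <- a + L - 1L
      # rc position j maps to plus-strand position n - j + 1 (1-based)
      p2a <- n - (b + co) + 1L
      p2b <- n - (a + co) + 1L
      if (p2a <= b && p2b >= a) next  # self-overlapping palindrome
      ivs <- list(interval(a - 1L, b), interval(p2a - 1L, p2b))
      ord <- order(c(ivs[[1]]$start, ivs[[2]]$start))
      cand <- list(irb = ivs[[ord[1]]], ira = ivs[[ord[2]]], len = L)
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && .lsc_start_of(cand, n) < .lsc_start_of(best, n))) {
        best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no inverted repeat pair of length >= ", min_len, " found")
  list(irb = best$irb, ira = best$ira)
}

# start coordinate of the longer gap arc (tie-break helper)
.lsc_start_of <- function(cand, n) {
  A <- cand$irb; B <- cand$ira
  g1 <- B$start - A$end
  g2 <- (A$start - B$end) %% n
  if (g1 >= g2) A$end else B$end %% n
}

#' Partition a plastome into LSC / IRb / SSC / IRa
#'
#' Given the two IR arm intervals, assigns the two gap arcs between them:
#' the longer arc becomes the large single-copy (LSC) region and the shorter
#' the small single-copy (SSC). \code{IRb} is the arm immediately following
#' the LSC in circular order, so the circle reads LSC, IRb, SSC, IRa.
#'
#' @param record Circular \code{\link{plastome_record}}.
#' @param irb,ira The two IR arm intervals (disjoint, equal length), e.g.
#'   from \code{\link{find_inverted_repeat}}.
#' @return Object of class \code{quadripartite_partition} with interval
#'   fields \code{lsc, irb, ssc, ira} and integer \code{lengths}.
#' @export
partition <- function(record, irb, ira) {
  n <- nchar(record$sequence)
  if (interval_length(irb, n) != interval_length(ira, n))
    stop("IR arms must have equal length")
  ivs <- list(irb, ira)
  ord <- order(c(irb$start, ira$start))
  A <- ivs[[ord[1]]]; B <- ivs[[ord[2]]]
  if (B$start < A$end) stop("IR arms overlap")
  g1 <- B$start - A$end                 # arc between A and B
  g2 <- (A$start - B$end) %% n          # arc wrapping past the origin
  if (g1 == 0 || g2 == 0) stop("degenerate partition: zero-length gap arc")
  if (g1 >= g2) {
    lsc <- interval(A$end, B$start)
    ssc <- if (B$end %% n < A$start) interval(B$end %% n, A$start)
           else interval(B$end %% n, A$start, wraps = TRUE)
    irb_ <- B; ira_ <- A
  } else {
    lsc <- if (B$end %% n < A$start) interval(B$end %% n, A$start)
           else interval(B$end %% n, A$start, wraps = TRUE)
    ssc <- interval(A$end, B$start)
    irb_ <- A; ira_ <- B
  }
  lens <- c(lsc = interval_length(lsc, n), irb = interval_length(irb_, n),
            ssc = interval_length(ssc, n), ira = interval_length(ira_, n))
  stopifnot(sum(lens) == n)
  structure(list(lsc = lsc, irb = irb_, ssc = ssc, ira = ira_,
                 lengths = lens, genome_length = n),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite> total %s | LSC %s  IRb %s  SSC %s  IRa %s\n",
              format(x$genome_length, big.mark = ","),
              format(x$lengths["lsc"], big.mark = ","),
              format(x$lengths["irb"], big.mark = ","),
              format(x$lengths["ssc"], big.mark = ","),
              format(x$lengths["ira"], big.mark = ",")))
  invisible(x)
}

# junction points: first base of the IR copy crossed when moving from a
# single-copy region into the repeat (JLB: LSC->IRb, JSB: SSC->IRb,
# JSA: SSC->IRa, JLA: LSC->IRa)
.junction_points <- function(part) {
  n <- part$genome_length
  list(
    JLB = list(p = part$irb$start,                ir_forward = TRUE),
    JSB = list(p = (part$irb$end - 1L) %% n,      ir_forward = FALSE),
    JSA = list(p = part$ira$start,                ir_forward = TRUE),
    JLA = list(p = (part$ira$end - 1L) %% n,      ir_forward = FALSE)
  )
}

#' Map each IR junction to its gene context
#'
#' For each of the four junctions (JLB, JSB, JSA, JLA) the junction point is
#' the first base of the IR arm crossed when moving from single-copy into
#' repeat. If an annotated gene contains that base (half-open containment),
#' the junction is reported inside that gene with \code{overlap_bp} = the
#' number of gene bases lying on the IR side (so a gene ending exactly at
#' the boundary is an intergenic context, while a junction on a gene's first
#' base counts the whole gene as duplicated). Otherwise the flanking gene
#' pair within \code{window} bp labels the context as
#' \code{"<IR-side gene>/<single-copy-side gene>"}; with no annotation in
#' reach the context is \code{"unresolved"}.
#'
#' @param part A \code{\link{partition}} result.
#' @param features List of \code{\link{gene_feature}}s.
#' @param window Search window for flanking genes (bp, default 5000).
#' @return List of 4 junction contexts, each with \code{junction_name},
#'   \code{containing_element}, \code{overlap_bp}.
#' @export
junction_context <- function(part, features, window = 5000) {
  n <- part$genome_length
  jp <- .junction_points(part)
  spans <- lapply(features, .feature_span)
  out <- lapply(names(jp), function(nm) {
    p <- jp[[nm]]$p
    fwd <- jp[[nm]]$ir_forward
    hit <- NULL
    for (i in seq_along(features)) {
      sp <- spans[[i]]
      if (p >= sp["start"] && p < sp["end"]) { hit <- i; break }
    }
    if (!is.null(hit)) {
      sp <- spans[[hit]]
      ov <- if (fwd) sp["end"] - p else p - sp["start"] + 1L
      return(list(junction_name = nm,
                  containing_element = features[[hit]]$name,
                  overlap_bp = as.integer(ov)))
    }
    # intergenic: nearest gene ending at/before p and nearest starting after p
    up <- NULL; up_d <- Inf
    dn <- NULL; dn_d <- Inf
    for (i in seq_along(features)) {
      sp <- spans[[i]]
      d_up <- (p - sp["end"] + 1L) %% n   # circular distance back to gene end
      d_dn <- (sp["start"] - p) %% n      # circular distance forward to start
      if (d_up < up_d) { up_d <- d_up; up <- i }
      if (d_dn < dn_d) { dn_d <- d_dn; dn <- i }
    }
    if (is.null(up) || is.null(dn) || up_d > window || dn_d > window) {
      return(list(junction_name = nm, containing_element = "unresolved",
                  overlap_bp = 0L))
    }
    g_up <- features[[up]]$name   # single-copy side for forward-IR junctions
    g_dn <- features[[dn]]$name
    lab <- if (fwd) paste0(g_dn, "/", g_up) else paste0(g_up, "/", g_dn)
    list(junction_name = nm, containing_element = lab, overlap_bp = 0L)
  })
  names(out) <- names(jp)
  out
}
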