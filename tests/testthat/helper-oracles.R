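# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use straightforward enumeration, not the package's
# algorithms.

rand_seq <- function(n, seed = NULL, gc = 0.375) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rc_chars <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# naive slicing oracle for extract_region on a circular sequence
oracle_slice <- function(seq, start, end, wraps) {
  x <- strsplit(seq, "")[[1]]
  idx <- if (wraps) c((start + 1):length(x), seq_len(end))
         else (start + 1):end
  paste(x[idx], collapse = "")
}

# O(n^3) enumeration of all (start, period, run) tandem tracts, with the
# same per-copy-vs-first-copy identity contract and collapse rule
oracle_tandem <- function(seq, min_unit = 18, max_unit = 250,
                          min_copies = 2, frac = 0.1) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  cands <- list()
  pmax <- min(max_unit, n %/% 2)
  if (pmax < min_unit) return(list())
  for (p in min_unit:pmax) {
    allowed <- floor(p * frac)
    for (s in 1:(n - 2 * p + 1)) {
      unit <- x[s:(s + p - 1)]
      cc <- 1L
      repeat {
        b <- s + cc * p
        if (b + p - 1 > n) break
        if (sum(x[b:(b + p - 1)] != unit) > allowed) break
        cc <- cc + 1L
      }
      if (cc < min_copies) next
      t0 <- s + cc * p
      tmax <- min(p - 1, n - t0 + 1)
      tail_bp <- 0L
      if (tmax > 0) {
        tm <- cumsum(x[t0:(t0 + tmax - 1)] != unit[1:tmax])
        ok <- which(tm <= floor(seq_len(tmax) * frac))
        if (length(ok)) tail_bp <- max(ok)
      }
      ids <- 1
      if (cc > 1) {
        ids <- (1 + sum(vapply(2:cc, function(k)
          1 - sum(x[(s + (k - 1) * p):(s + k * p - 1)] != unit) / p,
          numeric(1)))) / cc
      }
      cands[[length(cands) + 1L]] <- list(start = s - 1L, unit_len = p,
                                          copies = cc, tail_bp = tail_bp,
                                          identity = ids)
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

# signature for comparing tandem-repeat outputs
tandem_sig <- function(arrays) {
  vapply(arrays, function(a)
    sprintf("%d:%d:%d:%d", a$start, a$unit_len, a$copies, a$tail_bp),
    character(1))
}

# naive all-pairs amplicon scan on a linear template
oracle_pcr <- function(seq, primers, max_amplicon = 3000, max_mismatch = 0) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  site_scan <- function(pat, minus) {
    pv <- strsplit(if (minus) rc_chars(pat) else pat, "")[[1]]
    L <- length(pv)
    hits <- list()
    if (n < L) return(hits)
    for (i in 1:(n - L + 1)) {
      if (sum(x[i:(i + L - 1)] != pv) > max_mismatch) next
      ok3 <- if (minus) x[i] == pv[1] else x[i + L - 1] == pv[L]
      if (ok3) hits[[length(hits) + 1L]] <- c(start = i, end = i + L - 1L)
    }
    hits
  }
  out <- list()
  for (cfg in list(c("+", "f"), c("-", "r"))) {
    A <- if (cfg[2] == "f") primers$forward else primers$reverse
    B <- if (cfg[2] == "f") primers$reverse else primers$forward
    pa <- site_scan(A, FALSE)
    pb <- site_scan(B, TRUE)
    for (a in pa) for (b in pb) {
      if (b["start"] > a["end"] &&
          (b["end"] - a["start"] + 1) <= max_amplicon) {
        out[[length(out) + 1L]] <- list(start = unname(a["start"]) - 1L,
                                        end = unname(b["end"]),
                                        length_bp = unname(b["end"] - a["start"] + 1L),
                                        strand_of_forward = cfg[1])
      }
    }
  }
  out
}

pcr_sig <- function(amps) {
  sort(vapply(amps, function(a)
    sprintf("%d:%d:%s", a$start, a$length_bp, a$strand_of_forward),
    character(1)))
}

# naive substring search for motif occurrences (forward strand)
oracle_motifs <- function(seq, catalog) {
  hits <- list()
  for (nm in names(catalog)) {
    m <- catalog[[nm]]
    L <- nchar(m)
    for (i in seq_len(nchar(seq) - L + 1)) {
      if (substr(seq, i, i + L - 1) == m)
        hits[[length(hits) + 1L]] <- c(nm, i - 1L)
    }
  }
  sort(vapply(hits, function(h) paste(h, collapse = "@"), character(1)))
}

motif_sig <- function(hits) {
  sort(vapply(hits, function(h)
    paste(h$motif_name, h$position, sep = "@"), character(1)))
}

# exhaustive diagonal scan for the maximal reverse-complement interval pair
oracle_inverted_repeat <- function(seq, min_len) {
  n <- nchar(seq)
  sv <- strsplit(seq, "")[[1]]
  rv <- strsplit(rc_chars(seq), "")[[1]]
  best <- NULL
  for (co in (-(n - min_len)):(n - min_len)) {
    i0 <- max(1, 1 - co); i1 <- min(n, n - co)
    if (i1 - i0 + 1 < min_len) next
    idx <- i0:i1
    r <- rle(sv[idx] == rv[idx + co])
    ends <- cumsum(r$lengths)
    for (q in which(r$values & r$lengths >= min_len)) {
      L <- r$lengths[q]
      a <- idx[1] + ends[q] - L
      b <- a + L - 1
      p2a <- n - (b + co) + 1; p2b <- n - (a + co) + 1
      if (p2a <= b && p2b >= a) next
      lo <- min(a, p2a); hi <- min(b, p2b)
      if (is.null(best) || L > best$len)
        best <- list(len = L, start1 = min(a, p2a) - 1L,
                     start2 = max(a, p2a) - 1L)
    }
  }
  best
}

# straightforward point-in-interval scan for junction containment
oracle_junction <- function(part, features) {
  n <- part$genome_length
  pts <- list(JLB = c(part$irb$start, 1), JSB = c((part$irb$end - 1) %% n, 0),
              JSA = c(part$ira$start, 1), JLA = c((part$ira$end - 1) %% n, 0))
  lapply(pts, function(pp) {
    p <- pp[1]; fwd <- pp[2] == 1
    for (f in features) {
      s <- min(vapply(f$parts, function(q) q$start, integer(1)))
      e <- max(vapply(f$parts, function(q) q$end, integer(1)))
      if (p >= s && p < e) {
        return(list(element = f$name,
                    overlap = if (fwd) e - p else p - s + 1))
      }
    }
    list(element = NA_character_, overlap = 0L)
  })
}
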