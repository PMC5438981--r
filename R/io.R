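#' Read plastome sequences from FASTA
#'
#' @param path FASTA file path.
#' @return List of \code{\link{plastome_record}} objects in file order
#'   (empty list for an empty file). Sequences are upper-cased; features are
#'   empty (use \code{\link{read_annotation_table}} to attach them).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(list())
  ss <- Biostrings::readBStringSet(path)
  lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    plastome_record(id, as.character(ss[[i]]), is_circular = TRUE,
                    source = path)
  })
}

#' Write plastome records to FASTA
#'
#' Round-trips with \code{\link{read_fasta}}: identifier and sequence are
#' preserved exactly.
#'
#' @param records List of \code{plastome_record}s (or a single record).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "plastome_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(ss) <- vapply(records, `[[`, "", "identifier")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Fallback annotation input for plain-FASTA workflows: a TSV with columns
#' \code{record_id, gene, kind, strand, part_start, part_end} (0-based,
#' half-open; multi-exon genes occupy one row per part in biological order).
#'
#' @param path TSV path.
#' @param record A \code{plastome_record} to attach features to.
#' @return The record with its \code{features} list populated.
#' @export
read_annotation_table <- function(path, record) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("record_id", "gene", "kind", "strand", "part_start", "part_end")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[tab$record_id == record$identifier, , drop = FALSE]
  feats <- lapply(split(tab, tab$gene), function(g) {
    parts <- lapply(seq_len(nrow(g)), function(i)
      interval(g$part_start[i], g$part_end[i]))
    gene_feature(g$gene[1], g$kind[1], g$strand[1], parts)
  })
  record$features <- unname(feats)
  record
}

# ---- GenBank flat files -----------------------------------------------------
# No installed R package parses GenBank feature tables offline, so a minimal
# flat-file reader/writer lives here. It covers the subset this pipeline
# emits and consumes: LOCUS, gene/CDS/tRNA/rRNA features with
# join()/complement() locations, /gene and /pseudo qualifiers, ORIGIN.

.parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  pieces <- strsplit(loc, ",")[[1]]
  parts <- lapply(pieces, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 0) {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      if (length(m1) == 0) return(NULL)
      a <- as.integer(m1[2]); b <- a
    } else {
      a <- as.integer(m[2]); b <- as.integer(m[3])
    }
    interval(a - 1L, b)  # 1-based inclusive -> 0-based half-open
  })
  if (any(vapply(parts, is.null, logical(1)))) return(NULL)
  # biological exon order: ascending for "+", descending for "-"
  if (strand == "-") parts <- rev(parts)
  list(strand = strand, parts = parts)
}

.canonical_gene_name <- function(name, product = NA_character_) {
  # canonicalize tRNA symbols to trnX_ANTICODON across source dialects
  m <- regmatches(name, regexec("^trn([A-Za-z])[-_ ]?([ACGTU]{3})?$", name))[[1]]
  if (length(m) > 0 && nzchar(m[3])) {
    return(paste0("trn", toupper(m[2]), "_", chartr("T", "U", toupper(m[3]))))
  }
  gsub("-", "_", name)
}

#' Read a GenBank flat file
#'
#' Parses the first record of a GenBank flat file into a
#' \code{\link{plastome_record}}. Feature locations are translated to
#' 0-based half-open coordinates (an annotation \code{n..m} becomes
#' \code{[n-1, m)}); \code{join()} locations become multi-part features;
#' tRNA names are canonicalized to \code{trnX_ANTICODON}. Unparseable
#' locations are skipped with a warning; a missing sequence is an error.
#'
#' @param path GenBank flat-file path.
#' @return A \code{plastome_record}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file: ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else basename(path)
  circular <- length(locus) > 0 && grepl("circular", locus[1], ignore.case = TRUE)

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("GenBank file has no ORIGIN sequence: ", path)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(end - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) stop("GenBank file has empty sequence: ", path)

  fstart <- grep("^FEATURES", lines)
  features <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # feature headers start at column 6; qualifier/continuation lines later
    hdr <- grep("^ {5}\\S", block)
    for (i in seq_along(hdr)) {
      from <- hdr[i]
      to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(block)
      key <- trimws(substr(block[from], 1, 20))
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      body <- block[from:to]
      loc <- trimws(substr(body[1], 21, nchar(body[1])))
      j <- 2L
      while (j <= length(body) && !grepl("^\\s*/", body[j])) {
        loc <- paste0(loc, trimws(body[j])); j <- j + 1L
      }
      quals <- body[grepl("^\\s*/", body)]
      getq <- function(q) {
        hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (length(hit) == 0) return(NA_character_)
        gsub("\"", "", sub(paste0("^\\s*/", q, "="), "", trimws(hit[1])))
      }
      if (key == "gene") next  # gene features duplicate CDS/tRNA/rRNA entries
      parsed <- .parse_location(loc)
      if (is.null(parsed)) {
        warning("skipping feature with unparseable location: ", loc)
        next
      }
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("product")
      if (is.na(nm)) nm <- key
      features[[length(features) + 1L]] <- gene_feature(
        name = .canonical_gene_name(nm),
        kind = key, strand = parsed$strand, parts = parsed$parts,
        is_pseudo = any(grepl("/pseudo", quals)))
    }
  }
  plastome_record(id, sequence, is_circular = circular, features = features,
                  source = path)
}

#' Write a record as a GenBank flat file
#'
#' Minimal writer covering what \code{\link{read_genbank}} parses; used by
#' the synthetic generator so that planted genomes round-trip through the
#' standard annotation format.
#'
#' @param record A \code{plastome_record}.
#' @param path Output path.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$is_circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     record$identifier, n, topo), con)
  writeLines(sprintf("DEFINITION  %s synthetic plastome.", record$identifier), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in record$features) {
    locs <- vapply(f$parts, function(p) sprintf("%d..%d", p$start + 1L, p$end),
                   character(1))
    if (f$strand == "-") locs <- rev(locs)
    loc <- if (length(locs) > 1) paste0("join(", paste(locs, collapse = ","), ")")
           else locs
    if (f$strand == "-") loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-15s %s", f$kind, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (f$is_pseudo) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
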