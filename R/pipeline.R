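#' Pipeline configuration defaults
#'
#' @param min_ir_len Minimum IR length for detection (bp).
#' @param junction_window Flanking-gene search window at junctions (bp).
#' @param min_unit,max_unit Tandem-repeat unit bounds (bp).
#' @param max_mismatch_frac Per-copy mismatch tolerance.
#' @param ref_trnI Reference trnI_CAU sequence.
#' @param ref_exon1,ref_exon2 rps16 reference exons.
#' @param primers rps16 \code{\link{primer_pair}}.
#' @return Named list of settings.
#' @export
pipeline_config <- function(min_ir_len = 10000, junction_window = 5000,
                            min_unit = 18, max_unit = 250,
                            max_mismatch_frac = 0.1,
                            ref_trnI = trnI_reference(),
                            ref_exon1 = rps16_reference_exons()$exon1,
                            ref_exon2 = rps16_reference_exons()$exon2,
                            primers = rps16_primers()) {
  list(min_ir_len = min_ir_len, junction_window = junction_window,
       min_unit = min_unit, max_unit = max_unit,
       max_mismatch_frac = max_mismatch_frac, ref_trnI = ref_trnI,
       ref_exon1 = ref_exon1, ref_exon2 = ref_exon2, primers = primers)
}

.na_row <- function() {
  data.frame(record_id = NA_character_, total_len = NA_integer_,
             lsc_len = NA_integer_, ssc_len = NA_integer_,
             ir_len = NA_integer_, at_percent = NA_real_,
             gc_percent = NA_real_,
             jlb_element = NA_character_, jlb_overlap = NA_integer_,
             jsb_element = NA_character_, jsb_overlap = NA_integer_,
             jsa_element = NA_character_, jsa_overlap = NA_integer_,
             jla_element = NA_character_, jla_overlap = NA_integer_,
             rps16_class = NA_character_, amplicon_lengths = NA_character_,
             section_call = NA_character_,
             igs_len = NA_integer_, trnI_copies = NA_integer_,
             rpl23_trnI_len = NA_integer_, trnI_ycf2_len = NA_integer_,
             n_repeat_units = NA_integer_, unit_lengths = NA_character_,
             scenario = NA_character_, evidence = NA_character_,
             stringsAsFactors = FALSE)
}

# region handed to the rps16 classifier: the annotated trnK..trnQ
# neighbourhood when available, otherwise the whole sequence
.rps16_region <- function(record) {
  n <- nchar(record$sequence)
  anchors <- Filter(function(f) f$name %in% c("trnK_UUU", "trnQ_UUG", "rps16"),
                    record$features)
  if (length(anchors) == 0) return(record$sequence)
  sp <- vapply(anchors, .feature_span, c(start = 0, end = 0))
  a <- max(0L, min(sp["start", ]) - 2500L)
  b <- min(n, max(sp["end", ]) + 2500L)
  substr(record$sequence, a + 1L, b)
}

#' Run the full comparative pipeline over plastome records
#'
#' Per record: quadripartite partitioning, junction gene-context mapping,
#' base composition, rps16 integrity typing plus in-silico PCR section
#' call, rpl23--ycf2 spacer profiling (trnI copies, sub-spacers, tandem
#' repeats, motifs) and repeat-origin scenario classification. A failure in
#' one stage or record is reported as \code{NA} fields with a warning; the
#' batch continues.
#'
#' @param inputs Character vector of GenBank file paths, or a list of
#'   \code{\link{plastome_record}}s.
#' @param config Settings from \code{\link{pipeline_config}}.
#' @param verbose Log per-stage progress to stderr?
#' @return A data.frame with one summary row per record.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), verbose = FALSE) {
  if (length(inputs) == 0) stop("no inputs")
  records <- if (is.character(inputs)) {
    out <- list()
    for (p in inputs) {
      r <- tryCatch(read_genbank(p), error = function(e) {
        warning("skipping unreadable input ", p, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(r)) out[[length(out) + 1L]] <- r
    }
    out
  } else if (inherits(inputs, "plastome_record")) list(inputs) else inputs
  if (length(records) == 0) stop("no readable inputs")

  say <- function(...) if (verbose) message(sprintf(...))
  rows <- lapply(records, function(rec) {
    row <- .na_row()
    row$record_id <- rec$identifier
    row$total_len <- nchar(rec$sequence)
    cmp <- tryCatch(composition(rec$sequence), error = function(e) NULL)
    if (!is.null(cmp)) {
      row$at_percent <- cmp$at_percent
      row$gc_percent <- cmp$gc_percent
    }
    say("[%s] partitioning", rec$identifier)
    part <- tryCatch({
      ir <- find_inverted_repeat(rec, min_len = config$min_ir_len)
      partition(rec, ir$irb, ir$ira)
    }, error = function(e) {
      warning(rec$identifier, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(part)) {
      row$lsc_len <- part$lengths[["lsc"]]
      row$ssc_len <- part$lengths[["ssc"]]
      row$ir_len <- part$lengths[["irb"]]
      jc <- tryCatch(junction_context(part, rec$features,
                                      window = config$junction_window),
                     error = function(e) NULL)
      if (!is.null(jc)) {
        for (jn in c("JLB", "JSB", "JSA", "JLA")) {
          row[[paste0(tolower(jn), "_element")]] <- jc[[jn]]$containing_element
          row[[paste0(tolower(jn), "_overlap")]] <- jc[[jn]]$overlap_bp
        }
      }
    }
    say("[%s] rps16", rec$identifier)
    st <- tryCatch(
      classify_rps16(.rps16_region(rec), config$ref_exon1, config$ref_exon2),
      error = function(e) { warning(rec$identifier, ": ",
                                    conditionMessage(e)); NULL })
    if (!is.null(st)) row$rps16_class <- st$class
    amps <- tryCatch(insilico_pcr(rec, config$primers),
                     error = function(e) NULL)
    if (!is.null(amps)) {
      row$amplicon_lengths <- paste(vapply(amps, `[[`, 0L, "length_bp"),
                                    collapse = ",")
      row$section_call <- veratrum_section_call(amps)
    }
    say("[%s] spacer profile", rec$identifier)
    prof <- tryCatch(
      extract_igs(rec, ref_trnI = config$ref_trnI,
                  min_unit = config$min_unit, max_unit = config$max_unit,
                  max_mismatch_frac = config$max_mismatch_frac),
      error = function(e) { warning(rec$identifier, ": ",
                                    conditionMessage(e)); NULL })
    if (!is.null(prof)) {
      row$igs_len <- prof$total_len
      row$trnI_copies <- prof$trnI_copies
      row$rpl23_trnI_len <- prof$rpl23_trnI_len
      row$trnI_ycf2_len <- prof$trnI_ycf2_len
      row$n_repeat_units <- total_repeat_units(prof$repeat_arrays,
                                               config$min_unit)
      row$unit_lengths <- paste(vapply(prof$repeat_arrays, `[[`, 0L,
                                       "unit_len"), collapse = ",")
      sc <- tryCatch(classify_scenario(prof, ref_trnI = config$ref_trnI,
                                       min_unit = config$min_unit),
                     error = function(e) NULL)
      if (!is.null(sc)) {
        row$scenario <- sc$label
        row$evidence <- paste(sc$evidence, collapse = "; ")
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a pipeline summary
#'
#' Fixed, documented column order; missing analyses are explicit \code{NA}
#' fields. TSV writes one header plus one line per record; JSON wraps the
#' rows with a schema version and round-trips losslessly.
#'
#' @param rows data.frame from \code{\link{run_pipeline}}.
#' @param path Output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_summary <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(list(schema = "plastrep_summary_v1", rows = rows),
                         path, dataframe = "rows", na = "string",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a JSON pipeline summary
#'
#' @param path Path written by \code{\link{write_summary}} with
#'   \code{format = "json"}.
#' @return The summary rows as a data.frame.
#' @export
read_summary_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- obj$rows
  rows[rows == "NA"] <- NA
  rows
}
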