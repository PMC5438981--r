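#' Published rpl23--ycf2 spacer survey of Liliales
#'
#' The printed comparative survey of the rpl23--ycf2 intergenic spacer
#' across 68 Liliales taxa: spacer length, trnI_CAU copy number, the two
#' sub-spacer lengths, total repeat units (>= 18 bp) and the assigned
#' repeat-origin scenario. \code{flag} carries the table's row marks
#' (\code{"#"}, \code{"*"}, \code{"x"} for rows annotated with an unprinted
#' legend); flagged rows are exempt from decision-table validation.
#' Scenario \code{"-"} denotes no repeat accumulation.
#'
#' @return A data.frame with one row per surveyed taxon.
#' @export
igs_survey_table <- function() {
  rows <- c(
    "Paris verticillata|591|3|172|67|3|III_B|",
    "Paris quadrifolia|591|3|172|67|3|III_B|",
    "Paris incompleta|640|3|164|92|3|x|x",
    "Paris japonica|818|2|159|146|2|x|#x",
    "Paris dulongensis|724|1|159|491|16|III_A|",
    "Paris fargesii|708|1|159|475|16|III_A|",
    "Paris mairei|612|1|159|379|12|III_A|",
    "Paris luquanensis|636|1|159|403|13|III_A|",
    "Paris rugosa|612|1|159|379|12|III_A|",
    "Paris dunniana|420|1|159|187|4|III_A|",
    "Paris thibetica|485|1|159|252|7|III_A|",
    "Paris axialis|501|1|159|268|6|III_A|",
    "Paris vietnamensis|500|1|159|267|6|III_A|",
    "Paris polyphylla var. chinensis|523|1|159|290|12|III_A|",
    "Paris polyphylla var. polyphylla|612|1|159|290|8|III_A|",
    "Paris polyphylla var. stenophylla|636|1|159|403|13|III_A|",
    "Pseudotrillium rivale|299|1|164|61|0|-|",
    "Trillium undulatum|307|1|165|68|0|-|",
    "Trillium decumbens|402|1|205|123|0|-|",
    "Trillium cuneatum|378|1|210|94|0|-|",
    "Trillium smalii|447|1|173|200|7|III_A|",
    "Trillium tschonoskii|483|1|240|169|7|III_A|",
    "Trillium flexipes|637|1|173|390|18|III_A|#*",
    "Trillium simile|651|1|173|404|19|III_A|#*",
    "Trillium rugelii|665|1|169|422|20|III_A|#*",
    "Trillium erectum|669|1|173|422|20|III_A|#*",
    "Trillium underwoodii|602|2|205|113|2|II|#*",
    "Trillium chloropetalum|581|2|205|102|2|II|",
    "Trillium luteum|565|2|210|94|2|II|*",
    "Trillium sessile|565|2|210|94|2|II|*",
    "Trillium maculatum|569|2|214|94|2|II|*",
    "Trillium govanianum|612|3|164|65|3|I|",
    "Xerophyllum tenax|306|1|164|68|0|-|",
    "Xerophyllum asphodeloides|306|1|164|68|0|-|",
    "Chionographis japonica|302|1|160|68|0|-|",
    "Heloniopsis tubiflora|302|1|160|68|0|-|",
    "Veratrum patulum|304|1|157|73|0|-|",
    "Anticlea elegans|322|1|157|91|2|-|*",
    "Stenanthium densum|322|1|157|91|2|-|*",
    "Toxicoscordion micranthus|304|1|157|73|0|-|",
    "Schoenocaulon coricifolium|304|1|157|73|0|-|",
    "Zigadenus glaberrimus|299|1|157|68|0|-|",
    "Lilium longiflorum|307|1|165|68|0|-|",
    "Fritillaria cirrosa|307|1|165|68|0|-|",
    "Calochortus venustus|307|1|165|68|0|-|",
    "Tricyrtis macropoda|307|1|165|68|0|-|",
    "Gagea triflora|307|1|165|68|0|-|",
    "Erythronium japonicum|307|1|165|68|0|-|",
    "Tulipa sylvestris|307|1|165|68|0|-|",
    "Clintonia udensis|307|1|165|68|0|-|",
    "Streptopus ovalis|307|1|165|68|0|-|",
    "Smilax china|307|1|165|68|0|-|",
    "Smilax nipponica|307|1|165|68|0|-|",
    "Smilax glyciphylla|307|1|165|68|0|-|",
    "Heterosmilax china|307|1|165|68|0|-|",
    "Philesia magellanica|307|1|165|68|0|-|",
    "Rhipogonum scandens|307|1|165|68|0|-|",
    "Colchicum autumnale|298|1|165|59|0|-|",
    "Gloriosa superba|307|1|165|68|0|-|",
    "Wurmbea burtii|302|1|160|68|0|-|",
    "Tripladenia cunninghamii|299|1|157|68|0|-|",
    "Uvularia grandiflora|307|1|165|68|0|-|",
    "Disporum smilacinum|307|1|165|68|0|-|",
    "Alstroemeria aurea|307|1|165|68|0|-|",
    "Bomarea edulis|307|1|165|68|0|-|",
    "Luzuriaga radicans|307|1|165|68|0|-|",
    "Petermannia cirrosa|307|1|165|68|0|-|",
    "Campynema lineare|312|1|170|68|0|-|")
  m <- do.call(rbind, lapply(strsplit(rows, "|", fixed = TRUE), function(p) {
    length(p) <- 8L
    p
  }))
  m[is.na(m)] <- ""
  data.frame(species = m[, 1],
             igs_len = as.integer(m[, 2]),
             trnI_copies = as.integer(m[, 3]),
             rpl23_trnI_len = as.integer(m[, 4]),
             trnI_ycf2_len = as.integer(m[, 5]),
             units = as.integer(m[, 6]),
             scenario = m[, 7],
             flag = m[, 8],
             stringsAsFactors = FALSE)
}

#' Reconstruct a minimal IGS profile from a survey row
#'
#' Builds an \code{\link{igs_profile}}-shaped object from the summary
#' columns of \code{\link{igs_survey_table}} plus the structural facts the
#' survey narrative states about each group (repeats of multi-trnI rows
#' span the tRNA; U16 is present where HFIR is invoked; R1a is present
#' where the point-mutation pathway is invoked; single-trnI repeats lie in
#' the trnI--ycf2 sub-spacer). Used to check that the scenario decision
#' table reproduces the survey's printed calls; sequence-level fields are
#' synthetic placeholders.
#'
#' @param row One row of \code{igs_survey_table()}.
#' @return An \code{igs_profile}.
#' @export
survey_row_profile <- function(row) {
  filler <- function(n) substr(.gene_seqs[["ndhF"]], 1, n)
  arrays <- list()
  motifs <- list(list(motif_name = "R1", position = 10L, strand = "+"),
                 list(motif_name = "R1b", position = 13L, strand = "+"),
                 list(motif_name = "D7", position = 30L, strand = "+"))
  if (row$units > 0) {
    spans_trnI <- row$trnI_copies >= 2
    if (spans_trnI) {
      unit <- paste0(filler(45), trnI_reference(), filler(45))
      start <- max(0L, row$rpl23_trnI_len - 45L)
    } else {
      unit <- filler(30)
      start <- row$igs_len - row$trnI_ycf2_len + 2L
    }
    arrays <- list(tandem_repeat_array(unit, nchar(unit), row$units, start))
    if (row$trnI_copies == 3 && row$scenario != "I")
      motifs <- c(motifs, list(list(motif_name = "U16", position = 50L,
                                    strand = "+")))
    if (row$trnI_copies == 2)
      motifs <- c(motifs, list(list(motif_name = "R1a", position = 60L,
                                    strand = "+")))
  }
  structure(list(record_id = row$species, igs_seq = NA_character_,
                 total_len = row$igs_len,
                 rpl23_trnI_len = row$rpl23_trnI_len,
                 trnI_ycf2_len = row$trnI_ycf2_len,
                 trnI_copies = row$trnI_copies,
                 trnI_hits = NULL,
                 repeat_arrays = arrays,
                 motif_hits = motifs),
            class = "igs_profile")
}
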