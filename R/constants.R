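#' Conserved motif catalog of the rpl23--ycf2 intergenic spacer
#'
#' The five short direct-repeat motifs that recur around the
#' \emph{trnI_CAU}-bearing spacer in Liliales plastomes: the R-cluster
#' (R1, its point-mutant R1a which differs from R1 by a single A->C at the
#' second base, and the 6 bp core R1b) and the D-cluster (the 7 bp D7
#' repeat and the 16 bp U16 unit whose first seven bases are D7).
#' U16 arises when a D7 pair is fused by homology-facilitated illegitimate
#' recombination, so a U16 hit always implies a D7 hit at the same position.
#'
#' @return Named character vector of motif sequences.
#' @export
motif_catalog <- function() {
  c(R1  = "CAAATTCCAAT",
    R1a = "CCAATTCCAAT",
    R1b = "ATTCCA",
    D7  = "ATGGATG",
    U16 = "ATGGATGCTTAACAGG")
}

#' rps16 amplification primer pair
#'
#' Primer pair spanning the full rps16 coding region within the
#' trnK_UUU--trnQ_UUG neighbourhood, used to size-type the locus:
#' a ~1.5 kb product indicates retention of exon 1 only
#' (\emph{Veratrum} sect. \emph{Veratrum}) while a 400 bp product
#' indicates complete loss (sect. \emph{Fuscoveratrum}).
#'
#' @return A \code{primer_pair} object.
#' @export
rps16_primers <- function() {
  primer_pair(forward = "GTCAATATGAATGTTGATAA",
              reverse = "TTTTCTATTCCATACACATG",
              name = "rps16")
}

#' Reference exon sequences for rps16 integrity typing
#'
#' Fixed synthetic stand-ins for the two exons of plastid \emph{rps16}
#' (42 bp exon 1, 227 bp exon 2), used both by the synthetic-plastome
#' generator and as default references for \code{\link{classify_rps16}}.
#' They are versioned constants of this package, not sequences from any
#' deposited accession.
#'
#' @return Named list with elements \code{exon1} and \code{exon2}.
#' @export
rps16_reference_exons <- function() {
  list(exon1 = .gene_seqs[["rps16_exon1"]],
       exon2 = .gene_seqs[["rps16_exon2"]])
}

#' Reference trnI_CAU sequence
#'
#' Fixed 74 nt synthetic tRNA-Ile (CAU) stand-in carrying a single internal
#' D7 motif, mirroring the conserved D-repeat that real \emph{trnI_CAU}
#' copies carry. Used as the similarity template for
#' \code{\link{count_trnI}} and planted by the synthetic generator.
#'
#' @return Character scalar (74 nt).
#' @export
trnI_reference <- function() .gene_seqs[["trnI_CAU"]]

# Fixed synthetic gene sequences planted by the generator. Arbitrary but
# versioned: changing any of these invalidates frozen test expectations.
# None contains a catalog motif or a primer site (trnI_CAU carries exactly
# one internal D7, by construction).
.gene_seqs <- c(
  trnH_GUG = "ATTTGATAAAAGATTTCATATTGTTATCGCCTCCGAGGGCAACCTCATAATAAAAGCGCACTTACCGTAAACGG",
  rps19 = "GAGACTCTGCCCAGATAAATTATAACCTGTTAATTGTTTTGATTTTGCCACATAAAAAGATAAAAATTAAGTTCATGACGCACTTAAGGCATAAGGGCTATGAGCCATCCACAGTATTCTCATCCCTGGGTTCATTTAACTTTCTGACATCGTTGAAGAGGACAATAGCATAGCGAAAAGTGTTCATCGTTATAACCTACAGGACCCCATAAAAGAGCTATACTAGTCTTAAGACTCGTAACTGTACCCATGTGTTATAAGATCAGGCAATTGCCCTCG",
  rpl22 = "TTTAGGTACGTTTCGGAAGTTCTGGCAAAATTCTCCACGTGACTTCTTTTTATCAGTTCGCATTTGACATATAGTTACTGTTTAGTGCTAGCTATTCTTGAGAGTTACGTTCGGACCAACGCACTACGATAATGGTTGTTTGCGGAAGTCATACTGTGTCGATCGATAAAATCATAAAGTTAGTGAATGATACAATTTTTTGCTAATTCGGTGGTAGCCATTTCGTTGCCAATGAATAAATACACTTTTCAAATGTGAGGAGCGATCATATTGTATATGTATTAGTGTTCAGCCTAATTCTATTTACGTTAGATACGTCCTAAGATTCTTACCAGTTGTTGTTACCTATAAGCTCTGTCC",
  rps3 = "AGAGCACATGTCTCCCTTTTATAGTCACTGCTTCCTTAATAATTAACCATTGACCCTTATGCCGGTCGAAGTATACAATGCCAATACGTACTACACTTTTGACTTTTGTTTGACATGTTATCGATTATGGTGTCTAAACGTAGTCCCAGTAAGTAATCCAAATTTTAGCTCCCGATTTAAAAATTCTCTCAATAGATCTGAGAAGCTACACTGGTATTTCAAAAGGGGAAGGGCGCTTATCTAGAAAGTCTGAGGTGAAATATGCCAAGACGCTAACATTTTATGGACGTATCATAGCTTCATGTCGAGGGCAGGTGGGGATTACTCTACGTTTAATCTTCTGGATTGAATACACGACCAGCCACAAGCGTGTTCCTGAGTACGATCTGATCCATCAACACCTAATAGTACTCTTAACAGAGTCGGACTCGTCATCTACAAACGGTAAATATGATTTCAGCGGTAATAAGGTTTTGATTTGCACAGCATCTCTAACACTAAAGCCGATGATATTCACGTCATGCTGTCGATGTTGGATTAGACGTGTACGTGTACGAGTTAAGTCATGAGCTGAACACATGCAGACAAGAACCACTTTACTCAAGCCCCTTTTGAGAACTTAGTATTGGAAAATGGCGAATGCATTCTTTTTGGATG",
  rpl23 = "TTGCGCTTACTCGCAAATGCTGAATTACGATAGTGAGACATCTGCCGATATGAGTCACGTAACAGTTCCATCTTCAGTAATCCATGTGCGACACAATTGGATAGGCAGTCGTAAACAACTTAATAGAATGAGACCGCACTCCCTTAAGGTAAATGAGAATTCGTGCAGACTGATAAATTGACGCATTGAGCGTACAACTTGGTTCGTCTATCAAAGATACCTGATCAGAATTAACGTAGCCGATATCAATTCATAACGTTGCATAAGTGAAACGCATAGGGT",
  ycf2 = "TAACCGGTTTGAAGGAAGTAGGCTGTAAATACTGTTAAGACATGTTTAAAGATTCATTGCATTCCTTACAGTGAGAGAACGATAACACCAATTATTCGACTTACCGATGTGTTACAAACACACACGTCTAGAAATGAATGGTCTGCCTACCCTCCCTCTGAACCGTATATTCAGCTTCGGGCTTTATAAGATCATCTATGAGCGGTTTTTTATAGGCTAAATGTTGAGTAGATGCCTCAATTCTACGGGGAGTGCTCAGGCGGAATTTAAATTATGGGATAAAAAAGGCCTAAAGTCCCCACCCATTGCCATTAAGGTTCATAAGCACATGACATTGGTCAGGTATTTTACACGGTATGTTCATTTCTACTACACTGACTAATCCGGGATTCAACGATCTCAGCTTAAGATATAGATGTATGGATTTTTTTTGAGAGTTTCAATCGCTTGTTGCCGTGTACCCTCTGGTTTAACTAGTGTTGGAATGAGCTTCTACCACAGGAATCTCCTAAATCCAGTCTTTTAAAATACCCTTGCTAATCTTTAAAAAGTTGTGGTAACGAGATACCATTAGGTATACCTTAGCTTAATAAATTTCGT",
  trnK_UUU = "GTCTCGAACCGCGATAAGAAGTTACATGTGTAGTAATTCCCTGAAATCAAGGATACCTTATAATTAGTGTTT",
  trnQ_UUG = "GAAGACTATGACCGCTTGCTGTTAGACGAGGCGATTCCGAGCTTGGGTTTATTAGAAGACTGCTATTCCGAG",
  rps16_exon1 = "AAGGCTTGAATAAAAATAGACCGGGCTTGTATCCATGTACAT",
  rps16_exon2 = "TTAGAGGATTATTTCTGACTTTAAATAACGATTAATGGTCCCGCAACATAGTACACGCTTCGAGAACCAAACCGTTCCATAAGTTATTGAGTTTGGAATGGACATTCTACATTACAAGGTTTGAATATGATTAACGAGCAGTTGGCTGCCATAACACTCTTAGGGCAAAGCGTTGAATTCATTTGAAGTTAACGACTATTTTTTAAGCTCAAGATAATTGATTTCGT",
  ndhF = "CAAAAAGTGAGATAGTTATTTGAAAAAGCTGCACATTGAAGATACTATTGATAACTCCTCTGTTTAAGGAATTTTGATACCGTACGACGCGTTGGGCGTAACCGTGCTTCTAATCCGCGTCTAGGAAGACCCAATAGATGTGTATATGAACAAAATGATATTTAAATTTAATAGGAATATAATGTTTGTATTTTGGTATATGAGGTAATCATAATTTAGCATCGCTATTATCACGATATCACCGTTACCGTTAAGGATAGGACAATCCCTACTATTTAAATTTACCCGACACCATGTATATAAGAATTATTACTGAAATAAGCCTACACCACAGAGTAAATGGCTTTATAAATATCGGTCTAATAAACGAGTTCTATCATCATGAACCGGTCTTATCGATTAATTAGTGGATAATTCTAATTTTATTGGTTCTGTTCTGGAACTACACTCCCTTCCTTTGTTTGTCAAGGCTTTTCTCCAGATAAACCTGAGGACCGGGGTTTTCTTGATTTCATGTCATCAACTCTCCTGTAAGTATAC",
  trnI_CAU = "AAGTCCCAGATGGTTGGTTGATGCCACATTATGGATGAAAAGCATGGTCATATATCAAGCTGACTTGAATATCT"
)
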