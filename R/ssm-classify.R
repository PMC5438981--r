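#' Classify the repeat-origin scenario of an IGS profile
#'
#' Assigns an rpl23--ycf2 spacer profile to one of the hypothesized
#' repeat-origin scenarios via an explicit first-match decision table:
#' \enumerate{
#'   \item no array with unit length >= 18 bp: \code{NONE};
#'   \item >= 3 trnI_CAU copies, some array unit containing the full
#'     reference trnI (>= 95\% identity), and no U16 motif: \code{I}
#'     (slipped-strand duplication seeded at R1b, carrying the whole tRNA);
#'   \item exactly 3 trnI copies with a U16 hit: \code{III_B} (HFIR-derived
#'     U16 as the initial unit, then SSM);
#'   \item exactly 2 trnI copies, exactly 2 units in total, and an R1a hit:
#'     \code{II} (point-mutation-created R1/R1a direct repeat, then SSM) --
#'     the observed R1a motif is required, not merely inferred;
#'   \item exactly 1 trnI copy with at least one array in the trnI--ycf2
#'     sub-spacer: \code{III_A} (unequal recombination downstream of trnI);
#'   \item otherwise \code{COMPLEX}.
#' }
#' Rule 2 accepts >= 3 copies (not exactly 3) so over-expanded arrays still
#' classify; the threshold is exposed via \code{min_trnI_scenario_I}.
#'
#' @param profile An \code{\link{igs_profile}} with repeats and motifs
#'   populated (as \code{\link{profile_igs}} produces).
#' @param ref_trnI Reference trnI_CAU sequence used for the unit-spans-trnI
#'   test of rule 2.
#' @param min_unit Unit-length floor defining a qualifying array (18 bp).
#' @param min_trnI_scenario_I Minimum trnI copies for rule 2 (default 3).
#' @return Object of class \code{scenario_call}: \code{label} in
#'   \code{{I, II, III_A, III_B, NONE, COMPLEX}} plus \code{evidence} flags.
#' @export
classify_scenario <- function(profile, ref_trnI = trnI_reference(),
                              min_unit = 18, min_trnI_scenario_I = 3) {
  if (is.null(profile$motif_hits))
    stop("profile lacks a motif scan; run scan_motifs()/profile_igs() first")
  arrays <- Filter(function(a) a$unit_len >= min_unit, profile$repeat_arrays)
  units <- total_repeat_units(arrays, min_unit)
  motifs <- vapply(profile$motif_hits, `[[`, "", "motif_name")
  has <- function(m) m %in% motifs
  k <- profile$trnI_copies

  if (length(arrays) == 0)
    return(.scenario("NONE", character(0)))

  unit_spans_trnI <- any(vapply(arrays, function(a)
    length(count_trnI(a$unit_seq, ref_trnI)) >= 1, logical(1)))
  if (k >= min_trnI_scenario_I && unit_spans_trnI && !has("U16"))
    return(.scenario("I", c(sprintf("%d trnI copies", k),
                            "unit spans trnI", "no U16")))
  if (k == 3 && has("U16"))
    return(.scenario("III_B", c("3 trnI copies", "U16 present")))
  if (k == 2 && units == 2 && has("R1a"))
    return(.scenario("II", c("2 trnI copies", "2 units",
                             "R1a observed in sequence")))
  downstream_start <- profile$total_len - profile$trnI_ycf2_len
  any_downstream <- any(vapply(arrays, function(a)
    a$start >= downstream_start, logical(1)))
  if (k == 1 && any_downstream)
    return(.scenario("III_A", c("1 trnI copy", "array in trnI-ycf2 sub-IGS")))
  .scenario("COMPLEX", c(sprintf("%d trnI copies", k),
                         sprintf("%d units", units)))
}

.scenario <- function(label, evidence) {
  structure(list(label = label, evidence = evidence),
            class = "scenario_call")
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("scenario %s%s\n", x$label,
              if (length(x$evidence))
                paste0(" [", paste(x$evidence, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Repeat-unit length spectrum across profiles
#'
#' Tallies repeat units below versus at-or-above a length threshold across
#' a panel of profiles (24 bp by default, the split at which short units
#' dominate in Parideae spacers).
#'
#' @param profiles List of \code{igs_profile}s.
#' @param threshold Length split in bp (default 24).
#' @return List with \code{short}, \code{long} unit tallies and their
#'   \code{ratio} (\code{NA} with a \code{ratio_undefined} flag when both
#'   are zero or \code{long} is zero).
#' @export
length_spectrum <- function(profiles, threshold = 24) {
  stopifnot(length(profiles) >= 1)
  short <- 0L; long <- 0L
  for (pr in profiles) {
    for (a in pr$repeat_arrays) {
      if (a$unit_len < threshold) short <- short + a$copies
      else long <- long + a$copies
    }
  }
  ratio <- if (long > 0) short / long else NA_real_
  list(short = short, long = long, ratio = ratio,
       ratio_undefined = long == 0L)
}
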