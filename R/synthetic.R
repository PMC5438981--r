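# run expr under a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(expr)
}

# random background of length n with the GC fraction planted exactly
# (counts, not expectations), shuffled
.background <- function(n, gc = 37.5) {
  if (n <= 0) return("")
  ngc <- round(n * gc / 100)
  ng <- ngc %/% 2L
  na <- (n - ngc) %/% 2L
  pool <- c(rep("G", ng), rep("C", ngc - ng),
            rep("A", na), rep("T", n - ngc - na))
  paste(sample(pool), collapse = "")
}

.splice <- function(s, at, insert) {
  # insert string after 0-based position `at` (i.e., before index at in 0-based)
  paste0(substr(s, 1, at), insert, substr(s, at + 1, nchar(s)))
}

#' Synthetic plastome configuration
#'
#' Bundles every knob of the synthetic-plastome generator. Defaults emulate
#' a typical Melanthiaceae plastome: an ~85 kb LSC, ~18 kb SSC and ~27 kb
#' IR arms, background base composition GC 37.5\%, a JLB falling 6 bp
#' inside rps3, an intact rps16 locus and a repeat-free spacer cassette.
#'
#' @param seed Integer seed; the same configuration always yields a
#'   byte-identical genome.
#' @param lsc_len,ssc_len,ir_len Region lengths (bp).
#' @param junction_spec Named list per junction (currently \code{JLB}),
#'   each \code{list(element=, overlap_bp=)}; \code{element} is a gene
#'   symbol of the junction cassette or an IGS label
#'   \code{"geneA/geneB"} with \code{overlap_bp = 0}.
#' @param rps16_state One of \code{INTACT, EXON1_LOST, EXON2_LOST,
#'   EXON2_PARTIAL, COMPLETE_LOSS}.
#' @param igs_spec \code{list(scenario=, n_units=, unit_len=)} forwarded to
#'   \code{\link{simulate_ssm_cassette}}.
#' @param mutation_rate Per-base substitution rate applied to background
#'   sequence (planted genes, cassettes and 50 bp margins flanking each
#'   region boundary are never mutated, so planted coordinates stay exact);
#'   must lie in [0, 0.05].
#' @param gc Background GC percent.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1, lsc_len = 85000, ssc_len = 18000,
                         ir_len = 27000,
                         junction_spec = list(JLB = list(element = "rps3",
                                                         overlap_bp = 6)),
                         rps16_state = "INTACT",
                         igs_spec = list(scenario = "NONE"),
                         mutation_rate = 0, gc = 37.5) {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0,
            mutation_rate >= 0, mutation_rate <= 0.05)
  structure(list(seed = seed, lsc_len = lsc_len, ssc_len = ssc_len,
                 ir_len = ir_len, junction_spec = junction_spec,
                 rps16_state = rps16_state, igs_spec = igs_spec,
                 mutation_rate = mutation_rate, gc = gc),
            class = "synth_config")
}

#' Point-substitute a sequence at a fixed rate
#'
#' I.i.d. per-base substitution to a uniformly chosen different base;
#' seeded and reproducible. The expected number of substitutions is
#' \code{rate * nchar(seq)}.
#'
#' @param seq Nucleotide string.
#' @param rate Substitution probability per base, in [0, 1].
#' @param seed Integer seed.
#' @return Mutated sequence of identical length.
#' @export
mutate <- function(seq, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(seq)
  .with_seed(seed, {
    x <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(x)) < rate)
    for (i in hit) {
      x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
    }
    paste(x, collapse = "")
  })
}

# force the bases flanking a planted tandem tract to differ from the unit
# continuation, so the planted tract is the unique maximal report
.guard_tract <- function(s, start0, p, ncopies) {
  unit_first <- substr(s, start0 + 1L, start0 + 1L)
  unit_last <- substr(s, start0 + p, start0 + p)
  other <- function(b) if (b == "A") "C" else "A"
  if (start0 >= 1L && substr(s, start0, start0) == unit_last)
    substr(s, start0, start0) <- other(unit_last)
  after <- start0 + ncopies * p + 1L
  if (after <= nchar(s) && substr(s, after, after) == unit_first)
    substr(s, after, after) <- other(unit_first)
  s
}

# motif landmarks of the base spacer cassette (0-based offsets in `up`)
.CAS <- list(R1_at = 20L, D7_at = 100L, R1b_at = 110L, R1_2_at = 120L,
             up_len = 164L, down_len = 68L)

# base rpl23--ycf2 spacer: up gap with the conserved motif cluster, one
# trnI_CAU, then the conserved 68 bp downstream gap
.base_cassette <- function(gc = 37.5) {
  cas <- .CAS
  mot <- motif_catalog()
  up <- strsplit(.background(cas$up_len, gc), "")[[1]]
  plant <- function(v, at, s) { v[(at + 1):(at + nchar(s))] <- strsplit(s, "")[[1]]; v }
  up <- plant(up, cas$R1_at, mot[["R1"]])
  up <- plant(up, cas$D7_at, mot[["D7"]])
  up <- plant(up, cas$R1b_at, mot[["R1b"]])
  up <- plant(up, cas$R1_2_at, mot[["R1"]])
  paste0(paste(up, collapse = ""), .gene_seqs[["trnI_CAU"]],
         .background(cas$down_len, gc))
}

#' Simulate a repeat-accumulation scenario in the rpl23--ycf2 spacer
#'
#' Builds a repeat-free base cassette (164 bp upstream gap carrying the
#' conserved R1/R1b/D7 motif cluster, one trnI_CAU, 68 bp downstream gap)
#' and then applies the generative events of the requested scenario:
#' \describe{
#'   \item{NONE}{no event.}
#'   \item{I}{one slipped-strand duplication of a window anchored at the
#'     standalone R1b and spanning the whole trnI, to 3 tandem copies.}
#'   \item{II}{a single A->C point mutation converting the trnI-proximal R1
#'     into R1a, then one duplication of a trnI-spanning window (2 copies).}
#'   \item{III_A}{insertion of a fresh initial unit immediately downstream
#'     of trnI (unequal recombination), then n-1 duplications.}
#'   \item{III_B}{HFIR between the two D7 copies writes the 16 bp U16 unit
#'     at the upstream D7, then duplication of a window containing both U16
#'     and trnI to 3 tandem copies.}
#' }
#' The generator only plants; it performs no inference, and classifiers
#' never see the event log.
#'
#' @param scenario One of \code{"NONE", "I", "II", "III_A", "III_B"}.
#' @param params Optional overrides: \code{n_units} (III_A copies, default
#'   6), \code{unit_len} (III_A unit length, default 30), \code{gc}.
#' @param seed Integer seed.
#' @return List with \code{igs_seq}, \code{truth} (planted trnI copy count,
#'   arrays, scenario) and \code{event_log}.
#' @export
simulate_ssm_cassette <- function(scenario, params = list(), seed = 1) {
  scenario <- as.character(scenario)
  if (!scenario %in% c("NONE", "I", "II", "III_A", "III_B"))
    stop("invalid scenario: ", scenario)
  gc <- if (is.null(params$gc)) 37.5 else params$gc
  cas <- .CAS
  .with_seed(seed, {
    s <- .base_cassette(gc)
    trnI_at <- cas$up_len
    trnI_len <- nchar(.gene_seqs[["trnI_CAU"]])
    log <- list()
    arrays <- list()
    trnI_copies <- 1L
    if (scenario == "I") {
      w0 <- cas$R1b_at; wlen <- 164L
      W <- substr(s, w0 + 1, w0 + wlen)
      s <- .splice(s, w0 + wlen, paste0(W, W))
      s <- .guard_tract(s, w0, wlen, 3L)
      log <- c(log, list(list(type = "ssm_duplication", anchor = "R1b",
                              window = c(w0, w0 + wlen), copies_added = 2L)))
      arrays <- list(list(unit_len = wlen, copies = 3L, start = w0))
      trnI_copies <- 3L
    } else if (scenario == "II") {
      pos <- cas$R1_2_at + 1L  # second base of the trnI-proximal R1: A -> C
      before <- s
      substr(s, pos + 1, pos + 1) <- "C"
      log <- c(log, list(list(type = "point_mutation", position = pos,
                              from = "A", to = "C",
                              cassette_before = before)))
      w0 <- cas$R1_2_at; wlen <- 130L
      W <- substr(s, w0 + 1, w0 + wlen)
      s <- .splice(s, w0 + wlen, W)
      s <- .guard_tract(s, w0, wlen, 2L)
      log <- c(log, list(list(type = "ssm_duplication", anchor = "R1a",
                              window = c(w0, w0 + wlen), copies_added = 1L)))
      arrays <- list(list(unit_len = wlen, copies = 2L, start = w0))
      trnI_copies <- 2L
    } else if (scenario == "III_A") {
      n_units <- if (is.null(params$n_units)) 6L else as.integer(params$n_units)
      unit_len <- if (is.null(params$unit_len)) 30L else as.integer(params$unit_len)
      stopifnot(n_units >= 2, unit_len >= 18)
      U <- .background(unit_len, gc)
      q <- trnI_at + trnI_len + 10L
      s <- .splice(s, q, strrep(U, n_units))
      s <- .guard_tract(s, q, unit_len, n_units)
      log <- c(log,
               list(list(type = "initial_unit_insertion", position = q,
                         unit = U)),
               list(list(type = "ssm_duplication", anchor = "initial unit",
                         window = c(q, q + unit_len),
                         copies_added = n_units - 1L)))
      arrays <- list(list(unit_len = unit_len, copies = n_units, start = q))
    } else if (scenario == "III_B") {
      ins_at <- cas$D7_at + 7L
      s <- .splice(s, ins_at, "CTTAACAGG")
      log <- c(log, list(list(type = "hfir_insertion", position = ins_at,
                              inserted = "CTTAACAGG",
                              result = "U16 at upstream D7")))
      trnI_at <- trnI_at + 9L
      w0 <- 95L; wlen <- 172L
      W <- substr(s, w0 + 1, w0 + wlen)
      s <- .splice(s, w0 + wlen, paste0(W, W))
      s <- .guard_tract(s, w0, wlen, 3L)
      log <- c(log, list(list(type = "ssm_duplication", anchor = "U16",
                              window = c(w0, w0 + wlen), copies_added = 2L)))
      arrays <- list(list(unit_len = wlen, copies = 3L, start = w0))
      trnI_copies <- 3L
    }
    list(igs_seq = s,
         truth = list(scenario = scenario, trnI_copies = trnI_copies,
                      arrays = arrays, total_len = nchar(s)),
         event_log = log)
  })
}

# the JLB gene cassette: rps3, rpl22, rps19, trnH_GUG in coordinate order
# (trnH deepest in the IR), 30 bp gaps
.junction_cassette <- function(gc) {
  genes <- c("rps3", "rpl22", "rps19", "trnH_GUG")
  gaps <- vapply(1:3, function(i) .background(30L, gc), character(1))
  seqs <- .gene_seqs[genes]
  s <- paste0(seqs[1], gaps[1], seqs[2], gaps[2], seqs[3], gaps[3], seqs[4])
  offs <- cumsum(c(0L, nchar(seqs[1]), 30L, nchar(seqs[2]), 30L,
                   nchar(seqs[3]), 30L))
  starts <- offs[c(1, 3, 5, 7)]
  names(starts) <- genes
  list(seq = s, starts = starts,
       lens = stats::setNames(nchar(seqs), genes))
}

# rps16 locus block realizing an integrity state; primer sites flank the
# locus so product sizes type the state (~2.2 kb intact, 1.5 kb exon-2-lost,
# 400 bp complete loss)
.rps16_block <- function(state, gc) {
  fw <- rps16_primers()$forward
  rv <- rps16_primers()$reverse
  e1 <- .gene_seqs[["rps16_exon1"]]
  e2 <- .gene_seqs[["rps16_exon2"]]
  padA <- .background(706L, gc); padM <- .background(480L, gc)
  padB <- .background(712L, gc)
  # guard: the base preceding the 47 bp exon-2 remnant must differ from the
  # reference base before the retained suffix, so retention measures 47
  pre47 <- substr(e2, nchar(e2) - 47L, nchar(e2) - 47L)
  if (substr(padA, 706L, 706L) == pre47)
    substr(padA, 706L, 706L) <- if (pre47 == "A") "C" else "A"
  inner <- switch(state,
    INTACT        = list(seq = paste0(padA, e2, padM, e1, padB),
                         e2_at = 706L, e2_len = nchar(e2),
                         e1_at = 706L + nchar(e2) + 480L),
    EXON1_LOST    = list(seq = paste0(padA, e2, padM, padB),
                         e2_at = 706L, e2_len = nchar(e2), e1_at = NA),
    EXON2_LOST    = list(seq = paste0(padA, e1, padB),
                         e2_at = NA, e2_len = 0L, e1_at = 706L),
    EXON2_PARTIAL = list(seq = paste0(padA, substr(e2, nchar(e2) - 46, nchar(e2)),
                                      padM, padB),
                         e2_at = 706L, e2_len = 47L, e1_at = NA),
    COMPLETE_LOSS = list(seq = paste0(.background(360L, gc)),
                         e2_at = NA, e2_len = 0L, e1_at = NA),
    stop("unknown rps16 state: ", state))
  list(seq = paste0(fw, inner$seq, revcomp(rv)),
       e1_at = if (is.na(inner$e1_at)) NA else inner$e1_at + nchar(fw),
       e2_at = if (is.na(inner$e2_at)) NA else inner$e2_at + nchar(fw),
       e2_len = inner$e2_len)
}

#' Generate a synthetic plastome with planted ground truth
#'
#' Emits a circular quadripartite genome realizing the configuration
#' exactly: an exact IR arm pair (the IRa arm is the byte-wise reverse
#' complement of IRb, and region boundaries are constructed so the arms
#' cannot be extended), the junction gene cassette
#' (rps3/rpl22/rps19/trnH_GUG) positioned to realize \code{junction_spec},
#' a trnK--rps16--trnQ locus realizing \code{rps16_state} with primer sites
#' planted for in-silico PCR, and an rpl23--trnI_CAU--ycf2 cassette inside
#' IRb realizing \code{igs_spec} (mirrored into IRa with its annotations).
#' Identical configurations produce byte-identical records.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{record} (a \code{\link{plastome_record}}) and
#'   \code{truth} (planted partition, junction contexts, rps16 class, IGS
#'   profile facts, event log).
#' @export
generate_plastome <- function(config = synth_config()) {
  gc <- config$gc
  .with_seed(config$seed, {
    cass <- .junction_cassette(gc)
    jlb_spec <- config$junction_spec$JLB
    if (is.null(jlb_spec)) jlb_spec <- list(element = "rps3", overlap_bp = 6)
    el <- jlb_spec$element
    if (grepl("/", el, fixed = TRUE)) {
      pair <- strsplit(el, "/", fixed = TRUE)[[1]]
      # IGS label is "<IR-side>/<LSC-side>"; anchor mid-gap before the IR-side gene
      irg <- pair[1]
      if (!irg %in% names(cass$starts)) stop("unknown junction gene: ", irg)
      anchor <- cass$starts[[irg]] - 15L
      if (jlb_spec$overlap_bp != 0) stop("IGS junction requires overlap_bp = 0")
    } else {
      if (!el %in% names(cass$starts)) stop("unknown junction gene: ", el)
      glen <- cass$lens[[el]]
      if (jlb_spec$overlap_bp > glen)
        stop("unrealizable junction: overlap ", jlb_spec$overlap_bp,
             " exceeds ", el, " length ", glen)
      anchor <- cass$starts[[el]] + glen - jlb_spec$overlap_bp
    }
    lsc_tail <- substr(cass$seq, 1, anchor)
    irb_head <- substr(cass$seq, anchor + 1, nchar(cass$seq))

    rps16 <- .rps16_block(config$rps16_state, gc)
    sim <- simulate_ssm_cassette(
      config$igs_spec$scenario %||% "NONE",
      params = config$igs_spec[setdiff(names(config$igs_spec), "scenario")],
      seed = config$seed + 7L)

    lsc_len <- config$lsc_len; ssc_len <- config$ssc_len
    ir_len <- config$ir_len

    # ---- LSC: [bg1][trnK pad rps16-block pad trnQ][bg2][junction tail]
    trnK <- .gene_seqs[["trnK_UUU"]]; trnQ <- .gene_seqs[["trnQ_UUG"]]
    mid <- paste0(trnK, .background(80L, gc), rps16$seq,
                  .background(80L, gc), trnQ)
    fixed_len <- nchar(mid) + nchar(lsc_tail)
    bg_total <- lsc_len - fixed_len
    if (bg_total < 200) stop("lsc_len too small for planted loci")
    bg1_len <- bg_total %/% 2L
    bg2_len <- bg_total - bg1_len
    bg1 <- .background(bg1_len, gc); bg2 <- .background(bg2_len, gc)
    lsc <- paste0(bg1, mid, bg2, lsc_tail)
    mid_at <- bg1_len                           # 0-based offset of trnK

    # ---- IRb: [junction head][pad][rpl23][igs][ycf2][bg]
    rpl23 <- .gene_seqs[["rpl23"]]; ycf2 <- .gene_seqs[["ycf2"]]
    pad <- .background(150L, gc)
    core <- paste0(irb_head, pad, rpl23, sim$igs_seq, ycf2)
    bg3_len <- ir_len - nchar(core)
    if (bg3_len < 100) stop("ir_len too small for planted cassette")
    irb <- paste0(core, .background(bg3_len, gc))

    # ---- SSC with an ndhF mid-region
    ndhF <- .gene_seqs[["ndhF"]]
    half <- (ssc_len - nchar(ndhF)) %/% 2L
    if (half < 100) stop("ssc_len too small")
    ssc <- paste0(.background(half, gc), ndhF,
                  .background(ssc_len - nchar(ndhF) - half, gc))

    # forbid IR extension across the junctions: single-copy bases adjacent
    # to both IR arms must not be reverse complements of each other
    substr(ssc, 1, 1) <- "A"; substr(ssc, ssc_len, ssc_len) <- "A"
    last_lsc <- substr(lsc, lsc_len, lsc_len)
    s0 <- if (last_lsc == "T") "C" else "A"   # avoid s0 == complement(last)
    substr(lsc, 1, 1) <- s0

    genome <- paste0(lsc, irb, ssc, revcomp(irb))
    n <- nchar(genome)

    # background mutation (substitutions only; planted loci and 50 bp
    # junction margins stay exact, so planted coordinates remain valid)
    if (config$mutation_rate > 0) {
      mask <- rep(FALSE, n)
      mk <- function(a, b) if (b >= a) mask[a:b] <<- TRUE  # 1-based
      mk(52L, bg1_len - 1L)
      mk(bg1_len + nchar(mid) + 2L, bg1_len + nchar(mid) + bg2_len - 1L)
      irb0 <- lsc_len
      mk(irb0 + nchar(core) + 51L, irb0 + ir_len - 50L)
      ssc0 <- lsc_len + ir_len
      mk(ssc0 + 52L, ssc0 + half - 1L)
      mk(ssc0 + half + nchar(ndhF) + 2L, ssc0 + ssc_len - 51L)
      x <- strsplit(genome, "")[[1]]
      hit <- which(mask & stats::runif(n) < config$mutation_rate)
      for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
      # keep the IR arms exact copies: re-mirror IRb onto IRa
      genome <- paste(x, collapse = "")
      irb_now <- substr(genome, lsc_len + 1L, lsc_len + ir_len)
      genome <- paste0(substr(genome, 1, lsc_len + ir_len + ssc_len),
                       revcomp(irb_now))
    }

    # ---- features --------------------------------------------------------
    feats <- list()
    addf <- function(name, kind, strand, start, len) {
      feats[[length(feats) + 1L]] <<- gene_feature(
        name, kind, strand, interval(start, start + len))
    }
    # junction cassette: absolute start of cassette = lsc_len - anchor
    cas0 <- lsc_len - anchor
    for (g in names(cass$starts)) {
      kind <- if (g == "trnH_GUG") "tRNA" else "CDS"
      strand <- if (g == "trnH_GUG") "-" else "+"
      addf(g, kind, strand, cas0 + cass$starts[[g]], cass$lens[[g]])
    }
    # rps16 neighbourhood
    addf("trnK_UUU", "tRNA", "-", mid_at, nchar(trnK))
    rps16_at <- mid_at + nchar(trnK) + 80L
    addf("trnQ_UUG", "tRNA", "-",
         mid_at + nchar(mid) - nchar(trnQ), nchar(trnQ))
    if (!is.na(rps16$e1_at) || !is.na(rps16$e2_at)) {
      parts <- list()
      if (!is.na(rps16$e1_at))
        parts <- c(parts, list(interval(rps16_at + rps16$e1_at,
                                        rps16_at + rps16$e1_at + 42L)))
      if (!is.na(rps16$e2_at))
        parts <- c(parts, list(interval(rps16_at + rps16$e2_at,
                                        rps16_at + rps16$e2_at + rps16$e2_len)))
      feats[[length(feats) + 1L]] <- gene_feature(
        "rps16", "CDS", "-", parts,
        is_pseudo = config$rps16_state != "INTACT")
    }
    addf("ndhF", "CDS", "-", lsc_len + ir_len + half, nchar(ndhF))
    # rpl23 / trnI / ycf2 in IRb, plus mirrored IRa copies
    irb0 <- lsc_len
    rpl23_at <- irb0 + nchar(irb_head) + 150L
    igs_at <- rpl23_at + nchar(rpl23)
    ycf2_at <- igs_at + nchar(sim$igs_seq)
    mirror <- function(start, len) {
      off <- start - irb0
      n - ir_len + (ir_len - off - len)
    }
    addf("rpl23", "CDS", "+", rpl23_at, nchar(rpl23))
    addf("rpl23", "CDS", "-", mirror(rpl23_at, nchar(rpl23)), nchar(rpl23))
    addf("ycf2", "CDS", "+", ycf2_at, nchar(ycf2))
    addf("ycf2", "CDS", "-", mirror(ycf2_at, nchar(ycf2)), nchar(ycf2))
    trnI_len <- nchar(.gene_seqs[["trnI_CAU"]])
    trnI_rel <- .planted_trnI_offsets(sim$truth)
    for (o in trnI_rel) {
      addf("trnI_CAU", "tRNA", "+", igs_at + o, trnI_len)
      addf("trnI_CAU", "tRNA", "-", mirror(igs_at + o, trnI_len), trnI_len)
    }

    record <- plastome_record(
      identifier = sprintf("synth_seed%d", config$seed),
      sequence = genome, is_circular = TRUE, features = feats,
      source = "synthetic")

    junctions <- lapply(names(config$junction_spec), function(jn) {
      list(junction_name = jn,
           containing_element = config$junction_spec[[jn]]$element,
           overlap_bp = config$junction_spec[[jn]]$overlap_bp)
    })
    names(junctions) <- names(config$junction_spec)

    truth <- list(
      partition = list(lsc = interval(0L, lsc_len),
                       irb = interval(lsc_len, lsc_len + ir_len),
                       ssc = interval(lsc_len + ir_len,
                                      lsc_len + ir_len + ssc_len),
                       ira = interval(lsc_len + ir_len + ssc_len, n),
                       lengths = c(lsc = lsc_len, irb = ir_len,
                                   ssc = ssc_len, ira = ir_len)),
      junctions = junctions,
      rps16_class = config$rps16_state,
      igs = sim$truth,
      igs_start = igs_at,
      event_log = sim$event_log)
    list(record = record, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based offsets of planted trnI copies within the simulated cassette
.planted_trnI_offsets <- function(truth) {
  base_at <- .CAS$up_len
  switch(truth$scenario,
    NONE = base_at,
    III_A = base_at,
    I = {
      a <- truth$arrays[[1]]
      a$start + (0:2) * a$unit_len + (base_at - a$start)
    },
    II = {
      a <- truth$arrays[[1]]
      a$start + (0:1) * a$unit_len + (base_at - a$start)
    },
    III_B = {
      a <- truth$arrays[[1]]
      first <- base_at + 9L                      # HFIR insertion shifts trnI
      a$start + (0:2) * a$unit_len + (first - a$start)
    })
}
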