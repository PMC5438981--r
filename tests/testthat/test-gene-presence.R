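refs <- rps16_reference_exons()

# assemble a locus region with chosen exon content between random pads
locus_region <- function(exon2 = NULL, exon1 = NULL, seed = 1) {
  set.seed(seed)
  paste0(rand_seq(300), if (!is.null(exon2)) exon2, rand_seq(250),
         if (!is.null(exon1)) exon1, rand_seq(300))
}

test_that("the five rps16 integrity states map to five distinct classes", {
  st_int <- classify_rps16(locus_region(refs$exon2, refs$exon1))
  expect_equal(st_int$class, "INTACT")
  expect_equal(unname(st_int$retained_bp["exon1"]), nchar(refs$exon1))
  expect_equal(unname(st_int$retained_bp["exon2"]), nchar(refs$exon2))

  expect_equal(classify_rps16(locus_region(exon1 = refs$exon1))$class,
               "EXON2_LOST")
  expect_equal(classify_rps16(locus_region(exon2 = refs$exon2))$class,
               "EXON1_LOST")

  rem47 <- substr(refs$exon2, nchar(refs$exon2) - 46, nchar(refs$exon2))
  # guard base: the flank must not continue the reference, or the remnant
  # measures longer than its planted 47 bp
  pre <- substr(refs$exon2, nchar(refs$exon2) - 47, nchar(refs$exon2) - 47)
  guard <- if (pre == "A") "C" else "A"
  set.seed(1)
  region_part <- paste0(rand_seq(299), guard, rem47, rand_seq(250))
  st_part <- classify_rps16(region_part)
  expect_equal(st_part$class, "EXON2_PARTIAL")
  expect_equal(unname(st_part$retained_bp["exon2"]), 47)

  expect_equal(classify_rps16(locus_region())$class, "COMPLETE_LOSS")
})

test_that("the classifier is monotone under successive exon deletion", {
  for (seed in 1:5) {
    full <- classify_rps16(locus_region(refs$exon2, refs$exon1, seed = seed))
    no2 <- classify_rps16(locus_region(exon1 = refs$exon1, seed = seed))
    none <- classify_rps16(locus_region(seed = seed))
    expect_equal(full$class, "INTACT")
    expect_equal(no2$class, "EXON2_LOST")
    expect_equal(none$class, "COMPLETE_LOSS")
  }
})

test_that("a reference region classifies as fully intact", {
  region <- paste0(refs$exon2, rand_seq(100, seed = 8), refs$exon1)
  st <- classify_rps16(region)
  expect_equal(st$class, "INTACT")
  expect_equal(unname(st$retained_bp),
               c(nchar(refs$exon1), nchar(refs$exon2)))
  expect_error(classify_rps16(region, ref_exon1 = ""), "non-empty")
})

test_that("in-silico PCR sizes a constructed template and honours 3' ends", {
  pr <- rps16_primers()
  set.seed(21)
  tpl <- paste0(pr$forward, rand_seq(360), rc_chars(pr$reverse))
  amps <- insilico_pcr(tpl, pr)
  expect_length(amps, 1)
  expect_equal(amps[[1]]$length_bp, 400L)
  expect_equal(amps[[1]]$strand_of_forward, "+")

  # no reverse-primer site -> no product
  expect_length(insilico_pcr(paste0(pr$forward, rand_seq(360)), pr), 0)

  # an internal mismatch is tolerated only within the mismatch budget
  tpl_mid <- tpl
  substr(tpl_mid, 10, 10) <- if (substr(tpl_mid, 10, 10) == "A") "C" else "A"
  expect_length(insilico_pcr(tpl_mid, pr, max_mismatch = 0), 0)
  expect_length(insilico_pcr(tpl_mid, pr, max_mismatch = 1), 1)
  # but a mutated 3'-terminal base kills the product even within budget
  tpl3 <- tpl
  substr(tpl3, 20, 20) <- if (substr(tpl3, 20, 20) == "A") "C" else "A"
  expect_length(insilico_pcr(tpl3, pr, max_mismatch = 1), 0)
  expect_length(insilico_pcr(tpl3, pr, max_mismatch = 0), 0)
})

test_that("products crossing the circular origin are found", {
  pr <- rps16_primers()
  set.seed(22)
  lin <- paste0(pr$forward, rand_seq(360), rc_chars(pr$reverse))
  bg <- rand_seq(3000)
  rot <- paste0(substr(lin, 201, 400), bg, substr(lin, 1, 200))
  rec <- plastome_record("circ", rot, is_circular = TRUE)
  amps <- insilico_pcr(rec, pr)
  expect_length(amps, 1)
  expect_equal(amps[[1]]$length_bp, 400L)
})

test_that("amplicon sets equal the naive all-pairs scan on random templates", {
  pr <- rps16_primers()
  for (seed in 1:10) {
    set.seed(seed * 31)
    tpl <- rand_seq(5000)
    # plant 1-3 sites of each primer orientation
    x <- strsplit(tpl, "")[[1]]
    put <- function(x, at, s) { x[(at + 1):(at + nchar(s))] <- strsplit(s, "")[[1]]; x }
    x <- put(x, 100, pr$forward)
    x <- put(x, 100 + 20 + sample(200:2000, 1), rc_chars(pr$reverse))
    if (seed %% 2 == 0) x <- put(x, 3500, pr$reverse)
    if (seed %% 3 == 0) x <- put(x, 4300, rc_chars(pr$forward))
    tpl <- paste(x, collapse = "")
    expect_identical(pcr_sig(insilico_pcr(tpl, pr)),
                     pcr_sig(oracle_pcr(tpl, pr)))
  }
})

test_that("section calls are a pure function of amplicon length", {
  amp <- function(len) list(list(start = 0L, end = len, length_bp = len,
                                 strand_of_forward = "+"))
  expect_equal(veratrum_section_call(amp(1500)), "sect. Veratrum")
  expect_equal(veratrum_section_call(amp(400)), "sect. Fuscoveratrum")
  expect_equal(veratrum_section_call(list()), "indeterminate")
  expect_equal(veratrum_section_call(amp(900)), "indeterminate")
  expect_equal(veratrum_section_call(c(amp(400), amp(1500))), "indeterminate")
})

test_that("synthetic rps16 loss states produce the diagnostic product sizes", {
  sizes <- c(EXON2_LOST = 1500L, COMPLETE_LOSS = 400L)
  calls <- c(EXON2_LOST = "sect. Veratrum",
             COMPLETE_LOSS = "sect. Fuscoveratrum")
  for (state in names(sizes)) {
    g <- generate_plastome(synth_config(seed = 17, lsc_len = 7000,
                                        ssc_len = 2000, ir_len = 2500,
                                        rps16_state = state))
    amps <- insilico_pcr(g$record, rps16_primers())
    expect_length(amps, 1)
    expect_equal(amps[[1]]$length_bp, sizes[[state]])
    expect_equal(veratrum_section_call(amps), calls[[state]])
  }
})
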