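trnI <- trnI_reference()

test_that("trnI copies are counted by similarity on either strand", {
  set.seed(12)
  two <- paste0(rand_seq(50), trnI, rand_seq(40), trnI, rand_seq(50))
  hits <- count_trnI(two)
  expect_length(hits, 2)
  expect_equal(hits[[1]]$start, 50)
  expect_equal(attr(hits[[1]], "strand"), "+")

  # two mismatches in a 74 nt copy: 72/74 = 97.3% identity, still a hit
  mut <- trnI
  substr(mut, 10, 10) <- "C"; substr(mut, 40, 40) <- "G"
  expect_true(substr(trnI, 10, 10) != "C" && substr(trnI, 40, 40) != "G")
  one <- paste0(rand_seq(60), mut, rand_seq(60))
  hits2 <- count_trnI(one)
  expect_length(hits2, 1)
  expect_equal(attr(hits2[[1]], "mismatches"), 2L)

  rcc <- paste0(rand_seq(60), rc_chars(trnI), rand_seq(60))
  hits3 <- count_trnI(rcc)
  expect_length(hits3, 1)
  expect_equal(attr(hits3[[1]], "strand"), "-")

  expect_length(count_trnI(rand_seq(500, seed = 3)), 0)
})

test_that("planted tandem arrays are recovered exactly", {
  set.seed(33)
  unit <- rand_seq(24)
  # flank guards: bases adjacent to the tract differ from the unit
  # continuation, so the planted tract is the unique maximal report
  left <- rand_seq(80); right <- rand_seq(80)
  if (substr(left, 80, 80) == substr(unit, 24, 24)) substr(left, 80, 80) <- "N"
  if (substr(right, 1, 1) == substr(unit, 1, 1)) substr(right, 1, 1) <- "N"
  left <- gsub("N", if (substr(unit, 24, 24) == "A") "C" else "A", left)
  right <- gsub("N", if (substr(unit, 1, 1) == "A") "C" else "A", right)
  s <- paste0(left, strrep(unit, 3), right)
  arr <- find_tandem_repeats(s)
  expect_length(arr, 1)
  expect_equal(arr[[1]]$unit_len, 24L)
  expect_equal(arr[[1]]$copies, 3L)
  expect_equal(arr[[1]]$start, 80L)
  expect_equal(arr[[1]]$unit_seq, unit)
  expect_equal(arr[[1]]$identity, 1)
})

test_that("adding one exact copy increments the copy count by one", {
  set.seed(34)
  unit <- rand_seq(30)
  for (k in 2:5) {
    s <- paste0(rand_seq(60), strrep(unit, k), rand_seq(60))
    arr <- find_tandem_repeats(s)
    expect_length(arr, 1)
    expect_equal(arr[[1]]$copies, as.integer(k))
  }
})

test_that("tandem detection equals the brute-force enumeration", {
  # seeded random sequences, some with planted arrays of varied period
  for (seed in 1:25) {
    set.seed(seed * 7)
    n <- sample(60:260, 1)
    s <- rand_seq(n)
    if (seed %% 2 == 0) {
      p <- sample(18:60, 1)
      unit <- rand_seq(p)
      cp <- sample(2:4, 1)
      at <- sample(0:(n - 10), 1)
      s <- paste0(substr(s, 1, at), strrep(unit, cp),
                  substr(s, at + 1, n))
    }
    expect_identical(tandem_sig(find_tandem_repeats(s)),
                     tandem_sig(oracle_tandem(s)),
                     info = paste("seed", seed))
  }
  # mismatch-tolerant path: corrupt one base inside a copy
  for (seed in 1:10) {
    set.seed(seed * 11)
    unit <- rand_seq(40)
    mid <- unit
    pos <- sample(40, 1)
    substr(mid, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mid, pos, pos))[1]
    s <- paste0(rand_seq(50), unit, mid, unit, rand_seq(50))
    expect_identical(tandem_sig(find_tandem_repeats(s)),
                     tandem_sig(oracle_tandem(s)),
                     info = paste("mm seed", seed))
    expect_equal(find_tandem_repeats(s)[[1]]$copies, 3L)
  }
})

test_that("motif scans are exact and equal naive search", {
  cat <- motif_catalog()
  expect_length(Filter(function(h) h$motif_name == "R1",
                       scan_motifs("GGCAAATTCCATGG")), 0)
  hits <- scan_motifs(cat[["U16"]])
  nms <- vapply(hits, `[[`, "", "motif_name")
  pos <- vapply(hits, `[[`, 0L, "position")
  expect_setequal(nms, c("U16", "D7"))
  expect_true(all(pos == 0))

  set.seed(55)
  s <- rand_seq(1000)
  x <- strsplit(s, "")[[1]]
  put <- function(x, at, m) { x[(at + 1):(at + nchar(m))] <- strsplit(m, "")[[1]]; x }
  x <- put(x, 100, cat[["R1"]]); x <- put(x, 300, cat[["U16"]])
  x <- put(x, 600, cat[["R1a"]]); x <- put(x, 800, cat[["R1b"]])
  s <- paste(x, collapse = "")
  expect_identical(motif_sig(scan_motifs(s)), oracle_motifs(s, cat))

  # positional invariance under prepending
  shifted <- scan_motifs(paste0("GG", s))
  expect_equal(vapply(shifted, `[[`, 0L, "position"),
               vapply(scan_motifs(s), `[[`, 0L, "position") + 2L)
})

test_that("spacer extraction reports the survey's length bookkeeping", {
  # Xerophyllum-like layout: 164 + trnI + 68
  base <- simulate_ssm_cassette("NONE", seed = 2)$igs_seq
  rpl23 <- plastrep:::.gene_seqs[["rpl23"]]
  ycf2 <- plastrep:::.gene_seqs[["ycf2"]]
  set.seed(61)
  seqn <- paste0(rand_seq(120), rpl23, base, ycf2, rand_seq(120))
  rec <- plastome_record("toy", seqn, features = list(
    gene_feature("rpl23", "CDS", "+", interval(120, 120 + nchar(rpl23))),
    gene_feature("ycf2", "CDS", "+",
                 interval(120 + nchar(rpl23) + nchar(base),
                          120 + nchar(rpl23) + nchar(base) + nchar(ycf2)))))
  prof <- extract_igs(rec)
  expect_equal(prof$total_len, 306L)
  expect_equal(prof$rpl23_trnI_len, 164L)
  expect_equal(prof$trnI_ycf2_len, 68L)
  expect_equal(prof$trnI_copies, 1L)
  expect_length(prof$repeat_arrays, 0)

  # bookkeeping identity: total = up + down + trnI bases + inter-copy bp
  sim3 <- simulate_ssm_cassette("I", seed = 2)
  prof3 <- profile_igs(sim3$igs_seq)
  expect_equal(prof3$trnI_copies, 3L)
  inter <- prof3$total_len - prof3$rpl23_trnI_len - prof3$trnI_ycf2_len -
    prof3$trnI_copies * nchar(trnI)
  expect_gte(inter, 0)
  expect_equal(prof3$total_len,
               prof3$rpl23_trnI_len + prof3$trnI_ycf2_len +
                 prof3$trnI_copies * nchar(trnI) + inter)

  expect_error(extract_igs(plastome_record("x", rand_seq(500, seed = 1))),
               "rpl23")
})

test_that("a spacer without internal trnI degenerates by convention", {
  set.seed(62)
  prof <- profile_igs(rand_seq(200))
  expect_equal(prof$trnI_copies, 0L)
  expect_equal(prof$rpl23_trnI_len, prof$total_len)
  expect_equal(prof$trnI_ycf2_len, 0L)
})

test_that("the IR copy is profiled once, in rpl23 -> ycf2 orientation", {
  base <- simulate_ssm_cassette("NONE", seed = 9)$igs_seq
  rpl23 <- plastrep:::.gene_seqs[["rpl23"]]
  ycf2 <- plastrep:::.gene_seqs[["ycf2"]]
  fwd <- paste0(rpl23, base, ycf2)
  set.seed(63)
  seqn <- paste0(rand_seq(150), fwd, rand_seq(400), rc_chars(fwd),
                 rand_seq(150))
  a <- 150
  feats <- list(
    gene_feature("rpl23", "CDS", "+", interval(a, a + nchar(rpl23))),
    gene_feature("ycf2", "CDS", "+",
                 interval(a + nchar(rpl23) + nchar(base),
                          a + nchar(fwd))),
    # mirrored copy on the minus strand
    gene_feature("ycf2", "CDS", "-",
                 interval(a + nchar(fwd) + 400,
                          a + nchar(fwd) + 400 + nchar(ycf2))),
    gene_feature("rpl23", "CDS", "-",
                 interval(a + 2 * nchar(fwd) + 400 - nchar(rpl23),
                          a + 2 * nchar(fwd) + 400)))
  rec <- plastome_record("two-copy", seqn, features = feats)
  prof <- extract_igs(rec)
  expect_equal(prof$total_len, nchar(base))
  expect_equal(prof$igs_seq, base)
})

test_that("the trnI-spanning 164 bp triplication carries its own signature", {
  sim <- simulate_ssm_cassette("I", seed = 5)
  arr <- find_tandem_repeats(sim$igs_seq)
  expect_length(arr, 1)
  expect_equal(arr[[1]]$unit_len, 164L)
  expect_equal(arr[[1]]$copies, 3L)
  expect_length(count_trnI(sim$igs_seq), 3)
  # each unit contains the full trnI
  expect_length(count_trnI(arr[[1]]$unit_seq), 1)
})
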