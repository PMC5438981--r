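# plant an exact IR pair into a random circle, with extension-blocking
# flanks so planted coordinates are maximal
plant_ir_circle <- function(n, arm_len, seed, arm2_len = NULL) {
  set.seed(seed)
  arm1 <- rand_seq(arm_len)
  if (is.null(arm2_len)) {
    rest <- n - 2 * arm_len
    g1 <- rest %/% 3
    s <- paste0(rand_seq(g1), arm1, rand_seq(rest - 2 * g1),
                rc_chars(arm1), rand_seq(g1))
    x <- strsplit(s, "")[[1]]
    for (p in c(g1, g1 + arm_len + 1, g1 + arm_len + (rest - 2 * g1),
                n - g1 + 1)) {
      if (p >= 1 && p <= n) x[p] <- "A"
    }
    list(seq = paste(x, collapse = ""),
         irb = c(g1, g1 + arm_len),
         ira = c(n - g1 - arm_len, n - g1))
  } else {
    arm2 <- rand_seq(arm2_len)
    pad <- (n - 2 * arm_len - 2 * arm2_len) %/% 5
    s <- paste0(rand_seq(pad), arm1, rand_seq(pad), rc_chars(arm1),
                rand_seq(pad), arm2, rand_seq(pad), rc_chars(arm2))
    s <- paste0(s, rand_seq(n - nchar(s)))
    list(seq = s,
         irb = c(pad, pad + arm_len),
         ira = c(2 * pad + arm_len, 2 * pad + 2 * arm_len))
  }
}

test_that("a planted exact IR pair is recovered at its coordinates", {
  pl <- plant_ir_circle(20000, 4000, seed = 101)
  rec <- plastome_record("t", pl$seq)
  ir <- find_inverted_repeat(rec, min_len = 1000)
  expect_equal(c(ir$irb$start, ir$irb$end), pl$irb)
  expect_equal(c(ir$ira$start, ir$ira$end), pl$ira)
  # the two arms are exact reverse complements
  expect_identical(extract_region(rec, ir$irb),
                   rc_chars(extract_region(rec, ir$ira)))
})

test_that("the longer of two candidate IR pairs wins, matching brute force", {
  pl <- plant_ir_circle(6000, 1200, seed = 202, arm2_len = 800)
  rec <- plastome_record("t", pl$seq)
  ir <- find_inverted_repeat(rec, min_len = 600)
  bf <- oracle_inverted_repeat(pl$seq, 600)
  expect_equal(interval_length(ir$irb), bf$len)
  expect_equal(ir$irb$start, bf$start1)
  expect_equal(ir$ira$start, bf$start2)
  expect_gte(interval_length(ir$irb), 1200)
})

test_that("sequences without a long IR raise a no-IR error", {
  set.seed(5)
  rec <- plastome_record("noir", rand_seq(6000))
  expect_error(find_inverted_repeat(rec, min_len = 1000),
               "no inverted repeat")
})

test_that("partition assigns LSC/SSC by arc length and tiles the circle", {
  g <- generate_plastome(synth_config(seed = 1, lsc_len = 85000,
                                      ssc_len = 18000, ir_len = 27000))
  ir <- find_inverted_repeat(g$record)
  p <- partition(g$record, ir$irb, ir$ira)
  expect_equal(unname(p$lengths), c(85000, 27000, 18000, 27000))
  expect_equal(p$lsc$start, 0)
  expect_equal(sum(p$lengths), nchar(g$record$sequence))

  for (seed in 1:10) {
    set.seed(seed * 13)
    cfg <- synth_config(seed = seed, lsc_len = sample(6000:9000, 1),
                        ssc_len = sample(1500:3000, 1),
                        ir_len = sample(2400:3500, 1))
    gg <- generate_plastome(cfg)
    irr <- find_inverted_repeat(gg$record, min_len = 1500)
    pp <- partition(gg$record, irr$irb, irr$ira)
    expect_equal(sum(pp$lengths), nchar(gg$record$sequence))
    expect_equal(unname(pp$lengths),
                 c(cfg$lsc_len, cfg$ir_len, cfg$ssc_len, cfg$ir_len))
  }
})

test_that("junction contexts report the containing gene and IR-side overlap", {
  g6 <- generate_plastome(synth_config(seed = 3, lsc_len = 7000,
                                       ssc_len = 2000, ir_len = 2500,
                                       junction_spec = list(
                                         JLB = list(element = "rps3",
                                                    overlap_bp = 6))))
  ir <- find_inverted_repeat(g6$record, min_len = 1500)
  p <- partition(g6$record, ir$irb, ir$ira)
  jc <- junction_context(p, g6$record$features)
  expect_equal(jc$JLB$containing_element, "rps3")
  expect_equal(jc$JLB$overlap_bp, 6L)

  # Zigadenus-like deep expansion
  g161 <- generate_plastome(synth_config(seed = 4, lsc_len = 7000,
                                         ssc_len = 2000, ir_len = 2500,
                                         junction_spec = list(
                                           JLB = list(element = "rps3",
                                                      overlap_bp = 161))))
  ir <- find_inverted_repeat(g161$record, min_len = 1500)
  jc <- junction_context(partition(g161$record, ir$irb, ir$ira),
                         g161$record$features)
  expect_equal(jc$JLB$containing_element, "rps3")
  expect_equal(jc$JLB$overlap_bp, 161L)

  # junction in the trnH_GUG/rps19 spacer: IGS label, IR-side gene first
  gig <- generate_plastome(synth_config(seed = 5, lsc_len = 7000,
                                        ssc_len = 2000, ir_len = 2500,
                                        junction_spec = list(
                                          JLB = list(element = "trnH_GUG/rps19",
                                                     overlap_bp = 0))))
  ir <- find_inverted_repeat(gig$record, min_len = 1500)
  jc <- junction_context(partition(gig$record, ir$irb, ir$ira),
                         gig$record$features)
  expect_equal(jc$JLB$containing_element, "trnH_GUG/rps19")
  expect_equal(jc$JLB$overlap_bp, 0L)
})

test_that("junction boundary ties follow half-open containment", {
  part <- structure(list(lsc = interval(0, 5000),
                         irb = interval(5000, 7000),
                         ssc = interval(7000, 8000),
                         ira = interval(8000, 10000),
                         genome_length = 10000L),
                    class = "quadripartite_partition")
  # gene starting exactly at the JLB point is contained, whole gene in IR
  f1 <- gene_feature("rps19", "CDS", "+", interval(5000, 5279))
  jc <- junction_context(part, list(f1))
  expect_equal(jc$JLB$containing_element, "rps19")
  expect_equal(jc$JLB$overlap_bp, 279L)
  # gene ending exactly at the junction point is an IGS context
  f2 <- gene_feature("rpl22", "CDS", "+", interval(4640, 5000))
  f3 <- gene_feature("trnH_GUG", "tRNA", "-", interval(5100, 5174))
  jc2 <- junction_context(part, list(f2, f3))
  expect_equal(jc2$JLB$containing_element, "trnH_GUG/rpl22")
  expect_equal(jc2$JLB$overlap_bp, 0L)
})

test_that("junction containment agrees with a point-in-interval oracle", {
  set.seed(99)
  for (k in 1:100) {
    n <- 20000L
    part <- structure(list(lsc = interval(0, 9000),
                           irb = interval(9000, 13000),
                           ssc = interval(13000, 15000),
                           ira = interval(15000, 19000),
                           genome_length = n),
                      class = "quadripartite_partition")
    feats <- lapply(seq_len(sample(3:8, 1)), function(i) {
      s <- sample(0:(n - 900), 1)
      gene_feature(paste0("g", i), "CDS", sample(c("+", "-"), 1),
                   interval(s, s + sample(100:800, 1)))
    })
    jc <- junction_context(part, feats, window = n)
    orc <- oracle_junction(part, feats)
    for (jn in names(orc)) {
      if (!is.na(orc[[jn]]$element)) {
        expect_equal(jc[[jn]]$containing_element, orc[[jn]]$element)
        expect_equal(jc[[jn]]$overlap_bp, as.integer(orc[[jn]]$overlap))
      } else {
        # no containing gene: context must be intergenic, never a gene name
        expect_true(grepl("/", jc[[jn]]$containing_element, fixed = TRUE) ||
                    jc[[jn]]$containing_element == "unresolved")
      }
    }
  }
})
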