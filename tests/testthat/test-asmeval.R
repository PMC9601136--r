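# Assembly evaluation: N-statistics, truth alignment, chimera index,
# nonchimeric rate, composite metric and mapping-rate comparison.

test_that("N-statistics follow the cumulative definition", {
  ns <- nStatistics(c(8, 5, 3))
  expect_equal(unname(ns["N10"]), 8)
  expect_equal(unname(ns["N50"]), 8)
  expect_equal(unname(ns["N60"]), 5)
  expect_equal(unname(ns["N100"]), 3)
  expect_true(all(diff(ns) <= 0))

  one <- nStatistics(42)
  expect_true(all(one == 42))

  # merged dominates its parts
  merged <- nStatistics(12)
  partsA <- nStatistics(c(8, 5))
  partsB <- nStatistics(c(5, 3))
  expect_true(all(merged >= partsA) && all(merged >= partsB))

  expect_error(nStatistics(numeric(0)), "positive")
  expect_error(nStatistics(c(5, 0)), "positive")
})

test_that("N-statistics agree with a brute-force cumulative scan", {
  oracleN <- function(lengths, x) {
    s <- sort(lengths, decreasing = TRUE)
    tot <- sum(s)
    run <- 0
    for (l in s) { run <- run + l; if (run >= x / 100 * tot) return(l) }
  }
  set.seed(601)
  for (i in 1:20) {
    lens <- sample(500:20000, sample(3:15, 1))
    ns <- nStatistics(lens)
    for (x in seq(10, 100, 10))
      expect_equal(unname(ns[paste0("N", x)]), oracleN(lens, x))
    expect_equal(n50(lens), oracleN(lens, 50))
  }
})

test_that("truth alignment labels blocks by species", {
  gA <- randomSeq(12000, seed = 602)
  gB <- randomSeq(12000, seed = 603)
  truth <- Biostrings::DNAStringSet(c(spA = gA, spB = gB))
  clean <- Biostrings::DNAStringSet(c(s1 = substring(gA, 2001, 8000)))
  bl <- alignToTruth(clean, truth)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$species, "spA")
  expect_equal(bl$identity, 100)
  expect_equal(bl$s_start, 1L)
  expect_equal(bl$s_end, 6000L)
  expect_equal(bl$g_start, 2001L)

  chim <- Biostrings::DNAStringSet(c(
    x = paste0(substring(gA, 1, 5000), substring(gB, 1, 5000))))
  bl2 <- alignToTruth(chim, truth)
  expect_equal(sort(unique(bl2$species)), c("spA", "spB"))
  expect_equal(nrow(bl2), 2L)

  rnd <- Biostrings::DNAStringSet(c(z = randomSeq(5000, seed = 604)))
  expect_equal(nrow(alignToTruth(rnd, truth)), 0L)
})

test_that("chimera index covers the clean, chimeric and mixed fixtures", {
  lens <- c(clean = 10000, chim = 10000)
  blocksClean <- data.frame(scaffold = "clean", species = "spA",
                            s_start = 1, s_end = 10000,
                            g_start = 1, g_end = 10000,
                            orientation = "+", identity = 100)
  blocksChim <- data.frame(scaffold = c("chim", "chim"),
                           species = c("spA", "spB"),
                           s_start = c(1, 5001), s_end = c(5000, 10000),
                           g_start = c(1, 1), g_end = c(5000, 5000),
                           orientation = "+", identity = 100)
  expect_equal(chimeraIndex(blocksClean, lens["clean"]), 0)
  expect_equal(chimeraIndex(blocksChim, lens["chim"]), 1.0)
  both <- rbind(blocksClean, blocksChim)
  expect_equal(chimeraIndex(both, lens), 0.5)
  expect_true(is.na(suppressWarnings(
    chimeraIndex(blocksClean[0, ], lens))))
})

test_that("nonchimeric rate uses provenance truth on merged references", {
  g <- randomSeq(20000, seed = 605)
  R <- Biostrings::DNAStringSet(c(f1 = substring(g, 1, 11000)))
  Q <- Biostrings::DNAStringSet(c(f2 = substring(g, 9001, 20000)))
  m <- mergePair(R, Q, refSite = "s1", querySite = "s2")
  expect_equal(nonchimericRate(m, speciesOf = c(f1 = "spA", f2 = "spA")),
               100)
  # a forced cross-species join through an engineered shared overlap
  shared <- randomSeq(1500, seed = 606)
  a <- paste0(randomSeq(6000, seed = 607), shared)
  b <- paste0(shared, randomSeq(6000, seed = 608))
  chim <- mergePair(Biostrings::DNAStringSet(c(sa = a)),
                    Biostrings::DNAStringSet(c(sb = b)))
  expect_equal(length(scaffolds(chim)), 1L)
  rate <- nonchimericRate(chim, speciesOf = c(sa = "spA", sb = "spB"))
  expect_equal(rate, 0)
  expect_error(nonchimericRate(scaffolds(chim)), "labels")
})

test_that("the composite metric is monotone in accuracy and completeness", {
  gA <- randomSeq(10000, seed = 609)
  truth <- Biostrings::DNAStringSet(c(spA = gA))
  perfect <- Biostrings::DNAStringSet(c(s = gA))
  bl <- alignToTruth(perfect, truth)
  cm <- compositeMetric(bl, c(s = 10000))
  expect_equal(cm$ci, 0)
  expect_equal(cm$tal, 10000)
  expect_equal(cm$mal, 10000)
  expect_equal(cm$cpm, 10000)            # reduces to N50 when CI=0, TAL=total
  # fully chimeric: CI = 1 annihilates the score
  blChim <- data.frame(scaffold = "s", species = c("spA", "spB"),
                       s_start = c(1, 5001), s_end = c(5000, 10000),
                       g_start = c(1, 1), g_end = c(5000, 5000),
                       orientation = "+", identity = 100)
  expect_equal(compositeMetric(blChim, c(s = 10000))$cpm, 0)
})

test_that("evaluateAssembly assembles all metrics into one object", {
  com <- simulateGenomes(2L, c(20000L, 20000L), seed = 610L)
  frag <- fragmentPerSite(com, seed = 611L)
  m <- mergeSites(frag$scaffolds)
  speciesOf <- setNames(frag$truth$species, frag$truth$scaffold_id)
  ev <- evaluateAssembly(m, genomes(com), speciesOf = speciesOf)
  expect_s4_class(ev, "AssemblyEvaluation")
  expect_equal(ev@nonchimericRate, 100)
  expect_equal(ev@ci, 0)
  expect_equal(unname(ev@nstats["N50"]), 20000)
  expect_equal(ev@tal, 40000)
  expect_gt(ev@cpm, 0)
})

test_that("mapping rate separates native from foreign reads", {
  g <- randomSeq(8000, seed = 612)
  ref <- Biostrings::DNAStringSet(c(r = g))
  native <- data.table::rbindlist(lapply(1:20, function(i) {
    p <- 100 * i
    data.table::data.table(id = sprintf("n%d", i),
                           seq1 = substring(g, p, p + 99),
                           seq2 = rcSeq(substring(g, p + 200, p + 299)))
  }))
  expect_equal(mappingRate(ref, native), 100)
  foreign <- data.table::copy(native)
  h <- randomSeq(8000, seed = 613)
  foreign[, `:=`(seq1 = substring(h, .I * 100, .I * 100 + 99),
                 seq2 = rcSeq(substring(h, .I * 100 + 200,
                                        .I * 100 + 299)))]
  expect_equal(mappingRate(ref, foreign), 0)
})
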