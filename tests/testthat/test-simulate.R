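# Synthetic community generator: determinism, ORF validity, fragmentation
# overlaps, read budgets and error-free fidelity.

test_that("simulated genomes are deterministic with valid planted ORFs", {
  com1 <- simulateGenomes(1L, c(50000L, 50000L), gc = 0.5,
                          geneDensity = 1 / 5000, seed = 7L)
  com2 <- simulateGenomes(1L, c(50000L, 50000L), gc = 0.5,
                          geneDensity = 1 / 5000, seed = 7L)
  expect_identical(as.character(genomes(com1)), as.character(genomes(com2)))
  g <- geneModels(com1)
  expect_equal(length(g), 10L)            # floor(50 kb / 5 kb)
  seqs <- extractGeneSeqs(genomes(com1), g)
  expect_true(all(vapply(as.character(seqs), oracleValidOrf, TRUE)))
  # genes do not overlap
  expect_equal(length(IRanges::reduce(IRanges::ranges(g))), length(g))

  com3 <- simulateGenomes(1L, c(50000L, 50000L), seed = 8L)
  expect_false(identical(as.character(genomes(com1)),
                         as.character(genomes(com3))))
})

test_that("infeasible gene density is a parameter error", {
  expect_error(simulateGenomes(1L, c(10000L, 10000L), geneDensity = 1 / 200,
                               seed = 1L),
               "infeasible")
})

test_that("expression truth is deterministic and respects the design", {
  com <- simulateGenomes(2L, c(30000L, 30000L), seed = 3L)
  e1 <- assignExpression(com, nCovariantPairs = 4L, seed = 9L)
  e2 <- assignExpression(com, nCovariantPairs = 4L, seed = 9L)
  expect_identical(expressionTruth(e1), expressionTruth(e2))
  expect_true(all(expressionTruth(e1) >= 0))
  expect_true(all(abundanceTruth(e1) > 0))

  pairs <- covariantPairs(e1)
  expect_equal(nrow(pairs), 4L)
  m <- S4Vectors::mcols(geneModels(e1))
  # pair members share a reaction label in the hidden truth column
  tr <- setNames(m$true_reaction, m$gene_id)
  expect_true(all(tr[pairs$gene1] == pairs$reaction))
  expect_true(all(tr[pairs$gene2] == pairs$reaction))
  # unknown genes expose no labels (is_known <=> ko or cog present)
  expect_equal(!is.na(m$ko) | !is.na(m$cog), m$is_known)
  expect_true(all(m$reactions[!m$is_known] == ""))
  # roughly the requested fraction is unknown
  expect_equal(sum(!m$is_known), floor(0.3 * length(m$is_known)))
})

test_that("per-site fragmentation tiles genomes with overlaps >= mL", {
  com <- simulateGenomes(2L, c(30000L, 30000L), seed = 5L)
  expect_error(fragmentPerSite(com, minFrag = 500L), "parameter error")
  expect_error(fragmentPerSite(com, overlapRange = c(500L, 800L),
                               mL = 1000L), "parameter error")
  frag <- fragmentPerSite(com, seed = 11L)
  tr <- frag$truth
  mL <- 1000L
  for (sp in names(genomes(com))) {
    glen <- Biostrings::width(genomes(com)[sp])
    for (s in unique(tr$site)) {
      t_ <- tr[tr$site == s & tr$species == sp, ]
      t_ <- t_[order(t_$start), ]
      expect_equal(t_$start[1], 1L)
      expect_equal(t_$end[nrow(t_)], glen)
      if (nrow(t_) > 1)
        expect_true(all(t_$start[-1] == t_$end[-nrow(t_)] + 1L))
      expect_true(all(t_$end - t_$start + 1L >= 1000L))
    }
    # cross-site breakpoints are at least mL apart
    cuts <- lapply(unique(tr$site), function(s) {
      t_ <- tr[tr$site == s & tr$species == sp, ]
      setdiff(t_$end, max(t_$end))
    })
    for (i in seq_along(cuts)) for (j in seq_along(cuts)) {
      if (i >= j || !length(cuts[[i]]) || !length(cuts[[j]])) next
      d <- abs(outer(cuts[[i]], cuts[[j]], "-"))
      expect_true(all(d >= mL))
    }
  }
  # fragment sequences match the genome intervals they claim
  s1 <- frag$scaffolds[[1]]
  t1 <- frag$truth[frag$truth$site == names(frag$scaffolds)[1], ]
  i <- which.max(t1$end - t1$start)
  expect_equal(
    as.character(s1[[t1$scaffold_id[i]]]),
    substring(as.character(genomes(com)[[t1$species[i]]]),
              t1$start[i], t1$end[i]))
})

test_that("read simulation meets its budgets and is error-free at rate 0", {
  com <- simulateGenomes(1L, c(20000L, 20000L), seed = 2L)
  com <- assignExpression(com, nCovariantPairs = 2L, seed = 2L)
  reads <- simulateReads(com, dnaDepth = 1, rnaDepth = 0.5, readLen = 100L,
                         errorRate = 0, seed = 4L)
  reads2 <- simulateReads(com, dnaDepth = 1, rnaDepth = 0.5,
                          readLen = 100L, errorRate = 0, seed = 4L)
  expect_identical(reads$dna$seq1, reads2$dna$seq1)
  expect_identical(reads$rna$seq2, reads2$rna$seq2)

  gseq <- as.character(genomes(com))[[1]]
  some <- head(reads$dna, 50)
  expect_true(all(vapply(seq_len(nrow(some)), function(i) {
    grepl(some$seq1[i], gseq, fixed = TRUE) &&
      grepl(rcSeq(some$seq2[i]), gseq, fixed = TRUE)
  }, TRUE)))

  # DNA budget: rounded depth formula per species and sample
  ab <- abundanceTruth(com)
  sn <- colnames(ab)[1]
  expected <- round(1 * ab["sp01", sn] * 20000 / (2 * 100))
  expect_equal(sum(reads$dna$sample == sn), expected)

  # RNA budget: per gene, proportional to abundance x expression x length
  expr <- expressionTruth(com)
  g <- geneModels(com)
  gid <- S4Vectors::mcols(g)$gene_id[1]
  glen <- IRanges::width(g)[1]
  expectedRna <- round(0.5 * ab["sp01", sn] * expr[gid, sn] * glen /
                         (2 * 100))
  expect_equal(sum(reads$rna$sample == sn & reads$rna$gene_id == gid),
               expectedRna)

  # RNA reads stay within their gene body
  rr <- reads$rna[reads$rna$gene_id == gid]
  if (nrow(rr)) {
    expect_true(all(rr$pos >= IRanges::start(g)[1]))
    expect_true(all(rr$pos + rr$frag - 1L <= IRanges::end(g)[1]))
  }

  # substitution errors appear at the requested rate
  noisy <- simulateReads(com, dnaDepth = 1, rnaDepth = 0.5,
                         readLen = 100L, errorRate = 0.02, seed = 4L)
  mm <- sum(vapply(seq_len(min(200, nrow(noisy$dna))), function(i) {
    sum(charToRaw(noisy$dna$seq1[i]) != charToRaw(reads$dna$seq1[i]))
  }, 0))
  rate <- mm / (200 * 100)
  expect_gt(rate, 0.01); expect_lt(rate, 0.035)
})

test_that("designed covariant profile pairs separate when effect is large", {
  sim <- simulateClusterProfiles(30L, 30L, effectSize = 2, noiseSd = 0.02,
                                 seed = 21L)
  W <- gutWeights()
  Lm <- leeLMatrix(sim$profiles, W)
  idx <- cbind(match(sim$pairs$id1, rownames(sim$profiles)),
               match(sim$pairs$id2, rownames(sim$profiles)))
  Lpair <- Lm[idx]
  off <- Lm[upper.tri(Lm)]
  expect_gt(median(Lpair), quantile(off, 0.75))
  sim2 <- simulateClusterProfiles(30L, 30L, effectSize = 2,
                                  noiseSd = 0.02, seed = 21L)
  expect_identical(sim$profiles, sim2$profiles)
})
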