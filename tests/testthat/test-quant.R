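# Mapping, counting, TPM, DNA depth, per-cell normalisation and the
# differential-expression rule.

mkRef <- function(seq, nm = "ref") {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- nm
  x
}

pairAt <- function(g, pos, frag = 400L, rl = 100L, id = "p1") {
  data.table::data.table(
    id = id,
    seq1 = substring(g, pos, pos + rl - 1L),
    seq2 = rcSeq(substring(g, pos + frag - rl, pos + frag - 1L)))
}

test_that("mapper places unique reads at truth and rejects repeats", {
  g <- randomSeq(5000, seed = 401)
  ref <- mkRef(g)
  p <- pairAt(g, 1001L)
  aln <- mapReads(ref, p)
  expect_equal(nrow(aln), 2L)
  expect_true(all(aln$mapped))
  expect_equal(aln[aln$mate1 == TRUE]$pos, 1001L)
  expect_equal(aln[aln$mate1 == FALSE]$pos, 1001L + 400L - 100L)
  expect_true(all(aln$properly_paired))
  expect_equal(aln[aln$mate1 == TRUE]$tlen, 400L)

  # an exact two-copy repeat leaves the read unmapped (ambiguous)
  unit <- randomSeq(600, seed = 402)
  rep2 <- mkRef(paste0(randomSeq(500, seed = 403), unit,
                       randomSeq(500, seed = 404), unit,
                       randomSeq(500, seed = 405)))
  rp <- data.table::data.table(id = "r", seq1 = substring(unit, 50, 149),
                               seq2 = rcSeq(substring(unit, 350, 449)))
  aln2 <- mapReads(rep2, rp)
  expect_false(any(aln2$mapped))
})

test_that("mapping with mismatches matches a sliding-window Hamming oracle", {
  g <- randomSeq(4000, seed = 406)
  ref <- mkRef(g)
  read <- substring(g, 2001, 2150)
  ch <- strsplit(read, "")[[1]]
  for (p in c(10, 70, 140)) ch[p] <- setdiff(c("A", "C", "G", "T"),
                                             ch[p])[1]
  mut <- paste(ch, collapse = "")
  p <- data.table::data.table(id = "m", seq1 = mut,
                              seq2 = rcSeq(substring(g, 2251, 2400)))
  aln <- mapReads(ref, p, maxMismatchRate = 0.05)
  m1 <- aln[aln$mate1 == TRUE]
  expect_true(m1$mapped)
  # oracle: exhaustive Hamming scan over all placements
  mm <- vapply(seq_len(nchar(g) - 150 + 1), function(s) {
    sum(charToRaw(mut) != charToRaw(substring(g, s, s + 149)))
  }, 0L)
  expect_equal(m1$pos, which.min(mm))
  expect_equal(m1$pos, 2001L)
})

test_that("union-mode counting follows the rules and the overlap oracle", {
  g <- randomSeq(6000, seed = 407)
  ref <- mkRef(g)
  feats <- GenomicRanges::GRanges("ref",
                                  IRanges::IRanges(c(1001, 3001),
                                                   c(2000, 4000)))
  S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
    gene_id = c("gA", "gB"))
  # pair fully inside gene A
  inA <- pairAt(g, 1201L, id = "inA")
  # mate1 in A, mate2 in B -> ambiguous
  split_ <- data.table::data.table(
    id = "split", seq1 = substring(g, 1500, 1599),
    seq2 = rcSeq(substring(g, 3100, 3199)))
  # pair outside both genes
  out <- pairAt(g, 4501L, id = "none")
  aln <- mapReads(ref, rbind(inA, split_, out))
  cnt <- countReads(aln, feats,
                    scaffoldLengths = c(ref = nchar(g)))
  expect_equal(unname(cnt["gA"]), 1L)
  expect_equal(unname(cnt["gB"]), 0L)
  expect_equal(attr(cnt, "ambiguous"), 1L)
  expect_equal(attr(cnt, "no_feature"), 1L)

  expect_error(countReads(data.table::data.table(
    qname = "x", mapped = TRUE, target_id = "zzz", pos = 1L, len = 50L),
    feats, scaffoldLengths = c(ref = nchar(g))), "unknown scaffold")
})

test_that("counting equals the brute-force oracle on random fixtures", {
  set.seed(408)
  for (rep_ in 1:20) {
    nG <- sample(2:4, 1)
    starts <- sort(sample(seq(1, 8000, by = 700), nG))
    genes <- data.frame(gene_id = sprintf("g%d", seq_len(nG)), chr = "c",
                        start = starts, end = starts + 599L)
    feats <- GenomicRanges::GRanges("c", IRanges::IRanges(genes$start,
                                                          genes$end))
    S4Vectors::mcols(feats) <- S4Vectors::DataFrame(gene_id = genes$gene_id)
    nR <- 30L
    pos <- sample(8500, nR)
    aln <- data.table::data.table(
      qname = rep(sprintf("r%02d", seq_len(nR)), 2),
      mapped = TRUE, target_id = "c",
      pos = c(pos, pos + 250L), len = 100L,
      strand = rep(c("+", "-"), each = nR),
      mate1 = rep(c(TRUE, FALSE), each = nR),
      properly_paired = TRUE)
    cnt <- countReads(aln, feats)
    mateIv <- data.frame(qname = aln$qname, chr = "c", start = aln$pos,
                         end = aln$pos + aln$len - 1L)
    expect_equal(as.integer(cnt),
                 as.integer(oracleCountPairs(mateIv, genes)))
  }
})

test_that("TPM follows its closed form and conserves 1e6", {
  expect_equal(unname(computeTpm(c(5), c(2))), 1e6)
  tpm <- computeTpm(c(10, 10), c(1, 2))
  expect_equal(tpm, c(1e6 * 2 / 3, 1e6 / 3), tolerance = 1e-12)
  expect_equal(sum(tpm), 1e6)
  # permutation equivariance
  expect_equal(computeTpm(c(10, 10)[2:1], c(1, 2)[2:1]), tpm[2:1])
  z <- computeTpm(c(0, 0), c(1, 1))
  expect_equal(as.numeric(z), c(0, 0))
  expect_equal(attr(z, "flagged"), "all-zero sample")
  expect_error(computeTpm(c(-1), c(1)), "negative")
})

test_that("DNA depth is aligned bases over gene length and is linear", {
  feats <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 2000))
  S4Vectors::mcols(feats) <- S4Vectors::DataFrame(gene_id = "g")
  # ten 100 nt reads (5 pairs, both mates) fully inside a 1000 bp gene
  a <- data.table::data.table(
    qname = rep(sprintf("d%d", 1:5), 2), mapped = TRUE, target_id = "c",
    pos = seq(1001, by = 100, length.out = 10), len = 100L,
    mate1 = rep(c(TRUE, FALSE), 5), properly_paired = TRUE)
  d <- computeDepth(a, feats)
  expect_equal(unname(d), 1.0)
  # doubling the read set doubles depth exactly
  a2 <- rbind(a, data.table::copy(a)[, qname := paste0(qname, "x")])
  expect_equal(unname(computeDepth(a2, feats)), 2.0)
  # no reads -> zero
  expect_equal(unname(computeDepth(a[0], feats)), 0)
  # improperly paired alignments are excluded
  a3 <- data.table::copy(a)[, properly_paired := FALSE]
  expect_equal(unname(computeDepth(a3, feats)), 0)
})

test_that("per-cell normalisation cancels abundance and masks zero depth", {
  expect_equal(computePerCell(100, 1, 10), 10)
  expect_true(is.na(computePerCell(5, 1, 0)))
  expect_equal(computePerCell(5, 1, 0, pseudodepth = 1), 5)
  # 10x abundance scales counts and depth together; per-cell is unchanged
  c1 <- c(gA = 100, gB = 40); d1 <- c(gA = 5, gB = 5)
  l <- c(gA = 1, gB = 2)
  pc1 <- computePerCell(c1, l, d1)
  pc10 <- computePerCell(10 * c1, l, 10 * d1)
  expect_equal(pc1, pc10)
})

test_that("the 2-fold same-direction rule flags differential KOs", {
  samples <- data.frame(individual = rep(c("i1", "i2"), each = 2),
                        site = rep(c("cecum", "feces"), 2))
  # a tiny positive entry keeps the adaptive pseudocount negligible
  koMat <- rbind(
    sig = c(2^1.5 * 100, 100, 2^1.2 * 100, 100),     # +1.5, +1.2
    clash = c(2^1.5 * 100, 100, 100, 2^1.2 * 100),   # +1.5, -1.2
    weak = c(2^0.9 * 100, 100, 2^2 * 100, 100),      # +0.9, +2.0
    tiny = c(0.002, 0.002, 0.002, 0.002))
  colnames(koMat) <- paste(samples$individual, samples$site, sep = ".")
  res <- flagDifferential(koMat, samples, c("cecum", "feces"))
  sig <- setNames(res$significant, res$ko)
  expect_true(sig[["sig"]])
  expect_false(sig[["clash"]])
  expect_false(sig[["weak"]])
  expect_equal(res$ko[1], "weak")   # ranked by max |lfc|
})

test_that("KO aggregation sums member genes", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    ko = c("K1", "K1", NA))
  agg <- aggregateByKo(m, ann)
  expect_equal(dim(agg), c(1L, 2L))
  expect_equal(unname(agg["K1", ]), c(3, 9))
})
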