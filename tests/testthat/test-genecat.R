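# Gene catalogue: ORF calling against an independent scan oracle,
# cross-assembly identity matching, protein clustering, COG grouping.

test_that("a planted ORF is called at its exact coordinates", {
  orf <- simpleOrf(100L)                 # 300 nt
  p <- plantOrf(orf)
  ref <- Biostrings::DNAStringSet(p$seq)
  names(ref) <- "s1"
  f <- callOrfs(ref, minLen = 300L)
  expect_equal(length(f), 1L)
  expect_equal(IRanges::start(f), p$start)
  expect_equal(IRanges::end(f), p$end)
  expect_equal(as.character(GenomicRanges::strand(f)), "+")
  expect_equal(S4Vectors::mcols(f)$frame, (p$start - 1L) %% 3L)

  # reverse-complemented construct: same gene on the minus strand
  refRc <- Biostrings::DNAStringSet(rcSeq(p$seq))
  names(refRc) <- "s1"
  fr <- callOrfs(refRc, minLen = 300L)
  expect_equal(length(fr), 1L)
  expect_equal(as.character(GenomicRanges::strand(fr)), "-")
  L <- nchar(p$seq)
  expect_equal(IRanges::start(fr), L - p$end + 1L)
  expect_equal(IRanges::end(fr), L - p$start + 1L)
  # extracted sequence reads ATG..stop again
  expect_equal(as.character(extractGeneSeqs(refRc, fr)[[1]]), orf)
})

test_that("called ORFs agree with a brute-force scan on random sequence", {
  s <- randomSeq(10000, seed = 301)
  ref <- Biostrings::DNAStringSet(s)
  names(ref) <- "r"
  f <- callOrfs(ref, minLen = 300L)
  seqs <- extractGeneSeqs(ref, f)
  expect_true(all(vapply(as.character(seqs), oracleValidOrf, TRUE)))
  oracle <- oracleOrfScan(s, 300L)
  # every called ORF is in the oracle set
  if (length(f)) {
    key <- paste(IRanges::start(f), IRanges::end(f),
                 GenomicRanges::strand(f))
    okey <- paste(oracle$start, oracle$end, oracle$strand)
    expect_true(all(key %in% okey))
  }
  # every oracle ORF is either called or yields to a longer same-strand one
  for (i in seq_len(nrow(oracle))) {
    o <- oracle[i, ]
    same <- f[as.character(GenomicRanges::strand(f)) == o$strand]
    covered <- any(IRanges::start(same) == o$start &
                     IRanges::end(same) == o$end)
    if (!covered) {
      ov <- same[IRanges::start(same) <= o$end &
                   IRanges::end(same) >= o$start]
      expect_true(all(IRanges::width(ov) >= (o$end - o$start + 1L)))
      expect_gt(length(ov), 0L)
    }
  }
})

test_that("translation handles strand and ambiguity", {
  orf <- paste0("ATG", "AAA", "NNN", "TGA")
  aa <- translateGenes(Biostrings::DNAStringSet(c(g = orf)))
  expect_equal(as.character(aa[[1]]), "MKX")
})

test_that("gene identity matching counts common genes at <= 3 edits", {
  gene <- simpleOrf(120L)
  near <- function(x, nmut) {
    ch <- strsplit(x, "")[[1]]
    for (p in seq(10, by = 17, length.out = nmut))
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  sites <- list(
    s1 = Biostrings::DNAStringSet(c(a = gene)),
    s2 = Biostrings::DNAStringSet(c(b = gene)),
    s3 = Biostrings::DNAStringSet(c(c = gene)))
  mergedSame <- Biostrings::DNAStringSet(c(m = gene))
  r1 <- matchGenesAcross(sites, mergedSame)
  expect_equal(r1$n_common, 1L)
  expect_equal(r1$n_matched, 1L)
  expect_equal(r1$percent_matched, 100)

  # a merged copy with 4 substitutions is common but unmatched
  merged4 <- Biostrings::DNAStringSet(c(m = near(gene, 4L)))
  r2 <- matchGenesAcross(sites, merged4)
  expect_equal(r2$n_common, 1L)
  expect_equal(r2$n_matched, 0L)

  # 3 substitutions stay within the edit budget
  merged3 <- Biostrings::DNAStringSet(c(m = near(gene, 3L)))
  r3 <- matchGenesAcross(sites, merged3)
  expect_equal(r3$n_matched, 1L)

  # empty: no common genes is flagged undefined
  sitesOdd <- list(
    s1 = Biostrings::DNAStringSet(c(a = gene)),
    s2 = Biostrings::DNAStringSet(c(b = simpleOrf(150L))),
    s3 = Biostrings::DNAStringSet(c(c = simpleOrf(180L))))
  r4 <- matchGenesAcross(sitesOdd, mergedSame)
  expect_equal(r4$n_common, 0L)
  expect_true(r4$undefined)
})

test_that("site order does not change the gene match report", {
  set.seed(42)
  genes <- vapply(1:6, function(i) simpleOrf(100L + 7L * i), "")
  mkset <- function(nm) {
    x <- Biostrings::DNAStringSet(setNames(genes, paste0(nm, 1:6)))
    x
  }
  sites <- list(A = mkset("a"), B = mkset("b"), C = mkset("c"))
  merged <- Biostrings::DNAStringSet(setNames(genes[1:5], paste0("m", 1:5)))
  r1 <- matchGenesAcross(sites, merged)
  r2 <- matchGenesAcross(rev(sites), merged)
  expect_equal(r1$n_common, 6L)
  expect_equal(r1$n_matched, 5L)
  expect_equal(r2$n_common, r1$n_common)
  expect_equal(r2$n_matched, r1$n_matched)
})

test_that("greedy centroid clustering partitions proteins correctly", {
  p1 <- paste(rep("MKLVDEQRST", 20), collapse = "")
  aa <- Biostrings::AAStringSet(c(x = p1, y = p1))
  cl <- clusterUnknownProteins(aa)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 2L)

  set.seed(7)
  rnd <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                           "")[[1]], n, replace = TRUE),
                           collapse = "")
  aa2 <- Biostrings::AAStringSet(c(x = rnd(120), y = rnd(130)))
  cl2 <- clusterUnknownProteins(aa2)
  expect_equal(length(unique(cl2$cluster_id)), 2L)

  # two families of 5 at ~95 percent identity, unrelated across families
  mutate <- function(x, n) {
    ch <- strsplit(x, "")[[1]]
    at <- sample(length(ch), n)
    for (p in at) ch[p] <- sample(setdiff(strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch[p]), 1)
    paste(ch, collapse = "")
  }
  f1 <- rnd(200); f2 <- rnd(200)
  fam <- c(vapply(1:5, function(i) mutate(f1, 8L), ""),
           vapply(1:5, function(i) mutate(f2, 8L), ""))
  names(fam) <- sprintf("p%02d", 1:10)
  cl3 <- clusterUnknownProteins(Biostrings::AAStringSet(fam))
  expect_equal(length(unique(cl3$cluster_id)), 2L)
  # oracle: all-vs-all identity separates the families
  members <- split(cl3$gene_id, cl3$cluster_id)
  fams <- list(sprintf("p%02d", 1:5), sprintf("p%02d", 6:10))
  expect_true(all(vapply(members, function(m)
    all(m %in% fams[[1]]) || all(m %in% fams[[2]]), TRUE)))
  # the partition property: every protein in exactly one cluster
  expect_equal(sort(cl3$gene_id), sprintf("p%02d", 1:10))
})

test_that("COG grouping honours multi-membership and exclusions", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    cog = c("COG1", "COG1", "COG1", NA, "COG1;COG2"),
                    stringsAsFactors = FALSE)
  cl <- groupKnownByCog(ann)
  expect_equal(sum(cl$cluster_id == "COG1"), 4L)
  expect_equal(sum(cl$cluster_id == "COG2"), 1L)
  expect_false("g4" %in% cl$gene_id)
  expect_true(all(cl$multi[cl$gene_id == "g5"]))
})
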