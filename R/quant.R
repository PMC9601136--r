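# Read mapping and expression quantification.  The mapper is a gapless
# k-mer seed-and-verify stand-in for a production aligner: external SAM is
# accepted interchangeably wherever alignments are consumed.  Counting is
# HTSeq-style union mode; whole-community expression is TPM; per-cell
# expression divides the mRNA rate by the DNA coverage of the same gene.

#' Build a k-mer index of a reference
#'
#' @param reference DNAStringSet or \linkS4class{MergedReference}.
#' @param k seeding k-mer length.
#' @return a keyed data.table (kmer, id, pos) plus reference metadata in
#'   attributes; pass to \code{\link{mapReads}} to amortise index cost.
#' @export
buildKmerIndex <- function(reference, k = 31L) {
  if (is(reference, "MergedReference")) reference <- scaffolds(reference)
  seqs <- setNames(as.character(reference), names(reference))
  if (!length(seqs)) stop("reference is empty")
  idx <- dropAmbiguousKmers(kmerTable(seqs, k))
  setkey(idx, kmer)
  attr(idx, "k") <- k
  attr(idx, "refseqs") <- seqs
  idx
}

# map one batch of single-end sequences; returns best unique hits
mapMates <- function(seqs, idx, maxMismatchRate) {
  k <- attr(idx, "k")
  refseqs <- attr(idx, "refseqs")
  reflen <- setNames(nchar(refseqs), names(refseqs))
  n <- length(seqs)
  lens <- nchar(seqs)
  res <- data.table(read_idx = seq_len(n), target_id = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    mm = NA_integer_, n_hits = 0L)
  seedCand <- list()
  for (orient in c("+", "-")) {
    s <- if (orient == "+") seqs else revComp(seqs)
    nSeed <- 5L
    offs <- vapply(seq_len(nSeed), function(j)
      as.integer(pmax(1, 1 + floor((j - 1) * (lens - k) / (nSeed - 1)))),
      integer(n))
    if (n == 1L) offs <- matrix(offs, nrow = 1L)
    seeds <- data.table(
      read_idx = rep(seq_len(n), nSeed),
      offset = as.integer(offs),
      kmer = substring(rep(s, nSeed), as.integer(offs),
                       as.integer(offs) + k - 1L))
    seeds <- seeds[nchar(kmer) == k]
    hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hits)) next
    hits[, `:=`(start_ = pos - offset + 1L, strand = orient)]
    cand <- unique(hits[, .(read_idx, target_id = id, pos = start_, strand)])
    seedCand[[orient]] <- cand
  }
  cand <- rbindlist(seedCand)
  if (!nrow(cand)) return(res)
  cand[, len := lens[read_idx]]
  cand <- cand[pos >= 1L & pos + len - 1L <= reflen[target_id]]
  if (!nrow(cand)) return(res)
  readStr <- ifelse(cand$strand == "+", seqs[cand$read_idx],
                    revComp(seqs[cand$read_idx]))
  refStr <- substring(refseqs[cand$target_id], cand$pos,
                      cand$pos + cand$len - 1L)
  cand[, mm := stringMismatches(readStr, refStr)]
  cand <- cand[mm <= floor(maxMismatchRate * len)]
  if (!nrow(cand)) return(res)
  setorder(cand, read_idx, mm, target_id, pos, strand)
  bestMm <- cand[, .(best = mm[1], n_best = sum(mm == mm[1])),
                 by = read_idx]
  top <- cand[!duplicated(read_idx)]
  top <- merge(top, bestMm, by = "read_idx")
  uniqueBest <- top[top$n_best == 1L]
  res[uniqueBest$read_idx,
      `:=`(target_id = uniqueBest$target_id, pos = uniqueBest$pos,
           strand = uniqueBest$strand, mm = uniqueBest$mm, n_hits = 1L)]
  res[top$read_idx[top$n_best > 1L], n_hits := 2L]   # ambiguous best
  res
}

#' Map paired-end reads to a reference (gapless stand-in mapper)
#'
#' Candidate loci come from k-mer seeds at five read offsets in both
#' orientations, verified by gapless mismatch counting.  A mate is mapped
#' when a single locus attains the minimum mismatch count within the
#' per-base budget; an ambiguous best (for example an exact repeat) leaves
#' the mate unmapped, deterministically.  Mates mapped to the same scaffold
#' on opposite strands with a fragment of at most \code{maxFragmentLen} bp
#' are flagged properly paired.
#'
#' @param reference DNAStringSet or \linkS4class{MergedReference}; ignored
#'   when \code{index} is supplied.
#' @param pairs data.table with columns id, seq1, seq2 (from
#'   \code{\link{pairMates}} or \code{\link{simulateReads}}).
#' @param k seed length.
#' @param maxMismatchRate maximum mismatches as a fraction of read length.
#' @param maxFragmentLen properly-paired fragment cap in bp.
#' @param index optional prebuilt \code{\link{buildKmerIndex}}.
#' @return data.table with one row per mate: qname, mate1, mapped,
#'   target_id, pos (1-based), strand, cigar, mapq, properly_paired, tlen,
#'   len.
#' @export
mapReads <- function(reference, pairs, k = 31L, maxMismatchRate = 0.05,
                     maxFragmentLen = 2000L, index = NULL) {
  if (is.null(index)) index <- buildKmerIndex(reference, k)
  m1 <- mapMates(pairs$seq1, index, maxMismatchRate)
  m2 <- mapMates(pairs$seq2, index, maxMismatchRate)
  n <- nrow(pairs)
  mk <- function(m, mate1, seqs) data.table(
    qname = pairs$id, mate1 = mate1,
    mapped = !is.na(m$pos), target_id = m$target_id, pos = m$pos,
    strand = m$strand, len = nchar(seqs),
    cigar = sprintf("%dM", nchar(seqs)),
    mapq = fifelse(!is.na(m$pos), 60L, 0L))
  a1 <- mk(m1, TRUE, pairs$seq1)
  a2 <- mk(m2, FALSE, pairs$seq2)
  proper <- a1$mapped & a2$mapped &
    a1$target_id == a2$target_id & a1$strand != a2$strand
  lo <- pmin(a1$pos, a2$pos)
  hi <- pmax(a1$pos + a1$len, a2$pos + a2$len) - 1L
  frag <- hi - lo + 1L
  proper <- proper & !is.na(frag) & frag <= maxFragmentLen
  proper[is.na(proper)] <- FALSE
  a1[, properly_paired := proper]
  a2[, properly_paired := proper]
  sign1 <- fifelse(!is.na(a1$pos) & a1$pos <= fifelse(is.na(a2$pos),
                                                      a1$pos, a2$pos),
                   1L, -1L)
  a1[, tlen := fifelse(properly_paired, sign1 * frag, 0L)]
  a2[, tlen := fifelse(properly_paired, -sign1 * frag, 0L)]
  out <- rbind(a1, a2)
  out[mapped == FALSE, `:=`(target_id = NA_character_, pos = NA_integer_,
                            strand = NA_character_, mapq = 0L)]
  setorder(out, qname, -mate1)
  out
}

#' Count read pairs per gene (union mode)
#'
#' A pair is assigned to gene g exactly when the union of genes overlapped
#' by either mapped mate equals {g}; pairs overlapping no gene count as
#' no_feature, pairs overlapping two or more distinct genes count as
#' ambiguous; each pair is counted once, strand-agnostically.
#'
#' @param alignments data.table from \code{\link{mapReads}} or
#'   \code{\link{readSamRecords}}.
#' @param features GRanges with mcols gene_id.
#' @param scaffoldLengths named lengths of the reference scaffolds (used to
#'   reject alignments to unknown scaffolds).
#' @return named integer vector of counts per gene_id, with attributes
#'   no_feature and ambiguous.
#' @export
countReads <- function(alignments, features, scaffoldLengths = NULL) {
  a <- as.data.table(alignments)[mapped == TRUE]
  gid <- mcols(features)$gene_id
  counts <- setNames(integer(length(gid)), gid)
  if (!is.null(scaffoldLengths)) {
    unk <- setdiff(unique(a$target_id), names(scaffoldLengths))
    if (length(unk))
      stop("alignment to unknown scaffold: ", unk[1])
  }
  if (!nrow(a)) {
    attr(counts, "no_feature") <- 0L
    attr(counts, "ambiguous") <- 0L
    return(counts)
  }
  gr <- GRanges(a$target_id, IRanges(a$pos, a$pos + a$len - 1L))
  sl <- unique(c(as.character(seqnames(features)), a$target_id))
  GenomeInfoDb::seqlevels(gr) <- sl
  feat <- features
  GenomeInfoDb::seqlevels(feat) <- sl
  ov <- findOverlaps(gr, feat, ignore.strand = TRUE)
  hitdt <- data.table(qname = a$qname[S4Vectors::queryHits(ov)],
                      gene = gid[S4Vectors::subjectHits(ov)])
  hitdt <- unique(hitdt)
  perPair <- hitdt[, .(ng = length(unique(gene)), gene = gene[1]),
                   by = qname]
  assigned <- perPair[ng == 1L]
  tab <- table(assigned$gene)
  counts[names(tab)] <- as.integer(tab)
  allPairs <- unique(a$qname)
  attr(counts, "no_feature") <-
    length(setdiff(allPairs, perPair$qname))
  attr(counts, "ambiguous") <- sum(perPair$ng > 1L)
  counts
}

#' Transcripts per million
#'
#' rate_g = c_g / l_g (l_g in kb); tpm_g = 1e6 * rate_g / sum(rate).  An
#' all-zero sample returns all-zero TPM with attribute \code{flagged}.
#'
#' @param counts numeric vector of read counts per gene.
#' @param lengthsKb gene lengths in kilobases (> 0).
#' @return numeric vector of TPM values summing to 1e6 (or all zero).
#' @export
computeTpm <- function(counts, lengthsKb) {
  if (any(counts < 0)) stop("negative count")
  if (any(lengthsKb <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengthsKb
  tot <- sum(rate)
  if (tot == 0) {
    out <- rate
    attr(out, "flagged") <- "all-zero sample"
    return(out)
  }
  1e6 * rate / tot
}

#' Mean per-base DNA depth over gene intervals
#'
#' d_g = (sum of aligned bases overlapping the gene interval) / gene length
#' in bp; both mates of properly paired alignments contribute.
#'
#' @param dnaAlignments data.table from \code{\link{mapReads}} (only
#'   properly paired records are used).
#' @param features GRanges with mcols gene_id.
#' @return named numeric vector of mean depths per gene_id.
#' @export
computeDepth <- function(dnaAlignments, features) {
  a <- as.data.table(dnaAlignments)[mapped == TRUE & properly_paired == TRUE]
  gid <- mcols(features)$gene_id
  depth <- setNames(numeric(length(gid)), gid)
  if (!nrow(a)) return(depth)
  gr <- GRanges(a$target_id, IRanges(a$pos, a$pos + a$len - 1L))
  sl <- unique(c(as.character(seqnames(features)), a$target_id))
  GenomeInfoDb::seqlevels(gr) <- sl
  feat <- features
  GenomeInfoDb::seqlevels(feat) <- sl
  ov <- findOverlaps(gr, feat, ignore.strand = TRUE)
  inter <- pintersect(gr[S4Vectors::queryHits(ov)],
                      feat[S4Vectors::subjectHits(ov)])
  dt <- data.table(gene = gid[S4Vectors::subjectHits(ov)],
                   bases = width(inter))
  agg <- dt[, .(bases = sum(bases)), by = gene]
  depth[agg$gene] <- agg$bases / width(features)[match(agg$gene, gid)]
  depth
}

#' Per-cell expression: mRNA rate normalised by DNA coverage
#'
#' per_cell_g = (c_g / l_g in kb) / (d_g + pseudodepth).  Genes whose
#' denominator is zero are masked (NA), not zero: without DNA coverage the
#' per-bacterium rate is undefined.  Because both the mRNA count and the
#' DNA depth scale with species abundance, the ratio cancels abundance and
#' estimates expression per single bacterium.
#'
#' @param counts mRNA counts per gene.
#' @param lengthsKb gene lengths in kb.
#' @param depth DNA mean depth per gene (\code{\link{computeDepth}}).
#' @param pseudodepth optional stabiliser added to the denominator.
#' @return numeric vector, NA where undefined.
#' @export
computePerCell <- function(counts, lengthsKb, depth, pseudodepth = 0) {
  denom <- depth + pseudodepth
  out <- (counts / lengthsKb) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Assemble an expression SummarizedExperiment
#'
#' @param countsMat,tpmMat,perCellMat,depthMat gene x sample matrices.
#' @param features GRanges with mcols gene_id (row order must match).
#' @param samples data.frame with columns individual, site (column order
#'   must match).
#' @return SummarizedExperiment with assays counts, tpm, per_cell, depth;
#'   rowData carries the features, colData the sample grid.
#' @export
buildExpressionSE <- function(countsMat, tpmMat, perCellMat, depthMat,
                              features, samples) {
  stopifnot(nrow(countsMat) == length(features),
            nrow(samples) == ncol(countsMat))
  se <- SummarizedExperiment(
    assays = list(counts = countsMat, tpm = tpmMat, per_cell = perCellMat,
                  depth = depthMat),
    rowRanges = features,
    colData = DataFrame(samples))
  rownames(se) <- mcols(features)$gene_id
  se
}

#' Aggregate a gene x sample layer to KO x sample
#'
#' KO value = sum of member-gene values (genes without a KO label are
#' dropped; NA member values propagate as NA).
#'
#' @param mat gene x sample matrix with gene_id rownames.
#' @param annotations data.frame with columns gene_id, ko.
#' @return KO x sample matrix.
#' @export
aggregateByKo <- function(mat, annotations) {
  ko <- annotations$ko[match(rownames(mat), annotations$gene_id)]
  keep <- !is.na(ko) & nzchar(ko)
  if (!any(keep)) return(matrix(numeric(), 0, ncol(mat),
                                dimnames = list(NULL, colnames(mat))))
  rowsum(mat[keep, , drop = FALSE], group = ko[keep])
}

#' Flag differentially expressed KOs between two sites
#'
#' For each KO the log2 difference between the two sites is computed per
#' individual with a scale-adaptive pseudocount (half the smallest positive
#' value of the layer); a KO is significant when the difference exceeds
#' 2-fold in the same direction in every individual.
#'
#' @param koMat KO x sample matrix.
#' @param samples data.frame (individual, site) matching the columns.
#' @param sitePair character vector of two site names.
#' @return data.table with ko, one log2 difference column per individual,
#'   max_abs_lfc, significant; sorted by max_abs_lfc descending.
#' @export
flagDifferential <- function(koMat, samples, sitePair) {
  stopifnot(length(sitePair) == 2L)
  inds <- unique(samples$individual)
  haveBoth <- vapply(inds, function(ind)
    all(sitePair %in% samples$site[samples$individual == ind]), TRUE)
  if (sum(haveBoth) < 2L)
    stop("need >= 2 individuals sharing the site pair")
  if (any(!haveBoth))
    warning("individual(s) missing a site, skipped: ",
            paste(inds[!haveBoth], collapse = ", "))
  inds <- inds[haveBoth]
  pos <- koMat[koMat > 0]
  eps <- if (length(pos)) min(pos) / 2 else 0.5
  lfc <- sapply(inds, function(ind) {
    c1 <- which(samples$individual == ind & samples$site == sitePair[1])
    c2 <- which(samples$individual == ind & samples$site == sitePair[2])
    log2((koMat[, c1] + eps) / (koMat[, c2] + eps))
  })
  if (is.null(dim(lfc))) lfc <- matrix(lfc, nrow = 1,
                                       dimnames = list(rownames(koMat),
                                                       inds))
  sig <- apply(lfc, 1L, function(v)
    all(abs(v) > 1) && (all(v > 0) || all(v < 0)))
  out <- data.table(ko = rownames(koMat))
  for (ind in inds)
    data.table::set(out, j = paste0("lfc_", ind), value = lfc[, ind])
  out[, `:=`(max_abs_lfc = apply(abs(lfc), 1L, max), significant = sig)]
  setorder(out, -max_abs_lfc)
  out
}
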