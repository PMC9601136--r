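# Gene catalogue construction: ORF-based gene calling (a stand-in for a
# statistical gene finder; external GFF3 models are accepted everywhere a
# feature set is consumed), cross-assembly gene-identity matching at a
# small edit-distance budget, and greedy centroid clustering of unknown
# proteins.

#' Call open reading frames on a reference
#'
#' Finds all maximal ORFs (ATG to the next in-frame stop, both strands, all
#' three frames) of at least \code{minLen} nt, then resolves same-strand
#' overlaps longest-first.  The reported interval includes the stop codon,
#' so widths are multiples of 3.
#'
#' @param reference DNAStringSet or \linkS4class{MergedReference}.
#' @param minLen minimum ORF length in nt (start through stop codon).
#' @return GRanges with mcols gene_id and frame.
#' @export
callOrfs <- function(reference, minLen = 300L) {
  if (is(reference, "MergedReference")) reference <- scaffolds(reference)
  stopifnot(length(reference) >= 1L)
  seqs <- setNames(as.character(reference), names(reference))
  rows <- list()
  for (nm in names(seqs)) {
    L <- nchar(seqs[[nm]])
    for (std in c("+", "-")) {
      s <- if (std == "+") seqs[[nm]] else revComp(seqs[[nm]])
      for (f in 0:2) {
        nCod <- (L - f) %/% 3L
        if (nCod < minLen %/% 3L) next
        cs <- f + 1L + 3L * (seq_len(nCod) - 1L)
        cod <- substring(s, cs, cs + 2L)
        stops <- which(cod %in% STOP_CODONS)
        atgs <- which(cod == "ATG")
        if (!length(stops) || !length(atgs)) next
        nextStop <- findInterval(atgs - 1L, stops) + 1L
        ok <- nextStop <= length(stops)
        atgs <- atgs[ok]; nextStop <- nextStop[ok]
        if (!length(atgs)) next
        first <- tapply(atgs, nextStop, min)
        stopIdx <- as.integer(names(first))
        aCod <- as.integer(first)
        sCod <- stops[stopIdx]
        lenNt <- 3L * (sCod - aCod + 1L)
        keep <- lenNt >= minLen
        if (!any(keep)) next
        aCod <- aCod[keep]; sCod <- sCod[keep]
        st <- f + 3L * (aCod - 1L) + 1L
        en <- f + 3L * sCod
        if (std == "-") {
          tmp <- st
          st <- L - en + 1L
          en <- L - tmp + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = nm, start = st, end = en, strand = std, frame = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(GRanges(character(), IRanges(integer(), integer()),
                   gene_id = character(), frame = integer()))
  df <- do.call(rbind, rows)
  # same-strand overlap resolution, longest-first
  df <- df[order(-(df$end - df$start), df$scaffold, df$start), ]
  keepRow <- rep(TRUE, nrow(df))
  for (key in unique(paste(df$scaffold, df$strand))) {
    idx <- which(paste(df$scaffold, df$strand) == key)
    ir <- IRanges(df$start[idx], df$end[idx])
    taken <- IRanges()
    for (j in seq_along(idx)) {
      if (length(taken) && length(IRanges::findOverlaps(ir[j], taken)))
        keepRow[idx[j]] <- FALSE
      else taken <- c(taken, ir[j])
    }
  }
  df <- df[keepRow, ]
  df <- df[order(df$scaffold, df$start, df$end), ]
  gr <- GRanges(df$scaffold, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr) <- DataFrame(
    gene_id = sprintf("%s|%d-%d|%s", df$scaffold, df$start, df$end,
                      df$strand),
    frame = as.integer(df$frame))
  gr
}

#' Extract gene nucleotide sequences
#'
#' Minus-strand features are reverse complemented so every returned
#' sequence reads ATG..stop.
#'
#' @param reference DNAStringSet or \linkS4class{MergedReference}.
#' @param features GRanges with mcols gene_id.
#' @return DNAStringSet named by gene_id.
#' @export
extractGeneSeqs <- function(reference, features) {
  if (is(reference, "MergedReference")) reference <- scaffolds(reference)
  seqs <- setNames(as.character(reference), names(reference))
  s <- substring(seqs[as.character(seqnames(features))],
                 start(features), end(features))
  neg <- as.character(strand(features)) == "-"
  s[neg] <- revComp(s[neg])
  out <- DNAStringSet(s)
  names(out) <- mcols(features)$gene_id
  out
}

#' Translate gene sequences to proteins
#'
#' The trailing stop is removed; ambiguous codons (containing N) translate
#' to X.
#'
#' @param geneSeqs DNAStringSet of ATG..stop sequences.
#' @return AAStringSet named like the input.
#' @export
translateGenes <- function(geneSeqs) {
  aa <- suppressWarnings(translate(geneSeqs, if.fuzzy.codon = "solve"))
  ch <- as.character(aa)
  ch <- sub("\\*$", "", ch)
  out <- AAStringSet(ch)
  names(out) <- names(geneSeqs)
  out
}

# greedy bipartite matching between two sequence sets at <= maxEdit edits;
# candidates are globally sorted by (distance, idA, idB) so the result does
# not depend on input order.  Returns data.table(a, b, dist).
matchSeqSets <- function(a, b, maxEdit = 3L) {
  aC <- setNames(as.character(a), names(a))
  bC <- setNames(as.character(b), names(b))
  cand <- list()
  # exact phase
  hit <- match(aC, bC)
  exact <- which(!is.na(hit))
  if (length(exact))
    cand[[1]] <- data.table(a = names(aC)[exact],
                            b = names(bC)[hit[exact]], dist = 0L)
  # banded edit phase for the rest (length difference bound prunes pairs)
  restA <- setdiff(names(aC), if (length(exact)) names(aC)[exact] else NULL)
  usedB <- if (length(exact)) names(bC)[hit[exact]] else character(0)
  restB <- setdiff(names(bC), usedB)
  if (length(restA) && length(restB)) {
    la <- nchar(aC[restA]); lb <- nchar(bC[restB])
    pairs <- data.table(expand.grid(a = restA, b = restB,
                                    stringsAsFactors = FALSE))
    pairs <- pairs[abs(la[a] - lb[b]) <= maxEdit]
    if (nrow(pairs)) {
      d <- mapply(function(x, y) utils::adist(x, y), aC[pairs$a],
                  bC[pairs$b])
      pairs[, dist := as.integer(d)]
      pairs <- pairs[dist <= maxEdit]
      if (nrow(pairs)) cand[[length(cand) + 1L]] <- pairs
    }
  }
  if (!length(cand))
    return(data.table(a = character(), b = character(), dist = integer()))
  cc <- rbindlist(cand)
  setorder(cc, dist, a, b)
  usedA <- character(0); usedB2 <- character(0)
  keep <- logical(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    if (cc$a[i] %in% usedA || cc$b[i] %in% usedB2) next
    keep[i] <- TRUE
    usedA <- c(usedA, cc$a[i]); usedB2 <- c(usedB2, cc$b[i])
  }
  cc[keep]
}

#' Gene-identity retention across site assemblies and the merged reference
#'
#' A gene is "common to all sites" when greedy best-match at most
#' \code{maxEdit} edits links counterparts of it in every site's gene set
#' (matching over a globally sorted candidate list, each gene used once per
#' site pair); a common gene "matches the merged" when any of its
#' counterparts has a counterpart at most \code{maxEdit} edits away in the
#' merged catalogue.  Edit distance is Levenshtein (substitutions and
#' indels), with distances above \code{maxEdit} treated as infinite.
#'
#' @param siteGeneSeqs named list (site -> DNAStringSet of gene sequences).
#' @param mergedGeneSeqs DNAStringSet of merged-catalogue gene sequences.
#' @param maxEdit edit-distance budget (default 3).
#' @return list with n_common, n_matched, percent_matched (NA and flagged
#'   \code{undefined = TRUE} when no common genes exist).
#' @export
matchGenesAcross <- function(siteGeneSeqs, mergedGeneSeqs, maxEdit = 3L) {
  stopifnot(length(siteGeneSeqs) >= 2L)
  sites <- sort(names(siteGeneSeqs))
  tag <- function(s, ids) paste(s, ids, sep = "::")
  # cross-site greedy matchings -> connected components
  edges <- list()
  for (i in seq_along(sites)) for (j in seq_along(sites)) {
    if (i >= j) next
    m <- matchSeqSets(siteGeneSeqs[[sites[i]]], siteGeneSeqs[[sites[j]]],
                      maxEdit)
    if (nrow(m))
      edges[[length(edges) + 1L]] <- data.table(
        from = tag(sites[i], m$a), to = tag(sites[j], m$b))
  }
  nodes <- unlist(lapply(sites, function(s)
    tag(s, names(siteGeneSeqs[[s]]))))
  comp <- seq_along(nodes)
  if (length(edges)) {
    ed <- rbindlist(edges)
    # simple union-find over integer indices
    parent <- seq_along(nodes)
    rootOf <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(ed))) {
      a <- rootOf(match(ed$from[r], nodes))
      b <- rootOf(match(ed$to[r], nodes))
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_along(nodes), rootOf, 0L)
  }
  siteOf <- sub("::.*", "", nodes)
  groups <- split(seq_along(nodes), comp)
  common <- Filter(function(ix) all(sites %in% siteOf[ix]), groups)
  nCommon <- length(common)
  if (nCommon == 0L)
    return(list(n_common = 0L, n_matched = 0L, percent_matched = NA_real_,
                undefined = TRUE))
  # match the union of common-gene sequences against the merged catalogue
  allSeq <- unlist(lapply(sites, function(s)
    setNames(as.character(siteGeneSeqs[[s]]),
             tag(s, names(siteGeneSeqs[[s]])))))
  mergedC <- setNames(as.character(mergedGeneSeqs), names(mergedGeneSeqs))
  nMatched <- 0L
  for (ix in common) {
    ids <- nodes[ix]
    m <- matchSeqSets(allSeq[ids], mergedC, maxEdit)
    if (nrow(m)) nMatched <- nMatched + 1L
  }
  list(n_common = nCommon, n_matched = nMatched,
       percent_matched = 100 * nMatched / nCommon, undefined = FALSE)
}

proteinKmers <- function(x, k = 5L) {
  n <- nchar(x)
  if (n < k) return(x)
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Cluster unknown proteins by greedy centroid clustering
#'
#' Proteins are sorted by length (longest first); each joins the first
#' existing centroid with identity at least \code{minIdentity} over at
#' least \code{minCoverage} of the shorter sequence (shared 5-mer
#' prefilter, then local alignment), otherwise it founds a new cluster.
#' Deterministic; the result is a partition.
#'
#' @param proteins named AAStringSet.
#' @param minIdentity minimum fractional identity over the aligned region.
#' @param minCoverage minimum aligned fraction of the shorter sequence.
#' @return data.frame with columns cluster_id, gene_id, centroid, kind
#'   ("unknown").
#' @export
clusterUnknownProteins <- function(proteins, minIdentity = 0.9,
                                   minCoverage = 0.85) {
  if (!length(proteins))
    return(data.frame(cluster_id = character(), gene_id = character(),
                      centroid = character(), kind = character()))
  pc <- setNames(as.character(proteins), names(proteins))
  ord <- order(-nchar(pc), names(pc))
  pc <- pc[ord]
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- data_env$BLOSUM62
  centroids <- character(0)
  assign_ <- character(length(pc))
  kmerSets <- list()
  for (i in seq_along(pc)) {
    p <- pc[[i]]
    pk <- proteinKmers(p)
    placed <- FALSE
    for (cen in centroids) {
      if (!length(intersect(pk, kmerSets[[cen]]))) next
      aln <- pairwiseAlignment(pc[[cen]], p, type = "local",
                               substitutionMatrix = B62, gapOpening = 10,
                               gapExtension = 1)
      ps <- Biostrings::pattern(aln)
      ss <- Biostrings::subject(aln)
      spanP <- IRanges::end(ps) - IRanges::start(ps) + 1L
      spanS <- IRanges::end(ss) - IRanges::start(ss) + 1L
      alnLen <- nchar(as.character(Biostrings::pattern(aln)))
      ident <- nmatch(aln) / max(1L, alnLen)
      coverage <- if (nchar(p) <= nchar(pc[[cen]]))
        spanS / nchar(p) else spanP / nchar(pc[[cen]])
      if (ident >= minIdentity && coverage >= minCoverage) {
        assign_[i] <- cen
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cen <- names(pc)[i]
      centroids <- c(centroids, cen)
      kmerSets[[cen]] <- pk
      assign_[i] <- cen
    }
  }
  data.frame(
    cluster_id = sprintf("UC_%s", assign_),
    gene_id = names(pc), centroid = assign_,
    kind = "unknown", stringsAsFactors = FALSE)
}

#' Group known genes into clusters by COG label
#'
#' One cluster per COG label; a gene carrying several ";"-separated COG
#' labels joins each of them (flagged multi-membership).  Genes without a
#' COG label are excluded.
#'
#' @param annotations data.frame with columns gene_id, cog.
#' @return data.frame with columns cluster_id, gene_id, kind ("known"),
#'   multi (logical flag).
#' @export
groupKnownByCog <- function(annotations) {
  a <- annotations[!is.na(annotations$cog) & nzchar(annotations$cog), ,
                   drop = FALSE]
  if (!nrow(a))
    return(data.frame(cluster_id = character(), gene_id = character(),
                      kind = character(), multi = logical()))
  labs <- strsplit(a$cog, ";", fixed = TRUE)
  df <- data.frame(cluster_id = unlist(labs),
                   gene_id = rep(a$gene_id, lengths(labs)),
                   kind = "known",
                   multi = rep(lengths(labs) > 1L, lengths(labs)),
                   stringsAsFactors = FALSE)
  df[order(df$cluster_id, df$gene_id), ]
}
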