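# Synthetic multi-site community generator.  Produces genomes with planted
# ORFs, per-(individual, site) abundance and expression truth with designed
# covariant gene pairs, per-site genome fragmentations with cross-site
# overlaps, and paired-end DNA / mRNA reads -- everything a pure function of
# (parameters, seed), with complete truth tables.

STOP_CODONS <- c("TAA", "TAG", "TGA")

allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Simulate bacterial genomes with planted ORFs
#'
#' Each genome is an i.i.d. nucleotide sequence at the requested GC content
#' into which non-overlapping protein-coding genes are planted: each gene is
#' a valid ORF (ATG start, no internal in-frame stop, one of TAA/TAG/TGA at
#' the end, length a multiple of 3 between 300 and 3000 nt).  Every gene
#' initially carries unique KO and COG labels; a fraction is later relabeled
#' unknown by \code{\link{assignExpression}}.
#'
#' @param nSpecies number of genomes.
#' @param lengthRange integer range (min, max) of genome lengths in bp; at
#'   least 10 kb.
#' @param gc GC content of the intergenic background.
#' @param geneDensity genes per bp (for example 1/4000).
#' @param seed RNG seed.
#' @return a \linkS4class{SyntheticCommunity} skeleton (no expression yet).
#' @export
simulateGenomes <- function(nSpecies = 6L, lengthRange = c(30000L, 30000L),
                            gc = 0.5, geneDensity = 1 / 4000, seed = 0L) {
  stopifnot(nSpecies >= 1L)
  if (min(lengthRange) < 10000L)
    stop("parameter error: genome lengths must be >= 10 kb")
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    codons <- allCodons()
    sense <- setdiff(codons, STOP_CODONS)
    minGap <- 50L
    genomeSeqs <- character(nSpecies)
    species <- sprintf("sp%02d", seq_len(nSpecies))
    geneRows <- list()
    geneCounter <- 0L
    for (si in seq_len(nSpecies)) {
      glen <- if (lengthRange[1] == lengthRange[2]) lengthRange[1] else
        sample(seq.int(lengthRange[1], lengthRange[2]), 1L)
      chars <- sample(bases, glen, replace = TRUE, prob = probs)
      nGenes <- floor(glen * geneDensity)
      codLens <- sample(100:500, nGenes, replace = TRUE)   # 300..1500 nt
      ntLens <- 3L * codLens
      if (sum(ntLens) + (nGenes + 1L) * minGap > glen)
        stop("parameter error: gene_density infeasible for genome length")
      spare <- glen - sum(ntLens) - (nGenes + 1L) * minGap
      w <- runif(nGenes + 1L)
      extra <- floor(spare * w / sum(w))
      gaps <- minGap + extra
      starts <- integer(nGenes)
      cursor <- 0L
      for (i in seq_len(nGenes)) {
        cursor <- cursor + gaps[i]
        starts[i] <- cursor + 1L
        cursor <- cursor + ntLens[i]
      }
      strands <- sample(c("+", "-"), nGenes, replace = TRUE)
      for (i in seq_len(nGenes)) {
        nInt <- codLens[i] - 2L
        orf <- paste0("ATG",
                      paste(sample(sense, nInt, replace = TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1L))
        if (strands[i] == "-") orf <- revComp(orf)
        idx <- seq.int(starts[i], length.out = ntLens[i])
        chars[idx] <- strsplit(orf, "")[[1]]
        geneCounter <- geneCounter + 1L
        geneRows[[geneCounter]] <- data.frame(
          species = species[si], start = starts[i],
          end = starts[i] + ntLens[i] - 1L, strand = strands[i],
          gene_id = sprintf("%s_g%03d", species[si], i),
          stringsAsFactors = FALSE)
      }
      genomeSeqs[si] <- paste(chars, collapse = "")
    }
    gdf <- do.call(rbind, geneRows)
    genomeSet <- DNAStringSet(genomeSeqs)
    names(genomeSet) <- species
    genes <- GRanges(gdf$species,
                     IRanges(gdf$start, gdf$end),
                     strand = gdf$strand,
                     seqlengths = setNames(width(genomeSet), species))
    n <- length(genes)
    mcols(genes) <- DataFrame(
      gene_id = gdf$gene_id, frame = rep(0L, n),
      ko = sprintf("K%05d", seq_len(n)),
      cog = sprintf("COG%04d", seq_len(n)),
      reactions = rep("", n), is_known = rep(TRUE, n),
      true_reaction = rep("", n))
    new("SyntheticCommunity", genomes = genomeSet, genes = genes,
        samples = data.frame(individual = character(),
                             site = character()),
        abundance = matrix(numeric(), 0, 0),
        expression = matrix(numeric(), 0, 0),
        covariantPairs = data.frame(gene1 = character(),
                                    gene2 = character(),
                                    reaction = character(),
                                    both_known = logical()),
        params = list(seed = seed, nSpecies = nSpecies, gc = gc,
                      geneDensity = geneDensity))
  })
}


# Latent spatial profiles for covariant units.  Each unit is a direction in
# the spatially smooth subspace of the sample grid: a per-individual linear
# gradient over the ordered sites (energy share 1 - offsetShare) plus a
# between-individual offset contrast (energy share offsetShare), scaled by
# a lognormal amplitude around effectSize.  The energy split is fixed
# across units so that Lee's L of a shared profile does not depend on the
# unit's particular direction; pair members share the unit exactly.
latentUnitProfiles <- function(nUnits, effectSize, individuals, siteOrder,
                               offsetShare = 0.3, ampSd = 0.3) {
  nS <- length(siteOrder)
  nI <- length(individuals)
  n <- nS * nI
  z <- if (nS > 1) seq(-1, 1, length.out = nS) else 0
  siteIdx <- rep(seq_len(nS), nI)
  indIdx <- rep(seq_len(nI), each = nS)
  s <- if (nI > 1) offsetShare else 0
  out <- matrix(0, nUnits, n)
  if (effectSize == 0) return(out)
  for (p in seq_len(nUnits)) {
    g <- rnorm(nI)
    lin <- g[indIdx] * z[siteIdx]
    nl <- sqrt(sum(lin^2))
    lin <- if (nl > 0) lin / nl else lin
    off <- rep(0, n)
    if (nI > 1) {
      v <- rnorm(nI)
      v <- v - mean(v)
      nv <- sqrt(sum(v[indIdx]^2))
      if (nv > 0) off <- v[indIdx] / nv
    }
    amp <- effectSize * exp(rnorm(1, 0, ampSd))
    out[p, ] <- amp * (sqrt(1 - s) * lin + sqrt(s) * off)
  }
  out
}

#' Assign abundance and expression truth with designed covariant pairs
#'
#' Samples are the ordered (individual, site) pairs.  Species abundance
#' follows a species-specific smooth gradient over the site chain on a
#' lognormal individual baseline.  Every gene receives a latent site
#' profile: a smooth site gradient with an individual-level offset (a
#' random direction in the spatially smooth subspace of the sample grid,
#' scaled by \code{effectSize}).  The two members of a designed covariant
#' pair share one latent profile (so their spatial shapes agree, including
#' the individual-level variation, while per-gene magnitudes differ) and
#' one reaction label; all other genes draw independent profiles.
#' Expression is \code{exp(base + latent + N(0, noiseSd))}.  A fraction of
#' genes is stripped of KO/COG labels to act as "unknown" genes; their
#' reaction truth moves to a hidden column used only for scoring.
#'
#' @param community a \linkS4class{SyntheticCommunity}.
#' @param nCovariantPairs number of designed covariant gene pairs.
#' @param effectSize scale of the latent spatial gradients (0 = null).
#' @param noiseSd standard deviation of the per-observation log-normal
#'   noise.
#' @param unknownFraction fraction of genes relabeled unknown.
#' @param individuals individual ids.
#' @param siteOrder ordered site chain shared by all individuals.
#' @param offsetShare fixed fraction of a latent profile's energy carried
#'   by the between-individual offset contrast (the rest is a
#'   per-individual linear site gradient).
#' @param ampSd lognormal spread of the per-profile amplitude.
#' @param abundanceGradient scale of the species abundance site gradient.
#' @param seed RNG seed.
#' @return the community with abundance, expression, covariantPairs and
#'   sample grid filled in.
#' @export
assignExpression <- function(community, nCovariantPairs = 10L,
                             effectSize = 1, noiseSd = 0.1,
                             unknownFraction = 0.3,
                             individuals = c("ind1", "ind2"),
                             siteOrder = c("cecum", "transverse_colon",
                                           "feces"),
                             offsetShare = 0.3, ampSd = 0.3,
                             abundanceGradient = 1,
                             seed = 0L) {
  genes <- community@genes
  nGenes <- length(genes)
  if (2L * nCovariantPairs > nGenes)
    stop("parameter error: not enough genes for ", nCovariantPairs,
         " covariant pairs")
  withSeed(seed, {
    samples <- do.call(rbind, lapply(individuals, function(ind)
      data.frame(individual = ind, site = siteOrder,
                 stringsAsFactors = FALSE)))
    sampleNames <- paste(samples$individual, samples$site, sep = ".")
    nS <- length(siteOrder)
    z <- if (nS > 1) seq(-1, 1, length.out = nS) else 0
    z2 <- z^2 - mean(z^2)
    siteIdx <- match(samples$site, siteOrder)
    indIdx <- match(samples$individual, individuals)

    species <- names(community@genomes)
    ab <- matrix(0, length(species), nrow(samples),
                 dimnames = list(species, sampleNames))
    for (sp in seq_along(species)) {
      baseInd <- rlnorm(length(individuals), 0, 0.5)
      slope <- runif(1, -1, 1) * abundanceGradient
      ab[sp, ] <- baseInd[indIdx] * exp(slope * z[siteIdx])
    }

    ids <- mcols(genes)$gene_id
    pairGenes <- sample(seq_len(nGenes), 2L * nCovariantPairs)
    g1 <- pairGenes[seq_len(nCovariantPairs)]
    g2 <- pairGenes[nCovariantPairs + seq_len(nCovariantPairs)]
    profileOf <- seq_len(nGenes)            # profile unit per gene
    profileOf[g2] <- g1                     # pair members share a profile
    units <- unique(profileOf)
    lat <- latentUnitProfiles(length(units), effectSize, individuals,
                              siteOrder, offsetShare = offsetShare,
                              ampSd = ampSd)
    rownames(lat) <- as.character(units)
    base <- rnorm(nGenes, 3, 1)
    expr <- matrix(0, nGenes, nrow(samples),
                   dimnames = list(ids, sampleNames))
    for (g in seq_len(nGenes)) {
      latent <- lat[as.character(profileOf[g]), ]
      expr[g, ] <- exp(base[g] + latent + rnorm(nrow(samples), 0, noiseSd))
    }

    reactions <- sprintf("R%05d", seq_len(nCovariantPairs))
    m <- mcols(genes)
    m$true_reaction[g1] <- reactions
    m$true_reaction[g2] <- reactions
    m$reactions[g1] <- reactions
    m$reactions[g2] <- reactions
    nUnknown <- floor(unknownFraction * nGenes)
    unk <- sample(seq_len(nGenes), nUnknown)
    m$ko[unk] <- NA_character_
    m$cog[unk] <- NA_character_
    m$is_known[unk] <- FALSE
    m$reactions[unk] <- ""                  # hidden from the pipeline
    mcols(genes) <- m

    pairs <- data.frame(gene1 = ids[g1], gene2 = ids[g2],
                        reaction = reactions,
                        both_known = m$is_known[g1] & m$is_known[g2],
                        stringsAsFactors = FALSE)
    out <- community
    out@genes <- genes
    out@samples <- samples
    out@abundance <- ab
    out@expression <- expr
    out@covariantPairs <- pairs
    out@params <- c(community@params,
                    list(nCovariantPairs = nCovariantPairs,
                         effectSize = effectSize, noiseSd = noiseSd,
                         unknownFraction = unknownFraction,
                         exprSeed = seed))
    validObject(out)
    out
  })
}

#' Fragment genomes into per-site scaffold sets with designed overlaps
#'
#' Each site receives a complete tiling of every genome, cut at
#' site-specific breakpoints staggered by an offset drawn from
#' \code{overlapRange}; fragments from any two sites therefore overlap by at
#' least the smaller stagger, which must be at least \code{mL} so that the
#' merge stage can reconstruct the genome.  A genome tail shorter than
#' \code{minFrag} is absorbed into the final fragment, so no fragment falls
#' below the 1000 bp floor.
#'
#' @param community a \linkS4class{SyntheticCommunity}.
#' @param minFrag minimum fragment length in bp (must be >= 1000, the contig
#'   floor).
#' @param overlapRange integer range for the per-genome site stagger in bp;
#'   the lower bound must be >= \code{mL}.
#' @param baseFragLen nominal per-site fragment length in bp.
#' @param mL the merge length cutoff the overlaps must satisfy.
#' @param sites site names (one scaffold set per site).
#' @param seed RNG seed.
#' @return list with \code{scaffolds} (named list of DNAStringSet per site)
#'   and \code{truth} (data.frame site, scaffold_id, species, start, end).
#' @export
fragmentPerSite <- function(community, minFrag = 1000L,
                            overlapRange = c(2000L, 3000L),
                            baseFragLen = 9000L, mL = 1000L,
                            sites = c("cecum", "transverse_colon", "feces"),
                            seed = 0L) {
  if (minFrag < 1000L)
    stop("parameter error: minFrag must be >= 1000 (contig floor)")
  if (overlapRange[1] < mL)
    stop("parameter error: overlapRange lower bound ", overlapRange[1],
         " is below the merge length cutoff mL = ", mL)
  nSites <- length(sites)
  if (baseFragLen <= (nSites - 1L) * overlapRange[2] + mL)
    stop("parameter error: baseFragLen too small for the requested stagger")
  withSeed(seed, {
    truth <- list()
    sets <- setNames(vector("list", nSites), sites)
    for (s in sites) sets[[s]] <- list()
    for (sp in names(community@genomes)) {
      glen <- width(community@genomes[sp])
      gseq <- as.character(community@genomes[[sp]])
      delta <- sample(seq.int(overlapRange[1], overlapRange[2]), 1L)
      for (si in seq_len(nSites)) {
        off <- (si - 1L) * delta
        cps <- off + baseFragLen * seq.int(0L, ceiling(glen / baseFragLen))
        cps <- cps[cps > 0L & cps < glen]
        if (length(cps) && glen - cps[length(cps)] < minFrag)
          cps <- cps[-length(cps)]
        bounds <- c(0L, cps, glen)
        st <- bounds[-length(bounds)] + 1L
        en <- bounds[-1]
        keep <- (en - st + 1L) >= minFrag
        st <- st[keep]; en <- en[keep]
        ids <- sprintf("%s_%s_f%02d", sp, sites[si], seq_along(st))
        frag <- substring(gseq, st, en)
        sets[[sites[si]]][[sp]] <- setNames(frag, ids)
        truth[[length(truth) + 1L]] <- data.frame(
          site = sites[si], scaffold_id = ids, species = sp,
          start = st, end = en, stringsAsFactors = FALSE)
      }
    }
    scaffolds <- lapply(sets, function(l) {
      v <- unlist(l, use.names = TRUE)
      names(v) <- sub("^[^.]*\\.", "", names(v))  # drop list-name prefix
      x <- DNAStringSet(v)
      x
    })
    tdf <- do.call(rbind, truth)
    scaffolds <- lapply(names(scaffolds), function(s) {
      x <- scaffolds[[s]]
      t_ <- tdf[tdf$site == s, ]
      d <- sprintf("species=%s site=%s start=%d end=%d",
                   t_$species[match(names(x), t_$scaffold_id)], s,
                   t_$start[match(names(x), t_$scaffold_id)],
                   t_$end[match(names(x), t_$scaffold_id)])
      mcols(x) <- DataFrame(description = d)
      x
    })
    names(scaffolds) <- sites
    list(scaffolds = scaffolds, truth = tdf)
  })
}

injectErrors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  bases <- c("A", "C", "G", "T")
  nerr <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0L)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    at <- sample.int(length(ch), nerr[i])
    for (p in at) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

drawPairs <- function(seqChar, region, n, readLen, fragMean, fragSd) {
  # region = c(start, end) within seqChar; returns data.table of mate seqs
  rl <- region[2] - region[1] + 1L
  frag <- pmin(rl, pmax(readLen,
                        round(rnorm(n, fragMean, fragSd))))
  maxStart <- region[2] - frag + 1L
  st <- region[1] + floor(runif(n) * (maxStart - region[1] + 1L))
  s1 <- substring(seqChar, st, st + readLen - 1L)
  s2 <- revComp(substring(seqChar, st + frag - readLen, st + frag - 1L))
  data.table(pos = as.integer(st), frag = as.integer(frag),
             seq1 = s1, seq2 = s2)
}

#' Simulate paired-end DNA and mRNA reads with truth tables
#'
#' DNA pairs are drawn uniformly within each genome at a rate proportional
#' to species abundance; mRNA pairs are drawn within annotated gene bodies
#' at a rate proportional to abundance times expression.  Substitution
#' errors are i.i.d. at \code{errorRate}; qualities are constant 'I' (Q40).
#' The number of pairs emitted per species (DNA) and per gene (RNA) equals
#' the rounded depth budget exactly.
#'
#' @param community a community with expression assigned.
#' @param dnaDepth expected DNA fold-coverage of a species at abundance 1.
#' @param rnaDepth mRNA fold-coverage of a gene body per unit of
#'   abundance x expression (pairs scale with gene length, as for a
#'   fragmented transcript library).
#' @param readLen read length in nt.
#' @param fragmentMean,fragmentSd insert size distribution in bp.
#' @param errorRate per-base substitution error rate.
#' @param seed RNG seed.
#' @return list with data.tables \code{dna} and \code{rna} (columns: sample,
#'   id, seq1, qual1, seq2, qual2 and truth columns species, pos, frag and,
#'   for RNA, gene_id).
#' @export
simulateReads <- function(community, dnaDepth = 2, rnaDepth = 0.2,
                          readLen = 150L, fragmentMean = 400L,
                          fragmentSd = 40L, errorRate = 0, seed = 0L) {
  if (dnaDepth <= 0 || rnaDepth <= 0) stop("parameter error: depths > 0")
  if (!nrow(community@samples))
    stop("assignExpression must run before simulateReads")
  withSeed(seed, {
    samples <- community@samples
    sampleNames <- paste(samples$individual, samples$site, sep = ".")
    ab <- community@abundance
    expr <- community@expression
    genes <- community@genes
    gid <- mcols(genes)$gene_id
    gSpecies <- as.character(seqnames(genes))
    genomeChar <- setNames(as.character(community@genomes),
                           names(community@genomes))
    qual <- strrep("I", readLen)
    dnaOut <- list(); rnaOut <- list()
    for (k in seq_len(nrow(samples))) {
      sn <- sampleNames[k]
      for (sp in names(genomeChar)) {
        glen <- nchar(genomeChar[[sp]])
        n <- round(dnaDepth * ab[sp, sn] * glen / (2 * readLen))
        if (n < 1) next
        p <- drawPairs(genomeChar[[sp]], c(1L, glen), n, readLen,
                       fragmentMean, fragmentSd)
        p[, `:=`(sample = sn, species = sp,
                 id = sprintf("dna.%s.%s.%05d", sn, sp, seq_len(n)))]
        dnaOut[[length(dnaOut) + 1L]] <- p
      }
      for (g in seq_along(genes)) {
        sp <- gSpecies[g]
        glen_g <- end(genes)[g] - start(genes)[g] + 1L
        n <- round(rnaDepth * ab[sp, sn] * expr[gid[g], sn] *
                     glen_g / (2 * readLen))
        if (n < 1) next
        p <- drawPairs(genomeChar[[sp]],
                       c(start(genes)[g], end(genes)[g]), n, readLen,
                       fragmentMean, fragmentSd)
        p[, `:=`(sample = sn, species = sp, gene_id = gid[g],
                 id = sprintf("rna.%s.%s.%05d", sn, gid[g], seq_len(n)))]
        rnaOut[[length(rnaOut) + 1L]] <- p
      }
    }
    finish <- function(lst) {
      if (!length(lst)) return(data.table())
      dt <- rbindlist(lst, fill = TRUE)
      dt[, seq1 := injectErrors(seq1, errorRate)]
      dt[, seq2 := injectErrors(seq2, errorRate)]
      dt[, `:=`(qual1 = qual, qual2 = qual)]
      dt
    }
    list(dna = finish(dnaOut), rna = finish(rnaOut))
  })
}

#' Simulate cluster expression profiles with designed covariant pairs
#'
#' A lightweight profile-level generator for calibration and power studies
#' of the covariation analysis: the same latent site-gradient model as
#' \code{\link{assignExpression}}, without genomes or reads.  Each designed
#' pair shares one latent profile (up to individual-level noise); every
#' other profile is independent.
#'
#' @param nPairs number of designed covariant profile pairs.
#' @param nIndependent number of additional independent profiles.
#' @param effectSize scale of the latent spatial gradients (0 = null).
#' @param noiseSd per-observation log-scale noise.
#' @param offsetShare,ampSd latent-profile shape parameters (see
#'   \code{\link{assignExpression}}).
#' @param individuals,siteOrder the sample grid.
#' @param log2p1 return log2(1 + expression) profiles (the scale the L
#'   statistic is applied to).
#' @param seed RNG seed.
#' @return list with \code{profiles} (matrix (2 nPairs + nIndependent) x
#'   samples), \code{pairs} (data.frame id1, id2) and \code{samples}.
#' @export
simulateClusterProfiles <- function(nPairs, nIndependent = nPairs,
                                    effectSize = 1, noiseSd = 0.1,
                                    offsetShare = 0.3, ampSd = 0.3,
                                    individuals = c("ind1", "ind2"),
                                    siteOrder = c("cecum",
                                                  "transverse_colon",
                                                  "feces"),
                                    log2p1 = TRUE, seed = 0L) {
  withSeed(seed, {
    samples <- do.call(rbind, lapply(individuals, function(ind)
      data.frame(individual = ind, site = siteOrder,
                 stringsAsFactors = FALSE)))
    nProf <- 2L * nPairs + nIndependent
    ids <- sprintf("cl%04d", seq_len(nProf))
    unitOf <- c(rep(seq_len(nPairs), 2L),
                nPairs + seq_len(nIndependent))
    nUnits <- nPairs + nIndependent
    lat <- latentUnitProfiles(nUnits, effectSize, individuals, siteOrder,
                              offsetShare = offsetShare, ampSd = ampSd)
    base <- rnorm(nProf, 3, 1)
    prof <- matrix(0, nProf, nrow(samples),
                   dimnames = list(ids, paste(samples$individual,
                                              samples$site, sep = ".")))
    for (i in seq_len(nProf)) {
      prof[i, ] <- exp(base[i] + lat[unitOf[i], ] +
                         rnorm(nrow(samples), 0, noiseSd))
    }
    if (log2p1) prof <- log2(1 + prof)
    list(profiles = prof,
         pairs = data.frame(id1 = ids[seq_len(nPairs)],
                            id2 = ids[nPairs + seq_len(nPairs)],
                            stringsAsFactors = FALSE),
         samples = samples)
  })
}
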