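# Reconstruction of the common reference metagenome by merging per-site
# scaffold sets.  Overlaps are found by shared-k-mer seeding on diagonals
# with gapless verification; merging is greedy over the sorted candidate
# list with each scaffold end used at most once (union-find forbids
# cycles), reference bases winning inside accepted overlaps, and contained
# scaffolds dropped.  Provenance of every merged base is tracked.

# ---- working representation ------------------------------------------
# A "work" unit is list(id, seq (character), segs (data.table with
# source_site, source_scaffold, source_start, source_end, m_start, m_end,
# orientation)).  segs always tiles 1..nchar(seq).

newWork <- function(id, seq, site, sourceId = id, sourceStart = 1L) {
  list(id = id, seq = seq,
       segs = data.table(source_site = site, source_scaffold = sourceId,
                         source_start = as.integer(sourceStart),
                         source_end = as.integer(sourceStart + nchar(seq) - 1L),
                         m_start = 1L, m_end = as.integer(nchar(seq)),
                         orientation = "+"))
}

reflectIv <- function(iv, L) c(L - iv[2] + 1L, L - iv[1] + 1L)

orientWork <- function(w, flip) {
  if (!flip) return(w)
  L <- nchar(w$seq)
  segs <- copy(w$segs)
  newStart <- L - segs$m_end + 1L
  newEnd <- L - segs$m_start + 1L
  segs[, `:=`(m_start = newStart, m_end = newEnd,
              orientation = fifelse(orientation == "+", "-", "+"))]
  setorder(segs, m_start)
  list(id = w$id, seq = revComp(w$seq), segs = segs)
}

trimWork <- function(w, from, to) {
  stopifnot(from >= 1L, to <= nchar(w$seq), from <= to)
  segs <- w$segs[m_end >= from & m_start <= to]
  segs <- copy(segs)
  clipL <- pmax(0L, from - segs$m_start)
  clipR <- pmax(0L, segs$m_end - to)
  plus <- segs$orientation == "+"
  segs[, `:=`(
    m_start = pmax(m_start, as.integer(from)),
    m_end = pmin(m_end, as.integer(to)),
    source_start = source_start + fifelse(plus, clipL, clipR),
    source_end = source_end - fifelse(plus, clipR, clipL))]
  segs[, `:=`(m_start = m_start - as.integer(from) + 1L,
              m_end = m_end - as.integer(from) + 1L)]
  list(id = w$id, seq = substr(w$seq, from, to), segs = segs)
}

joinWork <- function(L, R, ovL, ovR, winnerIsL) {
  lenL <- nchar(L$seq); lenR <- nchar(R$seq)
  if (winnerIsL) {
    keepL <- c(1L, ovL[2])
    keepR <- c(ovR[2] + 1L, lenR)
  } else {
    keepL <- c(1L, ovL[1] - 1L)
    keepR <- c(ovR[1], lenR)
  }
  Lt <- trimWork(L, keepL[1], keepL[2])
  if (keepR[1] > keepR[2]) return(Lt)
  Rt <- trimWork(R, keepR[1], keepR[2])
  off <- nchar(Lt$seq)
  Rt$segs[, `:=`(m_start = m_start + off, m_end = m_end + off)]
  list(id = L$id, seq = paste0(Lt$seq, Rt$seq),
       segs = rbind(Lt$segs, Rt$segs))
}

# split scaffolds at runs of >= minRun N (scaffolding gaps must not seed
# anchors); returns list of work units
asWorkUnits <- function(seqs, site, minNRun = 10L, minLen = 1000L) {
  stopifnot(!is.null(names(seqs)))
  out <- list()
  short <- 0L
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    m <- gregexpr(sprintf("N{%d,}", minNRun), s)[[1]]
    if (m[1] == -1L) {
      pieces <- data.frame(start = 1L, end = nchar(s))
    } else {
      gapS <- as.integer(m); gapE <- gapS + attr(m, "match.length") - 1L
      st <- c(1L, gapE + 1L); en <- c(gapS - 1L, nchar(s))
      keep <- st <= en
      pieces <- data.frame(start = st[keep], end = en[keep])
    }
    multi <- nrow(pieces) > 1L
    for (i in seq_len(nrow(pieces))) {
      len <- pieces$end[i] - pieces$start[i] + 1L
      if (len < minLen) { short <- short + 1L; next }
      id <- if (multi) sprintf("%s.p%d", nm, i) else nm
      out[[length(out) + 1L]] <- newWork(
        id, substr(s, pieces$start[i], pieces$end[i]), site,
        sourceId = nm, sourceStart = pieces$start[i])
    }
  }
  if (short > 0L)
    warning(short, " scaffold piece(s) below ", minLen,
            " bp were rejected before merging")
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Find end-anchored and containment overlaps between two scaffold sets
#'
#' Candidates are seeded by shared k-mers (\code{anchor_k}), grouped on
#' alignment diagonals per scaffold pair and orientation, extended gaplessly
#' to the maximal implied overlap, and verified by mismatch counting.  Only
#' overlaps that are end-anchored (inner overhang at most \code{hco} on each
#' scaffold) with alignment length at least \code{mL} and identity at least
#' \code{c} percent are join candidates; a query aligned over at least
#' \code{containment_cov} of its length at identity \code{c} is flagged
#' contained.
#'
#' @param ref,query named DNAStringSet (or character vectors) of scaffolds.
#' @param params the \code{merge} list of a \code{\link{pipelineConfig}}.
#' @return data.table sorted by (aln_len desc, identity desc, ref_id,
#'   query_id) with columns ref_id, query_id, orientation ("same"/"rc"),
#'   r_start, r_end, q_start, q_end (oriented query coordinates), aln_len,
#'   identity, r_side, q_side, q_side_stored, contained, overhang_ref,
#'   overhang_query.
#' @export
findScaffoldOverlaps <- function(ref, query,
                                 params = pipelineConfig()$merge) {
  refC <- if (is(ref, "DNAStringSet"))
    setNames(as.character(ref), names(ref)) else ref
  qC <- if (is(query, "DNAStringSet"))
    setNames(as.character(query), names(query)) else query
  k <- params$anchor_k
  emptyCand <- data.table(
    ref_id = character(), query_id = character(), orientation = character(),
    r_start = integer(), r_end = integer(), q_start = integer(),
    q_end = integer(), aln_len = integer(), identity = numeric(),
    r_side = character(), q_side = character(), q_side_stored = character(),
    contained = logical(), overhang_ref = integer(),
    overhang_query = integer(), n_seed = integer())
  if (!length(refC) || !length(qC)) return(emptyCand)
  rt <- dropAmbiguousKmers(kmerTable(refC, k))
  if (!nrow(rt)) return(emptyCand)
  setkey(rt, kmer)
  rlen <- setNames(nchar(refC), names(refC))
  out <- list()
  for (orient in c("same", "rc")) {
    qO <- if (orient == "same") qC else setNames(revComp(qC), names(qC))
    qt <- dropAmbiguousKmers(kmerTable(qO, k))
    if (!nrow(qt)) next
    setnames(qt, c("id", "pos"), c("qid", "qpos"))
    setkey(qt, kmer)
    hits <- rt[qt, allow.cartesian = TRUE, nomatch = NULL]
    if (!nrow(hits)) next
    setnames(hits, c("id", "pos"), c("rid", "rpos"))
    hits[, diag_ := rpos - qpos]
    dg <- hits[, .(n_seed = .N), by = .(rid, qid, diag_)]
    setorder(dg, rid, qid, -n_seed, diag_)
    best <- dg[, .SD[1], by = .(rid, qid)]
    qlen <- setNames(nchar(qO), names(qO))
    for (i in seq_len(nrow(best))) {
      r <- best$rid[i]; q <- best$qid[i]; d <- best$diag_[i]
      rl <- rlen[[r]]; ql <- qlen[[q]]
      qs <- max(1L, 1L - d); qe <- min(ql, rl - d)
      if (qe < qs) next
      rs <- qs + d; re <- qe + d
      alnLen <- qe - qs + 1L
      minNeed <- min(params$mL, ceiling(params$containment_cov * ql))
      if (alnLen < minNeed) next
      mm <- stringMismatches(substr(refC[[r]], rs, re),
                             substr(qO[[q]], qs, qe))
      ident <- 100 * (1 - mm / alnLen)
      if (ident < params$c) next
      rSide <- if (rs == 1L && re == rl) "both" else
        if (rs == 1L) "left" else if (re == rl) "right" else NA_character_
      qSide <- if (qs == 1L && qe == ql) "both" else
        if (qs == 1L) "left" else if (qe == ql) "right" else NA_character_
      contained <- alnLen >= params$containment_cov * ql
      qSideStored <- if (orient == "same" || is.na(qSide) || qSide == "both")
        qSide else if (qSide == "left") "right" else "left"
      out[[length(out) + 1L]] <- data.table(
        ref_id = r, query_id = q, orientation = orient,
        r_start = rs, r_end = re, q_start = qs, q_end = qe,
        aln_len = alnLen, identity = ident, r_side = rSide,
        q_side = qSide, q_side_stored = qSideStored,
        contained = contained,
        overhang_ref = as.integer(min(rs - 1L, rl - re)),
        overhang_query = as.integer(min(qs - 1L, ql - qe)),
        n_seed = best$n_seed[i])
    }
  }
  if (!length(out)) return(emptyCand)
  cand <- rbindlist(out)
  # one candidate per scaffold pair: prefer longer, then more identical
  setorder(cand, -aln_len, -identity, ref_id, query_id)
  cand <- cand[!duplicated(cand[, .(ref_id, query_id)])]
  # enforce the inner-overhang cap for join candidates
  cand <- cand[contained == TRUE |
                 (overhang_ref <= params$hco & overhang_query <= params$hco)]
  setorder(cand, -aln_len, -identity, ref_id, query_id)
  cand
}

# assemble one connected path of accepted joins into a single work unit
assemblePath <- function(works, edges) {
  if (!length(edges)) return(works[[1]])
  deg <- table(unlist(lapply(edges, function(e) c(e$nodeA, e$nodeB))))
  termini <- sort(names(deg)[deg == 1L])
  start <- termini[[1]]
  edgeAt <- function(node, usedEdges) {
    which(vapply(edges, function(e)
      (e$nodeA == node || e$nodeB == node), TRUE) &
        !seq_along(edges) %in% usedEdges)
  }
  endOf <- function(e, node) {
    if (e$nodeA == node) list(side = e$sideA, ov = c(e$oA1, e$oA2))
    else list(side = e$sideB, ov = c(e$oB1, e$oB2))
  }
  used <- integer(0)
  ei <- edgeAt(start, used)[1]
  e <- edges[[ei]]
  endS <- endOf(e, start)
  flip <- endS$side == "left"
  cur <- orientWork(works[[start]], flip)
  off <- 0L           # assembly coord = node physical coord + off
  curNode <- start
  curFlip <- flip
  assembly <- cur
  repeat {
    e <- edges[[ei]]; used <- c(used, ei)
    nextNode <- if (e$nodeA == curNode) e$nodeB else e$nodeA
    endC <- endOf(e, curNode)
    endN <- endOf(e, nextNode)
    lenC <- nchar(works[[curNode]]$seq)
    ovC <- if (curFlip) reflectIv(endC$ov, lenC) else endC$ov
    ovL <- ovC + off
    nextFlip <- endN$side == "right"
    lenN <- nchar(works[[nextNode]]$seq)
    ovR <- if (nextFlip) reflectIv(endN$ov, lenN) else endN$ov
    wN <- orientWork(works[[nextNode]], nextFlip)
    winnerIsL <- e$winner == curNode
    prevLen <- if (winnerIsL) ovL[2] else ovL[1] - 1L
    keepRfrom <- if (winnerIsL) ovR[2] + 1L else ovR[1]
    assembly <- joinWork(assembly, wN, ovL, ovR, winnerIsL)
    off <- prevLen + 1L - keepRfrom
    curNode <- nextNode
    curFlip <- nextFlip
    nxt <- edgeAt(curNode, used)
    if (!length(nxt)) break
    ei <- nxt[1]
  }
  # canonical orientation: most merged bases forward, first segment "+" on
  # ties, so the same inputs always yield the same strand
  segW <- assembly$segs$m_end - assembly$segs$m_start + 1L
  minus <- sum(segW[assembly$segs$orientation == "-"])
  plus <- sum(segW) - minus
  if (minus > plus ||
      (minus == plus && assembly$segs$orientation[1] == "-"))
    assembly <- orientWork(assembly, TRUE)
  assembly
}

finalizeMerged <- function(works, dropped) {
  widths <- vapply(works, function(w) nchar(w$seq), 0L)
  firstSrc <- vapply(works, function(w) w$segs$source_scaffold[1], "")
  ord <- order(-widths, firstSrc)
  works <- works[ord]
  ids <- sprintf("ctg%05d", seq_along(works))
  seqs <- DNAStringSet(vapply(works, `[[`, "", "seq"))
  names(seqs) <- ids
  prov <- rbindlist(lapply(seq_along(works), function(i) {
    s <- copy(works[[i]]$segs)
    s[, `:=`(merged_id = ids[i])]
    setorder(s, m_start)
    s[, segment_index := seq_len(.N)]
    s
  }))
  prov <- as.data.frame(prov[, .(merged_id, segment_index, source_site,
                                 source_scaffold,
                                 merged_start = m_start, merged_end = m_end,
                                 source_start, source_end, orientation)])
  new("MergedReference", scaffolds = seqs, provenance = prov,
      dropped = dropped)
}

workUnitsOf <- function(x, site) {
  if (is(x, "MergedReference")) {
    lapply(setNames(names(x@scaffolds), names(x@scaffolds)), function(nm) {
      pv <- x@provenance
      s <- as.data.table(pv[pv$merged_id == nm, c(
        "source_site", "source_scaffold", "source_start", "source_end",
        "merged_start", "merged_end", "orientation")])
      setnames(s, c("merged_start", "merged_end"), c("m_start", "m_end"))
      list(id = nm, seq = as.character(x@scaffolds[[nm]]), segs = s)
    })
  } else {
    asWorkUnits(if (is(x, "DNAStringSet"))
      setNames(as.character(x), names(x)) else x, site)
  }
}

# drop output scaffolds contained in a longer output scaffold
containmentSweep <- function(works, params, dropped) {
  if (length(works) < 2L) return(list(works = works, dropped = dropped))
  seqs <- setNames(vapply(works, `[[`, "", "seq"),
                   vapply(works, `[[`, "", "id"))
  cand <- findScaffoldOverlaps(seqs, seqs, params)
  cand <- cand[contained == TRUE & ref_id != query_id]
  if (!nrow(cand)) return(list(works = works, dropped = dropped))
  w <- nchar(seqs)
  drop <- character(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand$ref_id[i]; q <- cand$query_id[i]
    if (r %in% drop || q %in% drop) next
    if (w[[q]] < w[[r]] || (w[[q]] == w[[r]] && q > r)) drop <- c(drop, q)
  }
  if (length(drop)) {
    add <- rbindlist(lapply(drop, function(q) {
      s <- works[[q]]$segs
      data.table(scaffold_id = s$source_scaffold, site = s$source_site,
                 contained_in = cand$ref_id[match(q, cand$query_id)])
    }))
    dropped <- rbind(dropped, as.data.frame(add))
    works <- works[!names(works) %in% drop]
  }
  list(works = works, dropped = dropped)
}

#' Merge a query scaffold set into a reference scaffold set
#'
#' Overlap candidates from \code{\link{findScaffoldOverlaps}} are accepted
#' greedily in sorted order, each scaffold end used at most once and cycles
#' forbidden; accepted joins splice sequences keeping reference-set bases
#' across the overlap; query scaffolds contained in a reference scaffold are
#' dropped; everything else is carried through unchanged.  The result is
#' deterministic for a fixed input order.
#'
#' @param ref reference set: DNAStringSet, named character vector, or a
#'   \linkS4class{MergedReference} from an earlier merge.
#' @param query query set (same types).
#' @param params the \code{merge} list of a \code{\link{pipelineConfig}}.
#' @param refSite,querySite site labels recorded in provenance (ignored for
#'   MergedReference inputs, which carry their own).
#' @return a \linkS4class{MergedReference}.
#' @export
mergePair <- function(ref, query, params = pipelineConfig()$merge,
                      refSite = "ref", querySite = "query") {
  refW <- workUnitsOf(ref, refSite)
  qW <- workUnitsOf(query, querySite)
  refSeqs <- setNames(vapply(refW, `[[`, "", "seq"), names(refW))
  qSeqs <- setNames(vapply(qW, `[[`, "", "seq"), names(qW))
  cand <- findScaffoldOverlaps(refSeqs, qSeqs, params)

  dropped <- data.frame(scaffold_id = character(), site = character(),
                        contained_in = character(),
                        stringsAsFactors = FALSE)
  containedQ <- unique(cand[contained == TRUE]$query_id)
  if (length(containedQ)) {
    firstRef <- vapply(containedQ, function(q)
      cand[contained == TRUE & query_id == q]$ref_id[1], "")
    dropped <- rbind(dropped, do.call(rbind, lapply(containedQ, function(q) {
      s <- qW[[q]]$segs
      data.frame(scaffold_id = s$source_scaffold, site = s$source_site,
                 contained_in = firstRef[[q]], stringsAsFactors = FALSE)
    })))
    qW <- qW[!names(qW) %in% containedQ]
  }

  joins <- cand[contained == FALSE & query_id %in% names(qW) &
                  r_side %in% c("left", "right") &
                  q_side_stored %in% c("left", "right") &
                  aln_len >= params$mL]
  # greedy acceptance: ends used once, no cycles (union-find)
  parent <- new.env(parent = emptyenv())
  findRoot <- function(x) {
    while (!is.null(parent[[x]]) && parent[[x]] != x) x <- parent[[x]]
    x
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (is.null(parent[[ra]])) parent[[ra]] <- ra
    parent[[rb]] <- ra
  }
  allNodes <- c(names(refW), names(qW))
  for (n in allNodes) parent[[n]] <- n
  usedEnd <- new.env(parent = emptyenv())
  edges <- list()
  if (nrow(joins)) for (i in seq_len(nrow(joins))) {
    r <- joins$ref_id[i]; q <- joins$query_id[i]
    keyR <- paste0(r, ".", joins$r_side[i])
    keyQ <- paste0(q, ".", joins$q_side_stored[i])
    if (!is.null(usedEnd[[keyR]]) || !is.null(usedEnd[[keyQ]])) next
    if (findRoot(r) == findRoot(q)) next
    usedEnd[[keyR]] <- TRUE; usedEnd[[keyQ]] <- TRUE
    unite(r, q)
    ql <- nchar(qSeqs[[q]])
    qOv <- c(joins$q_start[i], joins$q_end[i])
    if (joins$orientation[i] == "rc") qOv <- reflectIv(qOv, ql)
    edges[[length(edges) + 1L]] <- list(
      nodeA = r, sideA = joins$r_side[i],
      oA1 = joins$r_start[i], oA2 = joins$r_end[i],
      nodeB = q, sideB = joins$q_side_stored[i],
      oB1 = qOv[1], oB2 = qOv[2], winner = r)
  }

  works <- c(refW, qW)
  comp <- vapply(names(works), findRoot, "")
  merged <- list()
  for (root in unique(comp)) {
    nodes <- names(works)[comp == root]
    es <- Filter(function(e) e$nodeA %in% nodes, edges)
    m <- assemblePath(works[nodes], es)
    merged[[m$id]] <- m
  }
  sw <- containmentSweep(merged, params, dropped)
  finalizeMerged(sw$works, sw$dropped)
}

#' Merge scaffold sets from several sites into one common reference
#'
#' Sets are ordered by descending total assembly size (the largest set is
#' the backbone) and merged by a left fold of \code{\link{mergePair}};
#' provenance accumulates across folds.  Merging the per-individual merged
#' references of two individuals again is the same operation.
#'
#' @param scaffoldSets named list (name = site) of DNAStringSet / character
#'   vectors, or of MergedReference objects.
#' @param params the \code{merge} list of a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{MergedReference}.
#' @export
mergeSites <- function(scaffoldSets, params = pipelineConfig()$merge) {
  if (length(scaffoldSets) < 2L)
    stop("parameter error: mergeSites needs >= 2 scaffold sets")
  if (is.null(names(scaffoldSets)))
    names(scaffoldSets) <- sprintf("set%d", seq_along(scaffoldSets))
  totalBp <- vapply(scaffoldSets, function(s) {
    if (is(s, "MergedReference")) sum(width(s@scaffolds))
    else if (is(s, "DNAStringSet")) sum(width(s))
    else sum(nchar(s))
  }, 0)
  ord <- order(-totalBp, names(scaffoldSets))
  scaffoldSets <- scaffoldSets[ord]
  acc <- scaffoldSets[[1]]
  accSite <- names(scaffoldSets)[1]
  for (i in 2:length(scaffoldSets)) {
    acc <- mergePair(acc, scaffoldSets[[i]], params,
                     refSite = accSite, querySite = names(scaffoldSets)[i])
    accSite <- "merged"
  }
  if (!is(acc, "MergedReference"))
    acc <- finalizeMerged(workUnitsOf(acc, accSite),
                          data.frame(scaffold_id = character(),
                                     site = character(),
                                     contained_in = character()))
  acc
}
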