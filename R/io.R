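# I/O layer: FASTA / FASTQ / SAM (text subset) / GFF3 / annotation and
# matrix TSVs.  Coordinates are 1-based closed everywhere in memory (the
# IRanges convention), which is also the on-disk convention of SAM and GFF3,
# so the converters here perform no coordinate arithmetic.

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased and validated against the {A,C,G,T,N} alphabet;
#' record order is preserved.  Names are the first header token; the
#' remainder of the header is kept in \code{mcols(x)$description} (key=value
#' tags there can carry site/individual/truth provenance).
#'
#' @param path path to a FASTA file.
#' @return a named DNAStringSet.
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], ">"))
    stop("FASTA format error at line 1: expected '>' header")
  hdr <- startsWith(lines, ">")
  rec <- cumsum(hdr)
  ids <- character(sum(hdr)); desc <- character(sum(hdr))
  hlines <- which(hdr)
  for (i in seq_along(hlines)) {
    h <- sub("^>", "", lines[[hlines[i]]])
    if (!nzchar(trimws(h)))
      stop("FASTA format error at line ", hlines[i], ": empty header")
    toks <- strsplit(trimws(h), "[ \t]+")[[1]]
    ids[i] <- toks[[1]]
    desc[i] <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
  }
  seqs <- vapply(seq_len(sum(hdr)), function(i) {
    paste(lines[rec == i & !hdr], collapse = "")
  }, character(1))
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("FASTA format error at line ", hlines[empty[1]],
         ": record '", ids[empty[1]], "' has an empty sequence")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA format error: record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate record id '",
         ids[anyDuplicated(ids)], "'")
  x <- DNAStringSet(seqs)
  names(x) <- ids
  mcols(x) <- DataFrame(description = desc)
  x
}

#' Write a DNAStringSet to FASTA
#'
#' @param x a named DNAStringSet; \code{mcols(x)$description}, when present,
#'   is appended to each header.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastaRecords <- function(x, path) {
  stopifnot(is(x, "DNAStringSet"), !is.null(names(x)))
  y <- x
  d <- mcols(x)$description
  if (!is.null(d)) {
    nm <- ifelse(nzchar(d), paste(names(x), d), names(x))
    names(y) <- nm
  }
  writeXStringSet(y, filepath = path, width = 80L)
  invisible(path)
}

#' Read single-end FASTQ records
#'
#' Strict 4-line records; sequence and quality lengths must agree.
#'
#' @param path path to a FASTQ file.
#' @return data.table with columns id, seq, qual.
#' @export
readFastqReads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error: ", path, " does not contain 4-line records")
  n <- length(lines) %/% 4L
  i1 <- seq.int(1L, by = 4L, length.out = n)
  if (any(!startsWith(lines[i1], "@")))
    stop("FASTQ format error at line ",
         i1[which(!startsWith(lines[i1], "@"))[1]], ": expected '@' header")
  if (any(!startsWith(lines[i1 + 2L], "+")))
    stop("FASTQ format error: '+' separator missing")
  ids <- sub("^@", "", lines[i1])
  ids <- vapply(strsplit(ids, "[ \t]"), `[[`, "", 1L)
  seq <- toupper(lines[i1 + 1L])
  qual <- lines[i1 + 3L]
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("FASTQ format error at line ", i1[bad[1]],
         ": sequence and quality lengths differ for read '", ids[bad[1]], "'")
  data.table(id = ids, seq = seq, qual = qual)
}

#' Write FASTQ records
#' @param reads data.table/data.frame with columns id, seq, qual.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastqReads <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq.int(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq.int(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq.int(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq.int(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Pair mate-1 and mate-2 FASTQ streams by position
#'
#' Mate files must list the same read ids in the same order (a trailing /1
#' or /2 suffix is stripped).
#'
#' @param r1,r2 data.tables from \code{\link{readFastqReads}}.
#' @return data.table with columns id, seq1, qual1, seq2, qual2.
#' @export
pairMates <- function(r1, r2) {
  if (nrow(r1) != nrow(r2))
    stop("pairing error: mate files have ", nrow(r1), " and ", nrow(r2),
         " records")
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  if (!all(id1 == id2))
    stop("pairing error: mate ids disagree at record ",
         which(id1 != id2)[1])
  data.table(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual)
}

# ---------------------------------------------------------------- SAM ----

#' Read a SAM file (text subset)
#'
#' Supports @SQ header lines and the 11 mandatory columns.  Decoded flag
#' bits: paired (0x1), properly paired (0x2), unmapped (0x4), reverse
#' strand (0x10), first mate (0x40).  Records aligned to a target absent
#' from the header raise a reference error.  Coordinates stay 1-based as on
#' disk (the in-memory convention of this package).
#'
#' @param path path to a SAM file.
#' @return list with elements \code{header} (data.frame target, length) and
#'   \code{alignments} (data.table qname, flag, target_id, pos, mapq, cigar,
#'   rnext, pnext, tlen, seq, qual, mapped, strand, mate1, properly_paired).
#' @export
readSamRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  target <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  tlen_ <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  header <- data.frame(target = target, length = tlen_,
                       stringsAsFactors = FALSE)
  if (!length(body)) {
    aln <- data.table(qname = character(), flag = integer(),
                      target_id = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      rnext = character(), pnext = integer(),
                      tlen = integer(), seq = character(), qual = character())
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(f) < 11L)
    if (length(short))
      stop("SAM format error: record ", short[1], " has fewer than 11 fields")
    g <- function(i) vapply(f, `[[`, "", i)
    aln <- data.table(qname = g(1), flag = as.integer(g(2)),
                      target_id = g(3), pos = as.integer(g(4)),
                      mapq = as.integer(g(5)), cigar = g(6), rnext = g(7),
                      pnext = as.integer(g(8)), tlen = as.integer(g(9)),
                      seq = g(10), qual = g(11))
  }
  aln[, mapped := bitwAnd(flag, 4L) == 0L]
  aln[, strand := fifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]
  aln[, mate1 := bitwAnd(flag, 64L) != 0L |
        bitwAnd(flag, 1L) == 0L]          # unpaired reads count as mate 1
  aln[, properly_paired := bitwAnd(flag, 2L) != 0L]
  unk <- aln$mapped & !(aln$target_id %in% c("*", header$target))
  if (any(unk))
    stop("SAM reference error: unknown target id '",
         aln$target_id[which(unk)[1]], "'")
  aln[mapped == FALSE, `:=`(target_id = NA_character_, pos = NA_integer_)]
  list(header = header, alignments = aln)
}

#' Write alignments to SAM (text subset)
#'
#' @param alignments data.table in the layout produced by
#'   \code{\link{readSamRecords}} or \code{\link{mapReads}}.
#' @param header data.frame with columns target, length.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSamRecords <- function(alignments, header, path) {
  a <- as.data.table(alignments)
  if (!"flag" %in% names(a)) {
    a[, flag := 1L +                                   # paired
        fifelse(properly_paired, 2L, 0L) +
        fifelse(mapped, 0L, 4L) +
        fifelse(mapped & strand == "-", 16L, 0L) +
        fifelse(mate1, 64L, 128L)]
  }
  hl <- c("@HD\tVN:1.6\tSO:unsorted",
          sprintf("@SQ\tSN:%s\tLN:%d", header$target, header$length))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  a$qname, a$flag,
                  fifelse(is.na(a$target_id), "*", a$target_id),
                  fifelse(is.na(a$pos), 0L, a$pos),
                  fifelse(is.na(a$mapq), 0L, a$mapq),
                  if ("cigar" %in% names(a)) fifelse(is.na(a$cigar) | !a$mapped, "*", a$cigar) else "*",
                  if ("rnext" %in% names(a)) fifelse(is.na(a$rnext), "*", a$rnext) else "*",
                  if ("pnext" %in% names(a)) fifelse(is.na(a$pnext), 0L, a$pnext) else 0L,
                  if ("tlen" %in% names(a)) fifelse(is.na(a$tlen), 0L, a$tlen) else 0L,
                  if ("seq" %in% names(a)) fifelse(is.na(a$seq), "*", a$seq) else "*",
                  if ("qual" %in% names(a)) fifelse(is.na(a$qual), "*", a$qual) else "*")
  writeLines(c(hl, body), path)
  invisible(path)
}

# --------------------------------------------------------------- GFF3 ----

#' Read gene models from GFF3
#'
#' Imports CDS/gene rows via rtracklayer.  Records lacking an ID attribute
#' receive a synthesized id \code{scaffold:start-end} with a warning;
#' \code{end < start} on disk is a format error.
#'
#' @param path path to a GFF3 file.
#' @return GRanges with mcols gene_id and frame.
#' @export
readGff3Genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  rows <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(rows)) {
    f <- strsplit(rows, "\t", fixed = TRUE)
    st <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 5L)))
    bad <- which(!is.na(st) & !is.na(en) & en < st)
    if (length(bad))
      stop("GFF3 format error: end < start in record ", bad[1])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  miss <- is.na(ids) | !nzchar(ids)
  if (any(miss)) {
    ids[miss] <- sprintf("%s:%d-%d", as.character(seqnames(gr))[miss],
                         start(gr)[miss], end(gr)[miss])
    warning(sum(miss), " GFF3 record(s) lacked an ID attribute; ",
            "ids synthesized as scaffold:start-end")
  }
  fr <- gr$phase
  if (is.null(fr)) fr <- rep(0L, length(gr))
  fr[is.na(fr)] <- 0L
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = ids, frame = as.integer(fr))
  out
}

#' Write gene models to GFF3
#'
#' @param features GRanges with mcols gene_id and (optionally) frame.
#' @param path output path.
#' @param type feature type column, default "CDS".
#' @return invisibly, \code{path}.
#' @export
writeGff3Genes <- function(features, path, type = "CDS") {
  gr <- granges(features)
  fr <- mcols(features)$frame
  if (is.null(fr)) fr <- rep(0L, length(features))
  mcols(gr) <- DataFrame(source = "SpatialMetaTx", type = type,
                         phase = as.integer(fr),
                         ID = mcols(features)$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ------------------------------------------------------ TSV tables -------

#' Read a gene annotation table
#'
#' Expected columns: gene_id, ko, cog, reactions (semicolon-delimited).
#' Empty cells become NA; \code{is_known} is derived as "ko or cog present".
#' Comma- and tab-separated files are both accepted.
#'
#' @param path path to the table.
#' @return data.frame with columns gene_id, ko, cog, reactions, is_known.
#' @export
readAnnotationTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, colClasses = "character", na.strings = "")
  need <- c("gene_id", "ko", "cog", "reactions")
  if (!all(need %in% names(tab)))
    stop("annotation format error: header must contain ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("annotation format error: duplicate gene_id '",
         tab$gene_id[anyDuplicated(tab$gene_id)], "'")
  data.frame(gene_id = tab$gene_id, ko = tab$ko, cog = tab$cog,
             reactions = tab$reactions,
             is_known = !is.na(tab$ko) | !is.na(tab$cog),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation table
#' @param annotations data.frame with columns gene_id, ko, cog, reactions.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeAnnotationTsv <- function(annotations, path) {
  a <- annotations[, c("gene_id", "ko", "cog", "reactions")]
  data.table::fwrite(a, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Write / read a numeric matrix as TSV
#'
#' First column \code{id} holds row names; remaining columns are samples.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return \code{writeMatrixTsv}: invisibly, \code{path};
#'   \code{readMatrixTsv}: the matrix.
#' @export
writeMatrixTsv <- function(mat, path) {
  dt <- data.table(id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
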