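# Shared low-level helpers: seeded RNG scopes, string comparison, k-mer
# tables.  Everything downstream (merging, mapping, truth alignment) seeds
# overlaps from the k-mer tables built here.

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} after \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so simulation functions are pure functions of their seed
#' without disturbing the session RNG stream.
#'
#' @param seed integer seed (kept below 2^31).
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Count mismatching characters between equal-length strings
#'
#' Vectorised Hamming distance over pairs of equal-length strings; used by
#' the gapless overlap and read-mapping verifiers.
#'
#' @param a,b character vectors of equal length; \code{nchar(a[i]) ==
#'   nchar(b[i])} is required.
#' @return integer vector of mismatch counts.
#' @keywords internal
stringMismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0))
  if (any(nchar(a) != nchar(b)))
    stop("stringMismatches: unequal string lengths")
  vapply(seq_along(a), function(i) {
    sum(charToRaw(a[[i]]) != charToRaw(b[[i]]))
  }, integer(1))
}

#' Reverse complement of character sequences
#' @param x character vector of DNA strings.
#' @return character vector, reverse complemented.
#' @keywords internal
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Table of all k-mers of a sequence set
#'
#' @param seqs named character vector of sequences.
#' @param k k-mer size.
#' @param step sample every \code{step}-th position (1 = every position).
#' @return data.table with columns kmer, id, pos (1-based start).
#' @keywords internal
kmerTable <- function(seqs, k, step = 1L) {
  stopifnot(!is.null(names(seqs)))
  parts <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq.int(1L, n - k + 1L, by = step)
    data.table(kmer = substring(s, starts, starts + k - 1L),
               id = nm, pos = starts)
  })
  out <- rbindlist(parts)
  if (!nrow(out)) out <- data.table(kmer = character(), id = character(),
                                    pos = integer())
  out
}

# drop k-mers containing N (never used as anchors)
dropAmbiguousKmers <- function(dt) {
  if (!nrow(dt)) return(dt)
  dt[!grepl("N", kmer, fixed = TRUE)]
}

#' Parse key=value tags from a FASTA description
#' @param desc character vector of description strings.
#' @return list of named character vectors.
#' @keywords internal
parseHeaderTags <- function(desc) {
  lapply(desc, function(d) {
    if (is.na(d) || !nzchar(d)) return(character(0))
    toks <- strsplit(d, "[ \t]+")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    if (!length(kv)) return(character(0))
    parts <- strsplit(kv, "=", fixed = TRUE)
    setNames(vapply(parts, function(p) paste(p[-1], collapse = "="), ""),
             vapply(parts, `[[`, "", 1L))
  })
}

# deterministic md5 of a set of files (pipeline manifests)
fileChecksums <- function(paths) {
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  setNames(out, paths)
}
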