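# Independent oracles and small fixture builders shared across tests.
# Every oracle re-derives its quantity by brute force, without touching the
# implementation code paths it checks.

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcSeq <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# literal triple-loop implementation of the bivariate spatial statistic
oracleLeeL <- function(x, y, V) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  denomW <- 0
  num <- 0
  for (i in seq_len(n)) {
    wi <- 0
    sx <- 0
    sy <- 0
    for (j in seq_len(n)) {
      wi <- wi + V[i, j]
      sx <- sx + V[i, j] * (x[j] - xb)
      sy <- sy + V[i, j] * (y[j] - yb)
    }
    denomW <- denomW + wi^2
    num <- num + sx * sy
  }
  nx <- sqrt(sum((x - xb)^2)); ny <- sqrt(sum((y - yb)^2))
  (n / denomW) * num / (nx * ny)
}

# tie-corrected pair-counting (Mann-Whitney) AUC estimator
oracleAuc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force union-mode pair counting over explicit intervals
oracleCountPairs <- function(mateIv, genes) {
  # mateIv: data.frame(qname, chr, start, end); genes: data.frame(gene_id,
  # chr, start, end)
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  for (q in unique(mateIv$qname)) {
    m <- mateIv[mateIv$qname == q, , drop = FALSE]
    hit <- character(0)
    for (i in seq_len(nrow(m))) for (g in seq_len(nrow(genes))) {
      if (m$chr[i] == genes$chr[g] && m$start[i] <= genes$end[g] &&
          m$end[i] >= genes$start[g])
        hit <- union(hit, genes$gene_id[g])
    }
    if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
  }
  counts
}

# independent ORF validator: ATG start, stop end, no internal in-frame stop
oracleValidOrf <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0 || n < 6) return(FALSE)
  cod <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  stops <- c("TAA", "TAG", "TGA")
  cod[1] == "ATG" && cod[length(cod)] %in% stops &&
    !any(cod[-length(cod)] %in% stops)
}

# independent maximal-ORF scan (per strand / frame), distinct code path
# from the implementation: regex-free, translate-based stop detection
oracleOrfScan <- function(seqChar, minLen = 300L) {
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (std in c("+", "-")) {
    s <- if (std == "+") seqChar else rcSeq(seqChar)
    L <- nchar(s)
    for (f in 0:2) {
      cs <- seq(f + 1L, L - 2L, by = 3L)
      cod <- substring(s, cs, cs + 2L)
      stopIdx <- which(cod %in% stops)
      prev <- 0L
      for (si in stopIdx) {
        win <- which(cod[(prev + 1L):si] == "ATG")
        if (length(win)) {
          a <- prev + win[1]
          lenNt <- 3L * (si - a + 1L)
          if (lenNt >= minLen) {
            st <- f + 3L * (a - 1L) + 1L
            en <- f + 3L * si
            if (std == "-") { t <- st; st <- L - en + 1L; en <- L - t + 1L }
            out[[length(out) + 1L]] <- data.frame(start = st, end = en,
                                                  strand = std)
          }
        }
        prev <- si
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

gutWeights <- function() {
  buildWeights(c("ind1", "ind2"), c("cecum", "transverse_colon", "feces"))
}

# plant an ORF inside low-complexity padding that contains no ATG
plantOrf <- function(orfSeq, before = 400L, after = 400L) {
  pad <- function(n) paste(rep("C", n), collapse = "")
  list(seq = paste0(pad(before), orfSeq, pad(after)),
       start = before + 1L, end = before + nchar(orfSeq))
}

simpleOrf <- function(nCodons = 100L) {
  paste0("ATG", strrep("GAA", nCodons - 2L), "TAA")
}
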