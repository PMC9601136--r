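# Covariation analysis with bivariate spatial relevance.  Cluster
# expression profiles over the (individual x site) sample grid are compared
# with Lee's L statistic, which couples the correlation of two variables
# with their smoothing over a spatial weight matrix V encoding adjacency of
# sites within an individual.  A threshold calibrated on annotated clusters
# to a target false positive rate transfers functional labels to
# unannotated clusters; label enrichment is tested with Fisher's exact test
# and Benjamini-Hochberg correction.

#' Build site-adjacency spatial weights
#'
#' Within each individual, v_ij = 1 for identical (when
#' \code{includeSelf}) or chain-adjacent sites in the given order, 0
#' otherwise; weights are 0 across individuals; rows are standardised to
#' sum to 1.  The matrix depends only on the site layout, never on data.
#'
#' @param individuals individual ids.
#' @param siteOrder ordered site chain (>= 2 sites).
#' @param includeSelf include the diagonal before standardisation.
#' @return a \linkS4class{SpatialWeights}.
#' @export
buildWeights <- function(individuals, siteOrder, includeSelf = TRUE) {
  nS <- length(siteOrder)
  if (nS < 2L && !includeSelf)
    stop("single site per individual with includeSelf = FALSE yields ",
         "all-zero rows")
  samples <- do.call(rbind, lapply(individuals, function(ind)
    data.frame(individual = ind, site = siteOrder,
               stringsAsFactors = FALSE)))
  n <- nrow(samples)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (samples$individual[i] != samples$individual[j]) next
    si <- match(samples$site[i], siteOrder)
    sj <- match(samples$site[j], siteOrder)
    if ((includeSelf && si == sj) || abs(si - sj) == 1L) V[i, j] <- 1
  }
  rs <- rowSums(V)
  if (any(rs == 0))
    stop("all-zero weight row: site layout leaves a sample isolated")
  V <- V / rs
  rownames(V) <- colnames(V) <- paste(samples$individual, samples$site,
                                      sep = ".")
  new("SpatialWeights", V = V, samples = samples)
}

#' Lee's bivariate spatial association statistic
#'
#' L(x, y) = [n / sum_i (sum_j v_ij)^2] *
#'           sum_i [ (sum_j v_ij (x_j - xbar)) (sum_j v_ij (y_j - ybar)) ] /
#'           (||x - xbar|| * ||y - ybar||).
#'
#' With V = I the statistic reduces to the Pearson correlation of x and y.
#' It is symmetric in (x, y) and invariant to positive affine transforms of
#' either argument.  Constant vectors are undefined (error).
#'
#' @param x,y numeric vectors of length n.
#' @param W a \linkS4class{SpatialWeights} (or a bare n x n matrix).
#' @return the L value.
#' @export
leeL <- function(x, y, W) {
  V <- if (is(W, "SpatialWeights")) W@V else W
  n <- length(x)
  stopifnot(length(y) == n, nrow(V) == n, ncol(V) == n)
  xc <- x - mean(x)
  yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0)
    stop("lee's L is undefined for a constant vector")
  pref <- n / sum(rowSums(V)^2)
  pref * sum((V %*% xc) * (V %*% yc)) / (nx * ny)
}

#' Pairwise Lee's L between the rows of two profile matrices
#'
#' @param X,Y cluster x sample matrices (Y defaults to X).
#' @param W a \linkS4class{SpatialWeights}.
#' @return matrix of L values, rows of X against rows of Y.
#' @export
leeLMatrix <- function(X, W, Y = X) {
  V <- if (is(W, "SpatialWeights")) W@V else W
  n <- ncol(X)
  pref <- n / sum(rowSums(V)^2)
  cen <- function(M) M - rowMeans(M)
  Xc <- cen(X); Yc <- cen(Y)
  nX <- sqrt(rowSums(Xc^2)); nY <- sqrt(rowSums(Yc^2))
  if (any(nX == 0) || any(nY == 0))
    stop("lee's L is undefined for a constant profile")
  A <- Xc %*% t(V)
  B <- Yc %*% t(V)
  pref * (A %*% t(B)) / outer(nX, nY)
}

#' Cluster expression profiles over the sample grid
#'
#' The profile of a cluster is the sum (or mean) of its member genes'
#' expression per sample, optionally log2(1 + value) transformed.  Clusters
#' containing masked (NA) values, or with zero variance across samples, are
#' excluded with a message.
#'
#' @param mat gene x sample matrix of one expression layer.
#' @param clusters data.frame with columns cluster_id, gene_id.
#' @param aggregate "sum" or "mean".
#' @param log2p1 apply log2(1 + value) to the aggregated profile.
#' @return cluster x sample matrix.
#' @export
clusterProfiles <- function(mat, clusters, aggregate = c("sum", "mean"),
                            log2p1 = TRUE) {
  aggregate <- match.arg(aggregate)
  cl <- clusters[clusters$gene_id %in% rownames(mat), , drop = FALSE]
  if (!nrow(cl)) return(matrix(numeric(), 0, ncol(mat)))
  agg <- rowsum(mat[cl$gene_id, , drop = FALSE], group = cl$cluster_id)
  if (aggregate == "mean")
    agg <- agg / as.vector(table(cl$cluster_id)[rownames(agg)])
  if (log2p1) agg <- log2(1 + agg)
  bad <- apply(agg, 1L, function(v) anyNA(v) || sd(v) == 0)
  if (any(bad))
    message(sum(bad), " cluster profile(s) excluded (masked or constant)")
  agg[!bad, , drop = FALSE]
}

#' ROC curve over score thresholds
#'
#' Sweeps all distinct score values as thresholds (call positive when score
#' >= threshold) and reports (FPR, sensitivity) per threshold, with the
#' degenerate all-negative row (threshold Inf) first.
#'
#' @param L numeric scores.
#' @param positive logical truth labels.
#' @return data.frame with columns threshold, fpr, sensitivity.
#' @export
rocFromScores <- function(L, positive) {
  ord <- order(-L)
  Ls <- L[ord]; ps <- positive[ord]
  nPos <- sum(positive); nNeg <- sum(!positive)
  cumP <- cumsum(ps); cumN <- cumsum(!ps)
  runs <- rle(Ls)
  lastOf <- cumsum(runs$lengths)
  data.frame(threshold = c(Inf, runs$values),
             fpr = c(0, cumN[lastOf] / nNeg),
             sensitivity = c(0, cumP[lastOf] / nPos))
}

#' Area under a ROC curve by the trapezoid rule
#' @param fpr,sens ROC coordinates (the (0,0) and (1,1) endpoints are added
#'   if absent).
#' @return AUC in [0, 1].
#' @export
trapezoidAuc <- function(fpr, sens) {
  o <- order(fpr, sens)
  f <- c(fpr[o], 1); s <- c(sens[o], 1)
  if (f[1] != 0) { f <- c(0, f); s <- c(0, s) }
  sum(diff(f) * (head(s, -1) + tail(s, -1)) / 2)
}

#' Benchmark the covariation analysis on annotated clusters
#'
#' Over all unordered pairs of known clusters carrying reaction labels, a
#' pair is a true positive when the clusters share at least one reaction.
#' The ROC is swept over all distinct L values (call positive when L >=
#' threshold), the AUC is the trapezoid over (FPR, sensitivity), and theta
#' is the smallest L whose empirical FPR is at or below \code{targetFpr}.
#'
#' @param profiles cluster x sample matrix (\code{\link{clusterProfiles}}).
#' @param clusterReactions named list: cluster_id -> character vector of
#'   reaction labels (clusters absent or empty are excluded from the truth
#'   set, not treated as negatives).
#' @param W a \linkS4class{SpatialWeights}.
#' @param targetFpr FPR bound for threshold selection.
#' @return a \linkS4class{BenchmarkResult}.
#' @export
benchmarkKnown <- function(profiles, clusterReactions, W,
                           targetFpr = 0.05) {
  ids <- rownames(profiles)
  clusterReactions <- lapply(clusterReactions, function(v)
    v[!is.na(v) & nzchar(v)])
  withRxn <- ids[ids %in% names(clusterReactions) &
                   lengths(clusterReactions[ids]) > 0]
  if (length(withRxn) < 2L)
    stop("benchmark undefined: need >= 2 known clusters with reactions")
  P <- profiles[withRxn, , drop = FALSE]
  Lm <- leeLMatrix(P, W)
  pr <- combn(length(withRxn), 2L)
  L <- Lm[cbind(pr[1, ], pr[2, ])]
  rx <- clusterReactions[withRxn]
  if (all(lengths(rx) == 1L)) {      # fast path: single-label clusters
    lab <- unlist(rx)
    positive <- lab[pr[1, ]] == lab[pr[2, ]]
  } else {
    positive <- vapply(seq_len(ncol(pr)), function(i)
      length(intersect(rx[[pr[1, i]]], rx[[pr[2, i]]])) > 0, TRUE)
  }
  if (!any(positive) || all(positive))
    stop("benchmark undefined: need both positive and negative pairs")
  scoreBenchmark(L, positive, targetFpr)
}

#' Calibrate a score threshold to a target FPR
#'
#' Builds the ROC, computes the trapezoid AUC, and selects theta as the
#' smallest score whose empirical FPR is at or below \code{targetFpr}
#' (when no finite threshold qualifies, theta sits just above the maximum
#' score and sensitivity is 0).
#'
#' @param L numeric scores.
#' @param positive logical truth labels (both classes must occur).
#' @param targetFpr FPR bound.
#' @return a \linkS4class{BenchmarkResult}.
#' @export
scoreBenchmark <- function(L, positive, targetFpr = 0.05) {
  roc <- rocFromScores(L, positive)
  auc <- trapezoidAuc(roc$fpr, roc$sensitivity)
  okRows <- which(roc$fpr <= targetFpr & is.finite(roc$threshold))
  if (length(okRows)) {
    sel <- okRows[which.min(roc$threshold[okRows])]
    theta <- roc$threshold[sel]
    achFpr <- roc$fpr[sel]; achSens <- roc$sensitivity[sel]
  } else {
    theta <- max(L) + max(.Machine$double.eps * abs(max(L)),
                          .Machine$double.eps)
    achFpr <- 0; achSens <- 0
  }
  new("BenchmarkResult", roc = roc, auc = auc, theta = theta,
      fpr = achFpr, sensitivity = achSens, targetFpr = targetFpr)
}

#' Transfer functional labels to unknown clusters by covariation
#'
#' Every (unknown, known) cluster pair with L at or above \code{theta} is
#' linked; the predicted function set of an unknown cluster is the union of
#' its linked known clusters' labels, inherited by every member gene.
#'
#' @param unknownProfiles,knownProfiles cluster x sample matrices.
#' @param knownLabels named list: known cluster_id -> function labels.
#' @param W a \linkS4class{SpatialWeights}.
#' @param theta L threshold (from \code{\link{benchmarkKnown}} or a config
#'   override; the package documents 0.885 as a reference operating point).
#' @param membership optional data.frame (cluster_id, gene_id) mapping
#'   unknown clusters to member genes for per-gene predictions.
#' @return list with \code{links} (data.table unknown, known, L),
#'   \code{predictions} (named list unknown cluster -> labels),
#'   \code{genePredictions} (data.table gene_id, labels) and
#'   \code{nAnnotatedGenes}.
#' @export
transferFunctions <- function(unknownProfiles, knownProfiles, knownLabels,
                              W, theta, membership = NULL) {
  if (!nrow(unknownProfiles) || !nrow(knownProfiles))
    return(list(links = data.table(unknown = character(),
                                   known = character(), L = numeric()),
                predictions = list(),
                genePredictions = data.table(gene_id = character(),
                                             labels = character()),
                nAnnotatedGenes = 0L))
  Lm <- leeLMatrix(unknownProfiles, W, Y = knownProfiles)
  hit <- which(Lm >= theta, arr.ind = TRUE)
  links <- data.table(
    unknown = rownames(unknownProfiles)[hit[, 1]],
    known = rownames(knownProfiles)[hit[, 2]],
    L = Lm[hit])
  setorder(links, unknown, -L)
  preds <- lapply(split(links$known, links$unknown), function(ks)
    sort(unique(unlist(knownLabels[ks]))))
  genePred <- data.table(gene_id = character(), labels = character())
  nGenes <- 0L
  if (!is.null(membership) && length(preds)) {
    mm <- membership[membership$cluster_id %in% names(preds), ,
                     drop = FALSE]
    if (nrow(mm)) {
      genePred <- data.table(
        gene_id = mm$gene_id,
        labels = vapply(preds[mm$cluster_id], paste, "", collapse = ";"))
      nGenes <- length(unique(mm$gene_id))
    }
  }
  list(links = links, predictions = preds, genePredictions = genePred,
       nAnnotatedGenes = nGenes)
}

#' Function-category enrichment in unknown-linked versus known clusters
#'
#' For each category a 2x2 table (category vs not) x (unknown-linked
#' clusters vs known clusters) is tested with a two-sided Fisher exact
#' test; p values are Benjamini-Hochberg adjusted across categories;
#' enriched means adjusted p below \code{alpha}.
#'
#' @param transfer result of \code{\link{transferFunctions}}.
#' @param knownClusterLabels named list: known cluster_id -> labels.
#' @param alpha adjusted-p cutoff (default 0.01).
#' @return data.frame per category: counts, odds ratio, p, adjusted p,
#'   enriched flag.
#' @export
enrichFunctions <- function(transfer, knownClusterLabels, alpha = 0.01) {
  unkSets <- transfer$predictions
  knSets <- knownClusterLabels
  nU <- length(unkSets); nK <- length(knSets)
  cats <- sort(unique(c(unlist(unkSets), unlist(knSets))))
  rows <- lapply(cats, function(cat) {
    a <- sum(vapply(unkSets, function(s) cat %in% s, TRUE))
    b <- sum(vapply(knSets, function(s) cat %in% s, TRUE))
    if (a + b == 0L) return(NULL)
    tab <- matrix(c(a, nU - a, b, nK - b), 2L)
    ft <- fisher.test(tab, alternative = "two.sided")
    data.frame(category = cat, n_unknown = a, n_known = b,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(category = character(), n_unknown = integer(),
                      n_known = integer(), odds_ratio = numeric(),
                      p = numeric(), p_adj = numeric(),
                      enriched = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj < alpha
  out[order(out$p_adj, out$category), ]
}
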