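# Pipeline configuration: one validated object holds every tunable the
# stages consume, so a run is reproducible from (config, input files) alone.

#' Assemble and validate a pipeline configuration
#'
#' All knobs of the pipeline in one object.  Defaults follow the package's
#' documented operating point: minimum merge overlap 1000 bp, overlap
#' identity 95 percent, maximum inner overhang 100 bp, DNA mapping with a
#' 2000 bp fragment cap, covariation threshold calibrated to FPR < 0.05
#' (with 0.885 available as a documented manual override), and the
#' three-site gut chain cecum > transverse_colon > feces in each individual.
#'
#' @param merge list: \code{mL} minimum overlap alignment length in bp,
#'   \code{c} minimum overlap percent identity, \code{hco} maximum inner
#'   overhang in bp, \code{containment_cov} aligned fraction above which a
#'   query scaffold is dropped as contained, \code{anchor_k} seeding k-mer.
#' @param mapper list: \code{k} seeding k-mer, \code{max_mismatch_rate}
#'   per-base mismatch budget, \code{max_fragment_len} properly-paired
#'   fragment cap in bp.
#' @param quant list: \code{count_mode} ("union"), \code{pseudodepth} added
#'   to DNA depth in the per-cell denominator.
#' @param covariation list: \code{target_fpr}, \code{L_threshold_override}
#'   (NA = calibrate from the benchmark), \code{cluster_identity},
#'   \code{cluster_coverage} for unknown-protein clustering.
#' @param simulation list: \code{seed}, \code{n_species},
#'   \code{genome_length}, \code{error_rate}.
#' @param sites named list mapping each individual to its ordered site
#'   chain (at least 2 sites each).
#' @return a validated list of class \code{PipelineConfig}.
#' @export
#' @examples
#' cfg <- pipelineConfig()
#' cfg$merge$mL
pipelineConfig <- function(
    merge = list(),
    mapper = list(),
    quant = list(),
    covariation = list(),
    simulation = list(),
    sites = NULL) {
  defaults <- list(
    merge = list(mL = 1000L, c = 95, hco = 100L, containment_cov = 0.90,
                 anchor_k = 21L),
    mapper = list(k = 31L, max_mismatch_rate = 0.05,
                  max_fragment_len = 2000L),
    quant = list(count_mode = "union", pseudodepth = 0),
    covariation = list(target_fpr = 0.05, L_threshold_override = NA_real_,
                       cluster_identity = 0.9, cluster_coverage = 0.85),
    simulation = list(seed = 0L, n_species = 6L, genome_length = 30000L,
                      error_rate = 0),
    sites = list(ind1 = c("cecum", "transverse_colon", "feces"),
                 ind2 = c("cecum", "transverse_colon", "feces")))
  cfg <- defaults
  cfg$merge[names(merge)] <- merge
  cfg$mapper[names(mapper)] <- mapper
  cfg$quant[names(quant)] <- quant
  cfg$covariation[names(covariation)] <- covariation
  cfg$simulation[names(simulation)] <- simulation
  if (!is.null(sites)) cfg$sites <- sites
  validatePipelineConfig(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

validatePipelineConfig <- function(cfg) {
  m <- cfg$merge
  if (m$mL < 1) stop("merge$mL must be >= 1")
  if (m$c <= 0 || m$c > 100) stop("merge$c must lie in (0, 100]")
  if (m$hco < 0) stop("merge$hco must be >= 0")
  if (m$containment_cov <= 0 || m$containment_cov > 1)
    stop("merge$containment_cov must lie in (0, 1]")
  mp <- cfg$mapper
  if (mp$max_mismatch_rate < 0 || mp$max_mismatch_rate > 1)
    stop("mapper$max_mismatch_rate must lie in [0, 1]")
  if (mp$max_fragment_len < 1) stop("mapper$max_fragment_len must be >= 1")
  cv <- cfg$covariation
  if (cv$target_fpr <= 0 || cv$target_fpr >= 1)
    stop("covariation$target_fpr must lie in (0, 1)")
  if (!cfg$quant$count_mode %in% c("union"))
    stop("quant$count_mode must be 'union'")
  if (!is.list(cfg$sites) || !length(cfg$sites))
    stop("sites must be a non-empty named list")
  if (any(vapply(cfg$sites, length, 1L) < 2))
    stop("each individual needs an ordered chain of >= 2 sites")
  invisible(TRUE)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig\n")
  cat(sprintf("  merge: mL=%d bp, c=%.0f%%, hco=%d bp, containment=%.2f\n",
              x$merge$mL, x$merge$c, x$merge$hco, x$merge$containment_cov))
  cat(sprintf("  mapper: k=%d, mismatch rate <= %.2f, fragment <= %d bp\n",
              x$mapper$k, x$mapper$max_mismatch_rate,
              x$mapper$max_fragment_len))
  cat(sprintf("  covariation: target FPR %.2f, override theta %s\n",
              x$covariation$target_fpr,
              ifelse(is.na(x$covariation$L_threshold_override), "none",
                     sprintf("%.3f", x$covariation$L_threshold_override))))
  for (ind in names(x$sites))
    cat(sprintf("  sites[%s]: %s\n", ind, paste(x$sites[[ind]],
                                                collapse = " > ")))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any subset of the \code{\link{pipelineConfig}} groups;
#' unset values keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  pipelineConfig(merge = y$merge %||% list(),
                 mapper = y$mapper %||% list(),
                 quant = y$quant %||% list(),
                 covariation = y$covariation %||% list(),
                 simulation = y$simulation %||% list(),
                 sites = y$sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
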