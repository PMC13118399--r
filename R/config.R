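#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis in one validated
#' object. Defaults follow common practice for amplicon co-occurrence
#' studies: edges require |Spearman rho| > 0.7 at a Benjamini-Hochberg
#' adjusted p < 0.05, genera enter the network when their mean relative
#' abundance exceeds 0.1%, modules are "major" when they hold more than
#' 10% of the network's nodes, and keystone genera are the most abundant
#' members accounting for more than 75% of a keystone module's abundance.
#'
#' @param cor_threshold absolute Spearman correlation an edge must exceed.
#' @param edge_alpha significance level for (adjusted) edge p-values.
#' @param dominant_cutoff mean relative-abundance fraction a genus must
#'   strictly exceed to count as dominant (default 0.001 = 0.1%).
#' @param major_fraction fraction of network nodes a module must strictly
#'   exceed to count as major (default 0.10).
#' @param keystone_fraction cumulative share of module abundance the
#'   keystone-genus prefix must exceed (default 0.75).
#' @param alpha significance level for ANOVA/Duncan and keystone-module
#'   correlations.
#' @param n_perm permutations for PERMANOVA (>= 99).
#' @param rf_trees trees per random-forest ensemble.
#' @param rf_perm response permutations for importance p-values (>= 99).
#' @param walk_steps random-walk length for walktrap module detection.
#' @param seed integer seed recorded in all outputs and expanded into
#'   per-stage substreams.
#' @param scheme a [size_class_scheme()] describing the sieving fractions.
#'
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(cor_threshold = 0.7,
                       edge_alpha = 0.05,
                       dominant_cutoff = 0.001,
                       major_fraction = 0.10,
                       keystone_fraction = 0.75,
                       alpha = 0.05,
                       n_perm = 999,
                       rf_trees = 500,
                       rf_perm = 999,
                       walk_steps = 4,
                       seed = 1L,
                       scheme = size_class_scheme()) {
  cfg <- list(cor_threshold = cor_threshold, edge_alpha = edge_alpha,
              dominant_cutoff = dominant_cutoff,
              major_fraction = major_fraction,
              keystone_fraction = keystone_fraction, alpha = alpha,
              n_perm = as.integer(n_perm), rf_trees = as.integer(rf_trees),
              rf_perm = as.integer(rf_perm),
              walk_steps = as.integer(walk_steps), seed = as.integer(seed),
              scheme = scheme)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 && x <= 1
  if (!in01(cfg$cor_threshold)) stopf("cor_threshold must lie in (0, 1]")
  if (!in01(cfg$edge_alpha)) stopf("edge_alpha must lie in (0, 1]")
  if (!in01(cfg$dominant_cutoff)) stopf("dominant_cutoff must lie in (0, 1]")
  if (!in01(cfg$major_fraction)) stopf("major_fraction must lie in (0, 1]")
  if (!in01(cfg$keystone_fraction)) stopf("keystone_fraction must lie in (0, 1]")
  if (!in01(cfg$alpha)) stopf("alpha must lie in (0, 1]")
  if (cfg$n_perm < 99L) stopf("n_perm must be >= 99")
  if (cfg$rf_perm < 99L) stopf("rf_perm must be >= 99")
  if (cfg$rf_trees < 1L) stopf("rf_trees must be positive")
  if (cfg$walk_steps < 1L) stopf("walk_steps must be positive")
  if (is.na(cfg$seed)) stopf("seed must be an integer")
  stopifnot(inherits(cfg$scheme, "size_class_scheme"))
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Flat keys matching the arguments of [run_config()]; missing keys take
#' the defaults. The scheme may be given as `scheme: {lower: ..., upper:
#' ..., mid: ...}`.
#'
#' @param path YAML file path.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scheme)) {
    y$scheme <- size_class_scheme(lower = unlist(y$scheme$lower),
                                  upper = unlist(y$scheme$upper),
                                  mid = unlist(y$scheme$mid))
  }
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  cat("aggrekey run configuration\n")
  cat(sprintf("  edge rule: |rho| > %.2f, BH-adjusted p < %.2f\n",
              x$cor_threshold, x$edge_alpha))
  cat(sprintf("  dominant genus cutoff: %.3f%% mean relative abundance\n",
              100 * x$dominant_cutoff))
  cat(sprintf("  major module rule: > %.0f%% of network nodes\n",
              100 * x$major_fraction))
  cat(sprintf("  keystone genus prefix: > %.0f%% of module abundance\n",
              100 * x$keystone_fraction))
  cat(sprintf("  alpha = %.2f, PERMANOVA perms = %d, RF trees = %d, RF perms = %d\n",
              x$alpha, x$n_perm, x$rf_trees, x$rf_perm))
  cat(sprintf("  walktrap steps = %d, seed = %d\n", x$walk_steps, x$seed))
  invisible(x)
}

# stable hash of a config (seed included) stamped into every output
config_hash <- function(cfg) {
  flat <- cfg
  flat$scheme <- unclass(flat$scheme)
  object_hash(flat)
}
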