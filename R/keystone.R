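#' Identify keystone modules
#'
#' Correlates each major module's per-sample abundance with the C
#' proportion in each aggregate size class (Spearman). A major module is
#' keystone when it is significantly correlated with at least one
#' response at `alpha`.
#'
#' @param network a network with detected modules and major flags.
#' @param mab output of [module_abundance()].
#' @param responses matrix of per-sample responses (samples x responses),
#'   typically the four columns of [c_distribution()]; rownames are
#'   sample ids matching the abundance columns.
#' @param alpha significance level (default from config).
#' @return Data frame of class `"keystone_modules"`: one row per major
#'   module and per response with `rho`, `p`, plus a `keystone` flag.
#' @export
keystone_modules <- function(network, mab, responses, alpha = NULL) {
  stopifnot(inherits(network, "cooc_network"))
  if (is.null(network$modules$major)) stopf("run major_modules() first")
  alpha <- alpha %||% network$config$alpha
  responses <- as.matrix(responses)
  if (!identical(rownames(responses), colnames(mab$raw))) {
    stopf("samples misaligned between module profiles and responses")
  }
  majors <- network$modules$module[network$modules$major]
  if (!length(majors)) stopf("no major modules to test")
  rows <- list()
  for (m in majors) {
    for (r in colnames(responses)) {
      ct <- spearman_cor(mab$raw[m, ], responses[, r])
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, response = r, rho = ct$rho, p = ct$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  sig <- tapply(out$p < alpha, out$module, any)
  out$keystone <- unname(sig[out$module])
  class(out) <- c("keystone_modules", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Select keystone genera within a module
#'
#' Ranks the module's genera by mean relative abundance, takes the
#' smallest prefix whose cumulative share of the module's total abundance
#' strictly exceeds `fraction` (the genus crossing the boundary is
#' included), and keeps those prefix genera whose abundance differs
#' significantly between treatments (protected Duncan: not all
#' treatments share one letter).
#'
#' @param genera character vector: the module's member genus ids.
#' @param abundance relative-abundance matrix (genera x samples) covering
#'   the members, e.g. the network's pooled `abundance`.
#' @param design a [study_design()] aligned with the abundance columns.
#' @param fraction cumulative-abundance threshold (default 0.75).
#' @param alpha Duncan significance level.
#' @return Data frame: `genus`, `mean_abundance`, `cum_share`,
#'   `in_prefix`, `significant`, `keystone` (prefix AND significant),
#'   ordered by descending mean abundance.
#' @export
keystone_genera <- function(genera, abundance, design, fraction = 0.75,
                            alpha = 0.05) {
  if (!length(genera)) stopf("empty module")
  miss <- setdiff(genera, rownames(abundance))
  if (length(miss)) stopf("genera missing from abundance matrix: %s",
                          paste(miss, collapse = ", "))
  sub <- abundance[genera, design$sample_id, drop = FALSE]
  mu <- rowMeans(sub)
  ord <- order(-mu, names(mu))
  mu <- mu[ord]
  cum <- cumsum(mu) / sum(mu)
  k <- which(cum > fraction)[1]
  in_prefix <- seq_along(mu) <= k
  sig <- vapply(names(mu), function(g) {
    lt <- tryCatch(anova_duncan(sub[g, ], design, alpha = alpha),
                   error = function(e) NULL)
    !is.null(lt) && length(unique(lt$letters)) > 1
  }, logical(1))
  out <- data.frame(genus = names(mu), mean_abundance = unname(mu),
                    cum_share = unname(cum), in_prefix = in_prefix,
                    significant = unname(sig),
                    keystone = in_prefix & unname(sig),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Permutation-importance ranking of genera for one response
#'
#' Bagged regression trees (random forest) of the response on candidate
#' genus abundances. Importance is the mean increase in out-of-bag MSE
#' when a predictor is permuted, expressed as a percentage of the
#' response variance. Importance p-values come from refitting after
#' permuting the response `n_perm` times (per-genus null distributions);
#' variance explained is `1 - OOB MSE / Var(response)`.
#'
#' @param genera candidate genus ids (>= 2).
#' @param abundance relative-abundance matrix (genera x samples).
#' @param response numeric per-sample response aligned with the columns.
#' @param n_trees ensemble size.
#' @param n_perm response permutations for the null.
#' @param seed integer seed.
#' @return List with `importance` (data frame: genus, importance_pct, p,
#'   rank) and `var_explained` (fraction).
#' @export
importance_ranking <- function(genera, abundance, response, n_trees = 500,
                               n_perm = 999, seed = 1L) {
  if (length(genera) < 2) stopf("need at least 2 candidate genera")
  if (length(response) != ncol(abundance)) {
    stopf("response length does not match sample count")
  }
  if (length(response) < 10) stopf("need at least 10 samples")
  check_numeric_finite(response, "response")
  if (stats::sd(response) == 0) stopf("constant response")
  x <- t(abundance[genera, , drop = FALSE])
  vy <- stats::var(response)
  raw_importance <- function(y, sd) {
    rf <- with_seed(sd, randomForest::randomForest(
      x = x, y = y, ntree = n_trees, importance = TRUE))
    list(imp = randomForest::importance(rf, type = 1, scale = FALSE)[, 1],
         mse = rf$mse[n_trees])
  }
  obs <- raw_importance(response, seed)
  null <- matrix(NA_real_, n_perm, length(genera),
                 dimnames = list(NULL, genera))
  perm_y <- with_seed(stage_seed(seed, "rf_null"),
                      replicate(n_perm, sample(response), simplify = FALSE))
  for (b in seq_len(n_perm)) {
    null[b, ] <- raw_importance(perm_y[[b]], seed + b)$imp
  }
  p <- vapply(genera, function(g) {
    (1 + sum(null[, g] >= obs$imp[g])) / (1 + n_perm)
  }, numeric(1))
  imp_pct <- 100 * obs$imp / vy
  ord <- order(-imp_pct, genera)
  out <- data.frame(genus = genera[ord], importance_pct = unname(imp_pct[ord]),
                    p = unname(p[ord]), rank = seq_along(genera),
                    stringsAsFactors = FALSE)
  list(importance = out, var_explained = 1 - obs$mse / vy)
}

#' Crucial genera across the four C-proportion responses
#'
#' @param rankings named list (one element per response) of
#'   [importance_ranking()] results.
#' @param alpha importance p-value threshold.
#' @return List with `union` (character vector of genera significant for
#'   at least one response) and `membership` (data frame genus x
#'   response with importance and p for the significant pairs).
#' @export
crucial_genera <- function(rankings, alpha = 0.05) {
  rows <- list()
  for (r in names(rankings)) {
    imp <- rankings[[r]]$importance
    sig <- imp[imp$p < alpha, , drop = FALSE]
    if (nrow(sig)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genus = sig$genus, response = r,
        importance_pct = sig$importance_pct, p = sig$p,
        stringsAsFactors = FALSE)
    }
  }
  membership <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genus = character(0), response = character(0),
               importance_pct = numeric(0), p = numeric(0))
  u <- unique(membership$genus)
  if (!length(u)) warning("no genus reached significant importance for any response")
  list(union = u, membership = membership)
}
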