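#' Build the combined multi-kingdom co-occurrence network
#'
#' Pools the dominant genera of the bacterial, non-AMF and AMF tables
#' (each on its own compositional scale) into one node set, computes all
#' pairwise Spearman correlations within and across kingdoms, adjusts the
#' p-values by Benjamini-Hochberg over the complete pair set jointly, and
#' keeps edges with `|rho| > cor_threshold` and adjusted
#' `p < edge_alpha`. Isolated nodes are dropped from the graph; negative
#' edges are retained (with `|rho|` used later as the walk weight).
#'
#' @param tables list of relative [abundance_table()]s sharing one sample
#'   set; apply [dominant_genera()] filtering beforehand (or pass
#'   `dominant = TRUE` to apply it here).
#' @param config a [run_config()].
#' @param dominant apply the dominant-genus filter to each table first.
#' @return A list of class `"cooc_network"` with `nodes` (genus,
#'   kingdom), `edges` (source, target, rho, p, p_adj, sign),
#'   `n_samples`, `n_tested` and the pooled abundance matrix of the
#'   network's genera.
#' @export
build_network <- function(tables, config = run_config(), dominant = FALSE) {
  stopifnot(all(vapply(tables, inherits, logical(1), "abundance_table")))
  samples <- colnames(tables[[1]]$mat)
  for (tb in tables) {
    if (!identical(colnames(tb$mat), samples)) {
      stopf("all tables must share an identical sample set and order")
    }
    if (tb$type != "relative") stopf("network construction needs relative tables")
  }
  if (length(samples) < 4) stopf("need at least 4 samples for correlations")
  if (dominant) {
    tables <- lapply(tables, function(tb) {
      keep <- dominant_genera(tb, config$dominant_cutoff)
      tb$mat <- tb$mat[keep, , drop = FALSE]
      tb
    })
  }
  pooled <- do.call(rbind, lapply(tables, function(tb) tb$mat))
  kingdom <- unlist(lapply(tables, function(tb) rep(tb$kingdom, nrow(tb$mat))))
  names(kingdom) <- rownames(pooled)
  if (anyDuplicated(rownames(pooled))) stopf("duplicate genus ids after pooling")
  const <- apply(pooled, 1, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant genera before correlation", sum(const)))
    pooled <- pooled[!const, , drop = FALSE]
    kingdom <- kingdom[!const]
  }
  n <- length(samples)
  rho <- stats::cor(t(pooled), method = "spearman")
  ut <- upper.tri(rho)
  rv <- rho[ut]
  pv <- vapply(rv, spearman_p_approx, numeric(1), n = n)
  padj <- bh_adjust(pv)
  idx <- which(ut, arr.ind = TRUE)
  keep <- abs(rv) > config$cor_threshold & padj < config$edge_alpha
  edges <- data.frame(
    source = rownames(pooled)[idx[keep, 1]],
    target = rownames(pooled)[idx[keep, 2]],
    rho = rv[keep], p = pv[keep], p_adj = padj[keep],
    sign = ifelse(rv[keep] >= 0, "+", "-"),
    stringsAsFactors = FALSE)
  connected <- unique(c(edges$source, edges$target))
  nodes <- data.frame(genus = connected,
                      kingdom = unname(kingdom[connected]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n_samples = n,
                 n_tested = length(rv),
                 abundance = pooled[connected, , drop = FALSE],
                 config = config),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (of %d pairs tested) over %d samples\n",
              nrow(x$nodes), nrow(x$edges), x$n_tested, x$n_samples))
  if (!is.null(x$nodes$module)) {
    sz <- sort(table(x$nodes$module), decreasing = TRUE)
    cat("  modules:", paste(sprintf("%s(%d)", names(sz), sz), collapse = " "), "\n")
  }
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "rho")],
    directed = FALSE, vertices = network$nodes$genus)
}

#' Detect network modules by random-walk clustering
#'
#' Walktrap community detection (`igraph::cluster_walktrap`) on the
#' co-occurrence graph, using `|rho|` as edge weight so that negative
#' associations contribute their strength. The dendrogram is cut at
#' maximum modularity. Modules are relabelled by descending size with
#' Roman numerals (I, II, ...); ties broken by the smallest member name
#' for deterministic labels.
#'
#' @param network a [build_network()] result.
#' @param walk_steps random-walk length (default from the network's
#'   config, normally 4).
#' @return The network with a `module` column added to `nodes` and a
#'   `modules` summary data frame (`module`, `size`, `major` placeholder).
#' @export
detect_modules <- function(network, walk_steps = NULL) {
  stopifnot(inherits(network, "cooc_network"))
  if (nrow(network$edges) == 0) stopf("cannot detect modules in an empty edge set")
  walk_steps <- walk_steps %||% network$config$walk_steps
  g <- as_igraph(network)
  wt <- igraph::cluster_walktrap(g, weights = abs(igraph::E(g)$rho),
                                 steps = walk_steps)
  memb <- igraph::membership(wt)
  memb <- memb[network$nodes$genus]
  sizes <- table(memb)
  first_member <- tapply(network$nodes$genus, memb, min)
  ord <- order(-as.numeric(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  rank_id <- relabel[as.character(memb)]
  network$nodes$module <- roman_label(rank_id)
  network$modules <- data.frame(
    module = roman_label(seq_along(ord)),
    size = as.integer(sizes[ord]),
    stringsAsFactors = FALSE)
  network$modularity <- igraph::modularity(g, memb,
                                           weights = abs(igraph::E(g)$rho))
  network
}

#' Flag major modules
#'
#' A module is major when its node count strictly exceeds
#' `node_fraction` of the network's (non-isolated) node total.
#'
#' @param network a network with detected modules.
#' @param node_fraction threshold fraction (default from config, 0.10).
#' @return The network with a logical `major` column on `modules`.
#' @export
major_modules <- function(network, node_fraction = NULL) {
  stopifnot(inherits(network, "cooc_network"))
  if (is.null(network$modules)) stopf("run detect_modules() first")
  node_fraction <- node_fraction %||% network$config$major_fraction
  total <- nrow(network$nodes)
  network$modules$major <- network$modules$size > node_fraction * total
  if (!any(network$modules$major)) {
    warning("no module exceeds the major-module size threshold")
  }
  network
}

#' Per-sample module abundance profiles
#'
#' For each module, sums the member genera's relative abundances per
#' sample (each kingdom on its own compositional scale) and z-scores the
#' resulting vector across samples.
#'
#' @param network a network with detected modules.
#' @param modules which modules to profile (default: all).
#' @return List with `raw` and `z` matrices (modules x samples).
#' @export
module_abundance <- function(network, modules = NULL) {
  stopifnot(inherits(network, "cooc_network"))
  if (is.null(network$nodes$module)) stopf("run detect_modules() first")
  modules <- modules %||% network$modules$module
  miss <- setdiff(modules, network$nodes$module)
  if (length(miss)) stopf("module(s) with no members: %s",
                          paste(miss, collapse = ", "))
  raw <- t(vapply(modules, function(m) {
    members <- network$nodes$genus[network$nodes$module == m]
    colSums(network$abundance[members, , drop = FALSE])
  }, numeric(ncol(network$abundance))))
  rownames(raw) <- modules
  z <- t(scale(t(raw)))
  list(raw = raw, z = z)
}
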