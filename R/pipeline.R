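#' Default inner path model linking microbes to aggregate stability
#'
#' Latents: crucial-genera PC1 (single observed indicator), aggregate
#' mass distribution (4 indicators), per-fraction SOC concentration
#' (4 indicators), aggregate-associated C distribution (4 indicators)
#' and MWD (single indicator). Directed paths: microbes feed mass
#' distribution, SOC concentration and C distribution; mass and SOC
#' feed C distribution; mass, SOC and C distribution feed MWD.
#'
#' @return List with `blocks` (indicator names per latent) and `inner`
#'   (adjacency matrix for [fit_plspm()]).
#' @export
default_path_model <- function() {
  cls <- class_codes()
  blocks <- list(
    microbes = "pc1",
    mass_distribution = paste0("massprop_", cls),
    soc_concentration = paste0("socconc_", cls),
    c_distribution = paste0("cdist_", cls),
    mwd = "mwd")
  lat <- names(blocks)
  inner <- matrix(0, 5, 5, dimnames = list(lat, lat))
  inner["mass_distribution", "microbes"] <- 1
  inner["soc_concentration", "microbes"] <- 1
  inner["c_distribution", c("microbes", "mass_distribution",
                            "soc_concentration")] <- 1
  inner["mwd", c("mass_distribution", "soc_concentration",
                 "c_distribution")] <- 1
  list(blocks = blocks, inner = inner)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: aggregate metrics and Duncan letters; per-kingdom
#' ordination (Bray-Curtis PCoA + PERMANOVA); the combined co-occurrence
#' network with walktrap modules and the major-module flag; keystone
#' modules against the four C-distribution responses; keystone genera;
#' permutation-importance ranking per response and the crucial-genus
#' union; PC1 scores; and the PLS path model to MWD. All randomness
#' derives from `config$seed` through fixed per-stage substreams.
#'
#' @param tables named list of the three counts (or relative)
#'   [abundance_table()]s (`bacteria`, `non_amf`, `amf`).
#' @param profiles an [aggregate_profiles()] data frame.
#' @param design a [study_design()].
#' @param config a [run_config()].
#' @param taxonomy optional genus -> phylum map; when given, Glomeromycota
#'   genera are removed from the non-AMF table first.
#' @param rarefy rarefy counts tables to their per-marker minimum depth.
#' @param out_dir optional directory; when given, [write_results()] is
#'   called on the bundle.
#' @return A result bundle (list) of class `"aggrekey_result"`.
#' @export
run_pipeline <- function(tables, profiles, design, config = run_config(),
                         taxonomy = NULL, rarefy = TRUE, out_dir = NULL) {
  validate_run_config(config)
  check_replication(design)
  stage <- "aggregate_metrics"
  bundle <- tryCatch({
    metrics <- aggregate_metrics(profiles, config$scheme)
    summary_tab <- treatment_summary(metrics, design)

    stage <- "group_stats"
    metric_cols <- setdiff(names(metrics), "sample_id")
    letters_tab <- do.call(rbind, lapply(metric_cols, function(mc) {
      lt <- anova_duncan(metrics[[mc]], design, alpha = config$alpha)
      data.frame(metric = mc, as.data.frame(lt), stringsAsFactors = FALSE)
    }))

    stage <- "community_ecology"
    if (!is.null(taxonomy) && "non_amf" %in% names(tables)) {
      tables$non_amf <- remove_amf_from_its(tables$non_amf, taxonomy)
    }
    rel <- lapply(names(tables), function(kd) {
      tb <- tables[[kd]]
      if (tb$type == "counts" && rarefy) {
        tb <- rarefy_counts(tb, "min",
                            seed = stage_seed(config$seed, paste0("rarefy_", kd)))
      }
      relative_abundance(tb)
    })
    names(rel) <- names(tables)
    ordination <- lapply(names(rel), function(kd) {
      d <- bray_curtis(rel[[kd]])
      list(kingdom = kd, pcoa = pcoa_ord(d),
           permanova = permanova_test(
             d, design, n_perm = config$n_perm,
             seed = stage_seed(config$seed, paste0("permanova_", kd))))
    })
    names(ordination) <- names(rel)

    stage <- "cooccurrence_network"
    network <- build_network(rel, config, dominant = TRUE)
    network <- detect_modules(network)
    network <- major_modules(network)
    mab <- module_abundance(network)

    stage <- "keystone_selection"
    responses <- as.matrix(metrics[, paste0("cdist_", class_codes())])
    rownames(responses) <- metrics$sample_id
    km <- keystone_modules(network, mab, responses, alpha = config$alpha)
    keystone_mods <- unique(km$module[km$keystone])
    kg <- lapply(keystone_mods, function(m) {
      members <- network$nodes$genus[network$nodes$module == m]
      data.frame(module = m,
                 keystone_genera(members, network$abundance, design,
                                 fraction = config$keystone_fraction,
                                 alpha = config$alpha),
                 stringsAsFactors = FALSE)
    })
    kg <- if (length(kg)) do.call(rbind, kg) else NULL
    candidates <- unique(kg$genus[kg$keystone])
    rankings <- NULL
    crucial <- list(union = character(0), membership = NULL)
    if (length(candidates) >= 2) {
      rankings <- lapply(colnames(responses), function(r) {
        importance_ranking(candidates, network$abundance, responses[, r],
                           n_trees = config$rf_trees, n_perm = config$rf_perm,
                           seed = stage_seed(config$seed, paste0("rf_", r)))
      })
      names(rankings) <- colnames(responses)
      crucial <- crucial_genera(rankings, alpha = config$alpha)
    }

    stage <- "plspm"
    plspm <- NULL; pc1 <- NULL
    if (length(crucial$union) >= 2) {
      pc1 <- pc1_scores(network$abundance, crucial$union)
      pm <- default_path_model()
      dat <- data.frame(pc1 = pc1$scores[metrics$sample_id],
                        metrics[, unlist(pm$blocks)[-1]],
                        check.names = FALSE)
      plspm <- fit_plspm(dat, pm$blocks, pm$inner)
    }

    list(design = design, config = config, metrics = metrics,
         summary = summary_tab, letters = letters_tab,
         ordination = ordination, network = network,
         module_abundance = mab, keystone_modules = km,
         keystone_genera = kg, rankings = rankings, crucial = crucial,
         pc1 = pc1, plspm = plspm)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  class(bundle) <- "aggrekey_result"
  if (!is.null(out_dir)) write_results(out_dir, bundle)
  bundle
}

#' Aggregate-only analysis (no microbiome tables)
#'
#' Computes the aggregate metrics, Duncan letters, treatment summary and
#' the standard group contrasts from aggregate data alone.
#'
#' @param profiles an [aggregate_profiles()] data frame (or TSV path).
#' @param design a [study_design()] (or TSV path).
#' @param config a [run_config()].
#' @param groups named list of treatment sets for contrasts (default:
#'   the reference trial's Group1/Group2).
#' @return List with `metrics`, `summary`, `letters` and `contrasts`.
#' @export
run_tables_only <- function(profiles, design, config = run_config(),
                            groups = study_reference()$groups) {
  if (is.character(design)) design <- read_design(design)
  if (is.character(profiles)) profiles <- read_aggregate_profiles(profiles, design)
  if (nrow(design) == 0) stopf("empty design")
  check_replication(design)
  metrics <- aggregate_metrics(profiles, config$scheme)
  summary_tab <- treatment_summary(metrics, design)
  metric_cols <- setdiff(names(metrics), "sample_id")
  letters_tab <- do.call(rbind, lapply(metric_cols, function(mc) {
    lt <- anova_duncan(metrics[[mc]], design, alpha = config$alpha)
    data.frame(metric = mc, as.data.frame(lt), stringsAsFactors = FALSE)
  }))
  contrasts <- NULL
  if (all(unlist(groups) %in% design$treatment)) {
    pairs <- list(
      c("Group1", "Group2", "massprop_gt2"),
      c("Group1", "Group2", "r025_mass"),
      c("Group1", "Group2", "r025_soc"))
    contrasts <- do.call(rbind, lapply(pairs, function(p) {
      ct <- treatment_contrast(metrics, design, groups[[p[1]]],
                               groups[[p[2]]], p[3])
      data.frame(set_a = p[1], set_b = p[2], metric = p[3],
                 contrast_pct = ct$contrast, sd_pct = ct$sd,
                 stringsAsFactors = FALSE)
    }))
  }
  list(metrics = metrics, summary = summary_tab, letters = letters_tab,
       contrasts = contrasts)
}

#' @export
print.aggrekey_result <- function(x, ...) {
  cat("aggrekey pipeline result\n")
  cat(sprintf("  %d samples, %d treatments\n", nrow(x$design),
              length(unique(x$design$treatment))))
  print(x$network)
  if (!is.null(x$keystone_modules)) {
    ks <- unique(x$keystone_modules$module[x$keystone_modules$keystone])
    cat("  keystone modules:", if (length(ks)) paste(ks, collapse = ", ")
        else "none", "\n")
  }
  cat("  crucial genera:", if (length(x$crucial$union))
      paste(x$crucial$union, collapse = ", ") else "none", "\n")
  if (!is.null(x$plspm)) cat(sprintf("  PLS-PM GOF = %.3f\n", x$plspm$gof))
  invisible(x)
}
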