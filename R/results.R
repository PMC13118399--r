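#' Write a pipeline result bundle to disk
#'
#' Deterministic file set: `aggregate_metrics.tsv`, `summary.tsv`,
#' `anova_letters.tsv`, `network_edges.tsv`, `modules.tsv`,
#' `keystone.tsv`, `crucial_genera.tsv`, `plspm.json`, `run_log.txt`
#' (config + seed + config hash) and `manifest.json` with md5 checksums
#' of every written file. Two runs with identical inputs, config and
#' seed produce byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param bundle an `"aggrekey_result"` from [run_pipeline()].
#' @return Named character vector of written file paths, invisibly.
#' @export
write_results <- function(dir, bundle) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", dir)
  }
  if (file.access(dir, 2) != 0) stopf("output directory '%s' is not writable", dir)
  if (!is.null(bundle$plspm) && anyNA(bundle$plspm$path_coefficients)) {
    stopf("model not converged: NaN path coefficient in bundle")
  }
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  files <- c(
    aggregate_metrics = tsv(bundle$metrics, "aggregate_metrics.tsv"),
    summary = tsv(bundle$summary, "summary.tsv"),
    anova_letters = tsv(bundle$letters, "anova_letters.tsv"))
  if (!is.null(bundle$network)) {
    files["network_edges"] <- tsv(bundle$network$edges, "network_edges.tsv")
    nodes <- bundle$network$nodes
    if (!is.null(bundle$network$modules)) {
      nodes$major <- bundle$network$modules$major[
        match(nodes$module, bundle$network$modules$module)]
    }
    files["modules"] <- tsv(nodes, "modules.tsv")
  }
  ks <- bundle$keystone_modules
  if (is.null(ks)) {
    ks <- data.frame(module = character(0), response = character(0),
                     rho = numeric(0), p = numeric(0),
                     keystone = logical(0))
  }
  files["keystone"] <- tsv(as.data.frame(ks), "keystone.tsv")
  cg <- bundle$crucial$membership
  if (is.null(cg) || !nrow(cg)) {
    cg <- data.frame(genus = character(0), response = character(0),
                     importance_pct = numeric(0), p = numeric(0))
  }
  files["crucial_genera"] <- tsv(cg, "crucial_genera.tsv")
  if (!is.null(bundle$plspm)) {
    pm <- bundle$plspm
    path <- file.path(dir, "plspm.json")
    jsonlite::write_json(list(
      blocks = pm$blocks,
      path_coefficients = as.data.frame(pm$path_coefficients),
      r_squared = as.list(pm$r_squared),
      effects = pm$effects, gof = pm$gof,
      pc1_var_explained = bundle$pc1$var_explained),
      path, auto_unbox = TRUE, digits = NA, na = "null")
    files["plspm"] <- path
  }
  cfg <- bundle$config
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(
    "aggrekey run log",
    paste0("config_hash: ", config_hash(cfg)),
    paste0("seed: ", cfg$seed),
    utils::capture.output(print(cfg))), log_path)
  files["run_log"] <- log_path
  manifest <- list(
    config_hash = unname(config_hash(cfg)),
    seed = cfg$seed,
    files = lapply(stats::setNames(as.list(files), names(files)),
                   function(f) list(name = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["manifest"] <- file.path(dir, "manifest.json")
  invisible(files)
}
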