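#' Per-sample aggregate profiles
#'
#' One row per sample: oven-dry mass (g) of each of the four wet-sieved
#' size classes, SOC concentration (g C kg^-1 fraction) of each class,
#' and the bulk-soil SOC concentration (g kg^-1).
#'
#' @param df data frame with columns `sample_id`, `mass_gt2`,
#'   `mass_m025_2`, `mass_m0053_025`, `mass_lt0053`, `soc_gt2`,
#'   `soc_m025_2`, `soc_m0053_025`, `soc_lt0053`, `bulk_soc`.
#' @return A data frame of class `"aggregate_profiles"`.
#' @export
aggregate_profiles <- function(df) {
  need <- profile_columns()
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing profile column(s): %s",
                          paste(miss, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in profiles")
  num <- df[, setdiff(need, "sample_id")]
  check_numeric_finite(as.matrix(num), "aggregate profile values")
  mass <- as.matrix(df[, paste0("mass_", class_codes())])
  if (any(mass < 0)) stopf("negative fraction mass")
  if (any(rowSums(mass) <= 0)) stopf("all-zero fraction masses for sample(s): %s",
    paste(df$sample_id[rowSums(mass) <= 0], collapse = ", "))
  soc <- as.matrix(df[, paste0("soc_", class_codes())])
  if (any(soc < 0)) stopf("negative SOC concentration")
  class(df) <- c("aggregate_profiles", "data.frame")
  df
}

profile_columns <- function() {
  c("sample_id", paste0("mass_", class_codes()),
    paste0("soc_", class_codes()), "bulk_soc")
}

#' Read per-sample aggregate profiles from TSV
#'
#' @param path TSV with the columns of [aggregate_profiles()].
#' @param design optional [study_design()] the samples must match.
#' @return An `"aggregate_profiles"` data frame.
#' @export
read_aggregate_profiles <- function(path, design = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- aggregate_profiles(df)
  if (!is.null(design)) {
    missing <- setdiff(design$sample_id, out$sample_id)
    extra <- setdiff(out$sample_id, design$sample_id)
    if (length(missing) || length(extra)) {
      stopf("sample mismatch vs design; missing: [%s]; unexpected: [%s]",
            paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
    out <- out[match(design$sample_id, out$sample_id), ]
    rownames(out) <- NULL
    class(out) <- c("aggregate_profiles", "data.frame")
  }
  out
}

#' Write aggregate profiles as TSV (round-trip safe)
#'
#' @param profiles an `"aggregate_profiles"` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_aggregate_profiles <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
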