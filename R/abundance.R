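#' Genus x sample abundance table with kingdom tags
#'
#' The three marker sets (16S bacteria, ITS non-AMF fungi, 18S AMF) each
#' yield one genus-level table. Genus ids are prefixed by kingdom
#' (`B_`, `F_`, `AMF_`) so that names stay unique when the three tables
#' are pooled into one co-occurrence network.
#'
#' @param mat non-negative numeric matrix, genera in rows, samples in
#'   columns, both dimnames set.
#' @param kingdom one of `"bacteria"`, `"non_amf"`, `"amf"`.
#' @param type `"counts"` or `"relative"`.
#' @param prefix prefix genus ids by kingdom if not already prefixed.
#'
#' @return A list of class `"abundance_table"` with elements `mat`,
#'   `kingdom` and `type`.
#' @export
abundance_table <- function(mat, kingdom = c("bacteria", "non_amf", "amf"),
                            type = c("counts", "relative"), prefix = TRUE) {
  kingdom <- match.arg(kingdom)
  type <- match.arg(type)
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("mat must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stopf("mat must have genus rownames and sample colnames")
  }
  check_numeric_finite(mat, "abundance matrix")
  if (any(mat < 0)) stopf("negative abundance")
  bad <- !grepl("^[A-Za-z0-9_.-]+$", rownames(mat))
  if (any(bad)) {
    stopf("invalid genus ids: %s", paste(rownames(mat)[bad], collapse = ", "))
  }
  pf <- kingdom_prefix(kingdom)
  if (prefix) {
    need <- !startsWith(rownames(mat), pf)
    rownames(mat)[need] <- paste0(pf, rownames(mat)[need])
  }
  if (anyDuplicated(rownames(mat))) stopf("duplicate genus id within kingdom")
  if (type == "relative") {
    cs <- colSums(mat)
    if (any(abs(cs - 1) > 1e-9 & cs > 0)) {
      stopf("relative table columns must sum to 1")
    }
  }
  structure(list(mat = mat, kingdom = kingdom, type = type),
            class = "abundance_table")
}

kingdom_prefix <- function(kingdom) {
  c(bacteria = "B_", non_amf = "F_", amf = "AMF_")[[kingdom]]
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d %s genera x %d samples (%s)\n",
              nrow(x$mat), x$kingdom, ncol(x$mat), x$type))
  invisible(x)
}

#' Read a genus abundance table from TSV
#'
#' Expects a tab-separated matrix: first column genus identifiers, header
#' row of sample ids, non-negative numeric cells. Genus ids are prefixed
#' by kingdom on read.
#'
#' @param path file path.
#' @param kingdom one of `"bacteria"`, `"non_amf"`, `"amf"`.
#' @param design optional [study_design()]; when given, the table's
#'   samples must cover the design exactly.
#' @param type `"counts"` (default) or `"relative"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, kingdom, design = NULL,
                                 type = "counts") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stopf("abundance table needs a genus column plus samples")
  genus <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genus
  if (anyNA(mat)) stopf("abundance table contains non-numeric or missing cells")
  if (any(mat < 0)) stopf("negative abundance")
  if (!is.null(design)) {
    missing <- setdiff(design$sample_id, colnames(mat))
    extra <- setdiff(colnames(mat), design$sample_id)
    if (length(missing) || length(extra)) {
      stopf("sample mismatch vs design; missing: [%s]; unexpected: [%s]",
            paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
    mat <- mat[, design$sample_id, drop = FALSE]
  }
  abundance_table(mat, kingdom = kingdom, type = type)
}

#' Write an abundance table as TSV (round-trip safe)
#'
#' @param table an [abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(genus = rownames(table$mat), table$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert counts to per-sample relative abundances
#'
#' Each kingdom's table is closed to 1 on its own compositional scale;
#' the three marker sets are never renormalized jointly because read
#' counts are not quantitatively comparable across markers.
#'
#' @param table an [abundance_table()].
#' @return A relative [abundance_table()].
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$type == "relative") return(table)
  cs <- colSums(table$mat)
  if (any(cs == 0)) {
    stopf("cannot close all-zero samples: %s",
          paste(colnames(table$mat)[cs == 0], collapse = ", "))
  }
  out <- table
  out$mat <- sweep(table$mat, 2, cs, "/")
  out$type <- "relative"
  out
}
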