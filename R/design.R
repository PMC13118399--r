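#' Sample-to-treatment design
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param treatment character vector mapping each sample to a treatment.
#' @param replicate integer replicate number within treatment.
#'
#' @return A data frame of class `"study_design"`.
#' @export
study_design <- function(sample_id, treatment, replicate = NULL) {
  sample_id <- as.character(sample_id)
  treatment <- as.character(treatment)
  if (length(sample_id) != length(treatment)) {
    stopf("sample_id and treatment must have equal length")
  }
  if (anyDuplicated(sample_id)) stopf("duplicate sample_id in design")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(treatment), treatment, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1)) {
    stopf("replicate must be a positive integer")
  }
  d <- data.frame(sample_id = sample_id, treatment = treatment,
                  replicate = replicate, stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

#' Default 7-treatment x 3-replicate design
#'
#' The layout of the motivating trial: seven cropping systems
#' (MM, MI1-MI6), three field replicates each.
#'
#' @param treatments treatment codes.
#' @param n_rep replicates per treatment.
#' @return A `"study_design"` data frame with 21 samples named
#'   `<treatment>_<replicate>`.
#' @export
default_design <- function(treatments = study_reference()$treatments,
                           n_rep = 3) {
  tr <- rep(treatments, each = n_rep)
  rp <- rep(seq_len(n_rep), times = length(treatments))
  study_design(paste(tr, rp, sep = "_"), tr, rp)
}

#' Read a design table (TSV with sample_id, treatment, replicate columns)
#'
#' @param path file path.
#' @return A `"study_design"` data frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment")
  if (!all(need %in% names(d))) {
    stopf("design file must have columns: %s", paste(need, collapse = ", "))
  }
  study_design(d$sample_id, d$treatment, d$replicate %||% NULL)
}

# require >= 2 replicates per treatment before any significance testing
check_replication <- function(design, min_rep = 2) {
  n <- table(design$treatment)
  if (any(n < min_rep)) {
    stopf("treatments with fewer than %d replicates: %s", min_rep,
          paste(names(n)[n < min_rep], collapse = ", "))
  }
  invisible(design)
}
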