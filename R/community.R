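#' Remove Glomeromycota genera from an ITS table
#'
#' AMF are profiled by their own 18S marker, so genera classified as
#' Glomeromycota are removed from the ITS fungal table; the remainder is
#' the non-AMF community. Genera absent from the taxonomy map are kept.
#'
#' @param table an [abundance_table()] (kingdom `"non_amf"`).
#' @param taxonomy named character vector mapping genus to phylum; names
#'   may be given with or without the kingdom prefix.
#' @return The filtered [abundance_table()].
#' @export
remove_amf_from_its <- function(table, taxonomy) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- rownames(table$mat)
  raw <- sub("^(B_|F_|AMF_)", "", ids)
  phylum <- taxonomy[raw]
  hit <- ifelse(is.na(phylum), taxonomy[ids], phylum)
  drop <- !is.na(hit) & hit == "Glomeromycota"
  if (all(drop)) warning("all genera were Glomeromycota; empty table returned")
  out <- table
  out$mat <- table$mat[!drop, , drop = FALSE]
  out
}

#' Rarefy counts to an even depth
#'
#' Subsamples each sample without replacement so that every column sum
#' equals `depth`. `depth = "min"` uses the smallest sample total, the
#' usual choice when equalizing sequencing effort across samples.
#'
#' @param table a counts [abundance_table()].
#' @param depth integer target depth, or `"min"`.
#' @param seed integer seed for the subsampling.
#' @return A counts [abundance_table()] with equal column sums.
#' @export
rarefy_counts <- function(table, depth = "min", seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$type != "counts") stopf("rarefaction needs a counts table")
  mat <- table$mat
  if (any(mat != floor(mat))) stopf("rarefaction needs integer counts")
  cs <- colSums(mat)
  if (identical(depth, "min")) depth <- min(cs)
  depth <- as.integer(depth)
  if (depth > min(cs)) {
    stopf("depth %d exceeds the smallest sample total (%d)", depth, min(cs))
  }
  # counts are validated above; rrarefy's "observed counts" heuristic can
  # misfire when the smallest positive count exceeds 1
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(mat), depth))))
  dimnames(out) <- dimnames(mat)
  res <- table
  res$mat <- out
  res
}

#' Dominant genera by mean relative abundance
#'
#' @param table a relative [abundance_table()].
#' @param cutoff fraction the mean relative abundance across samples must
#'   strictly exceed (default 0.001 = 0.1%).
#' @return Character vector of dominant genus ids.
#' @export
dominant_genera <- function(table, cutoff = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$type != "relative") stopf("dominance filter needs a relative table")
  mu <- rowMeans(table$mat)
  names(mu)[mu > cutoff]
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum |x_a - x_b| / sum (x_a + x_b)` over genera.
#'
#' @param table an [abundance_table()] (counts or relative).
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  zero <- colSums(table$mat) == 0
  if (sum(zero) >= 2) {
    stopf("Bray-Curtis undefined between all-zero samples: %s",
          paste(colnames(table$mat)[zero], collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(table$mat), method = "bray"))
}

#' Principal coordinate analysis
#'
#' Classical scaling of the double-centered `-d^2/2` matrix. Negative
#' eigenvalues (expected for the non-Euclidean Bray-Curtis) are reported
#' untransformed; variance-explained fractions are taken over the
#' positive eigenvalues only.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @return List with `points` (samples x axes), `eig` (all eigenvalues)
#'   and `var_explained` (fractions over positive eigenvalues).
#' @export
pcoa_ord <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stopf("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  n <- nrow(d)
  # cmdscale warns about the (expected) negative eigenvalues; we report them
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  pts <- sc$points
  if (is.null(pts) || ncol(pts) == 0) {
    pts <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
  } else {
    colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  }
  pos <- sc$eig[sc$eig > 1e-12]
  ve <- if (length(pos)) pos / sum(pos) else numeric(0)
  list(points = pts, eig = sc$eig, var_explained = ve)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from among-
#' and within-group sums of squared distances, with unrestricted
#' permutation of sample labels and
#' `p = (1 + #permuted F >= observed) / (1 + n_perm)`.
#'
#' @param d square symmetric distance matrix.
#' @param design a [study_design()] (or character group vector) aligned
#'   with the rows of `d`.
#' @param n_perm number of permutations (>= 99), ignored when
#'   `permutations` is given.
#' @param seed integer seed.
#' @param permutations optional matrix of explicit permutations (rows are
#'   orderings of the sample indices), e.g. an exhaustive enumeration.
#' @return List with `f`, `p`, `r2` and `n_perm`.
#' @export
permanova_test <- function(d, design, n_perm = 999, seed = 1L,
                           permutations = NULL) {
  d <- as.matrix(d)
  groups <- if (inherits(design, "study_design")) design$treatment else as.character(design)
  if (length(groups) != nrow(d)) stopf("design does not match distance matrix")
  if (length(unique(groups)) < 2) stopf("PERMANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs >= 2 members")
  dat <- data.frame(group = factor(groups))
  if (is.null(permutations)) {
    if (n_perm < 99) stopf("n_perm must be >= 99")
    fit <- with_seed(seed,
      vegan::adonis2(stats::as.dist(d) ~ group, data = dat,
                     permutations = n_perm))
    used <- n_perm
  } else {
    fit <- vegan::adonis2(stats::as.dist(d) ~ group, data = dat,
                          permutations = permutations)
    used <- nrow(permutations)
  }
  list(f = fit$F[1], p = fit$`Pr(>F)`[1], r2 = fit$R2[1], n_perm = used)
}
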