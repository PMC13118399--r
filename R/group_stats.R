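#' One-way ANOVA with Duncan's multiple range letters
#'
#' Fits the one-way fixed-effects model, then runs Duncan's multiple
#' range test protected by the omnibus F-test: when the ANOVA p-value is
#' not below `alpha`, all treatments share the letter "a". Otherwise a
#' span of p ordered means is declared homogeneous when its range does
#' not exceed `q(alpha_p, p, df) * sqrt(MSE / n_h)`, with the protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)` and `n_h` the harmonic mean
#' group size; compact letters are read off the maximal homogeneous
#' spans. Treatments sharing a letter are not significantly different.
#'
#' @param values numeric vector, one entry per sample.
#' @param design a [study_design()] aligned with `values` (values are in
#'   `design$sample_id` order), or a factor/character vector of groups.
#' @param alpha significance level (default 0.05).
#' @return Data frame of class `"duncan_letters"`: one row per treatment
#'   (sorted by descending mean) with `n`, `mean`, `sd`, `letters`;
#'   attributes `f`, `p_value`, `mse`, `df`.
#' @export
anova_duncan <- function(values, design, alpha = 0.05) {
  groups <- if (inherits(design, "study_design")) design$treatment else as.character(design)
  check_numeric_finite(values, "values")
  if (length(values) != length(groups)) stopf("values and design lengths differ")
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least 2 groups")
  if (any(tab < 2)) stopf("every group needs >= 2 replicates")

  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  ns <- as.numeric(tab)[match(names(means), names(tab))]
  N <- length(values); k <- length(means)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df <- N - k
  if (ssw <= 0) stopf("degenerate ANOVA: zero within-group variance in all groups")
  mse <- ssw / df
  ssb <- sum(ns * (means - mean(values))^2)
  f <- (ssb / (k - 1)) / mse
  p_f <- stats::pf(f, k - 1, df, lower.tail = FALSE)

  # sort by descending mean, ties broken by treatment label
  ord <- order(-means, names(means))
  m <- means[ord]

  if (p_f < alpha) {
    n_h <- k / sum(1 / ns)
    se <- sqrt(mse / n_h)
    nonsig <- diag(TRUE, k)
    for (span in seq(k, 2)) {
      crit <- stats::qtukey(1 - (1 - alpha)^(span - 1), span, df) * se
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        covered <- span < k && any(nonsig[seq_len(i), j:k])
        if (covered || (m[i] - m[j]) <= crit) nonsig[i, j] <- TRUE
      }
    }
    letters_sorted <- cld_from_spans(nonsig)
  } else {
    letters_sorted <- rep("a", k)
  }

  out <- data.frame(treatment = names(m), n = ns[ord],
                    mean = unname(m), sd = unname(sds[ord]),
                    letters = letters_sorted, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "f") <- f
  attr(out, "p_value") <- p_f
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  attr(out, "alpha") <- alpha
  class(out) <- c("duncan_letters", "data.frame")
  out
}

# compact letter display from an upper-triangular homogeneity matrix over
# means sorted in descending order: letters = maximal homogeneous spans
cld_from_spans <- function(nonsig) {
  k <- nrow(nonsig)
  jmax <- vapply(seq_len(k), function(i) max(which(nonsig[i, ])), integer(1))
  lett <- rep("", k)
  s <- 0L
  best <- 0L
  for (i in seq_len(k)) {
    if (jmax[i] > best) {
      s <- s + 1L
      lett[i:jmax[i]] <- paste0(lett[i:jmax[i]], letters[s])
      best <- jmax[i]
    }
  }
  lett
}

#' Spearman rank correlation with exact or approximate p-value
#'
#' Rank correlation using midranks for ties. For n > 10 the p-value uses
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))`; for n <= 10
#' it is the two-sided tail of the exact permutation distribution over
#' all n! orderings.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
spearman_cor <- function(x, y) {
  check_numeric_finite(x, "x"); check_numeric_finite(y, "y")
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (n < 4) stopf("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("rho undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n > 10) {
    p <- spearman_p_approx(rho, n)
    method <- "t-approximation"
  } else {
    p <- spearman_p_exact(rx, ry)
    method <- "exact"
  }
  list(rho = rho, p = p, n = n, method = method)
}

spearman_p_approx <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
}

# exact two-sided permutation p over all n! orderings of the y ranks
spearman_p_exact <- function(rx, ry) {
  n <- length(rx)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  obs <- abs(sum(cx * cy) / denom)
  count <- 0; total <- 0
  # chunk by the first position to bound memory at (n-1)! rows
  sub <- perm_matrix(n - 1L)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    perms <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    s <- matrix(cx[perms], nrow(perms), n) %*% cy
    count <- count + sum(abs(s / denom) >= obs - 1e-12)
    total <- total + nrow(perms)
  }
  count / total
}

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perm_matrix(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[p], m, n - 1L)
  }
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  check_numeric_finite(pvalues, "pvalues")
  if (any(pvalues < 0 | pvalues > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
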