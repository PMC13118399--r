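#' First principal component scores of the crucial-genera sub-matrix
#'
#' Column-standardizes the samples x genera abundance sub-matrix and
#' takes the first right-singular direction. The sign is fixed so that
#' the first genus loads positively.
#'
#' @param abundance relative-abundance matrix (genera x samples).
#' @param genera crucial genus ids (>= 2).
#' @return List with `scores` (per-sample, mean 0), `var_explained`
#'   (fraction in (0, 1\]) and `loadings`.
#' @export
pc1_scores <- function(abundance, genera) {
  if (length(genera) < 2) stopf("need at least 2 genera")
  x <- t(abundance[genera, , drop = FALSE])
  if (nrow(x) < 3) stopf("need at least 3 samples")
  const <- apply(x, 2, stats::sd) == 0
  if (all(const)) stopf("all genus columns are constant")
  if (any(const)) {
    warning(sprintf("dropping constant genus column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  xs <- scale(x)
  sv <- svd(xs)
  scores <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  if (loadings[1] < 0) { scores <- -scores; loadings <- -loadings }
  names(scores) <- rownames(x)
  names(loadings) <- colnames(x)
  list(scores = scores, var_explained = sv$d[1]^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Fit a partial least squares path model
#'
#' Reflective (mode A) measurement for every block and the path
#' inner-weighting scheme. Indicators are standardized; outer weights
#' start at 1 and the algorithm alternates (i) latent scores as
#' standardized weighted indicator sums, (ii) inner weights by the path
#' scheme (regression coefficients on predecessors, correlations with
#' successors), and (iii) mode-A outer weights as indicator-latent-proxy
#' correlations, until the largest outer-weight change falls below
#' `tol`. Path coefficients are then OLS regressions of each endogenous
#' latent on its predecessors; GOF is
#' `sqrt(mean communality x mean R^2)`. Latent sign is anchored to a
#' positive correlation with each block's first indicator.
#'
#' @param data data frame or matrix of indicators (samples x indicators).
#' @param blocks named list: latent name -> character vector of indicator
#'   columns; each indicator belongs to exactly one block.
#' @param inner square 0/1 matrix over the latents, lower-triangular in
#'   some ordering (acyclic); `inner[i, j] = 1` means a directed path
#'   from latent j to latent i.
#' @param tol convergence tolerance on outer weights.
#' @param max_iter maximum iterations.
#' @return An object of class `"plspm_fit"` with latent `scores`, outer
#'   `weights` and `loadings`, `path_coefficients` (matrix B with
#'   `B[i, j]` the coefficient of j in the equation for i), per-latent
#'   `r_squared`, `communality`, `gof`, an `effects` table and the
#'   convergence trace.
#' @export
fit_plspm <- function(data, blocks, inner, tol = 1e-7, max_iter = 300) {
  data <- as.data.frame(data)
  lat <- names(blocks)
  if (is.null(lat) || any(lat == "")) stopf("blocks must be a named list")
  inner <- as.matrix(inner)
  if (!identical(dim(inner), c(length(lat), length(lat)))) {
    stopf("inner must be a square matrix over the %d latents", length(lat))
  }
  dimnames(inner) <- list(lat, lat)
  if (any(inner != 0 & inner != 1)) stopf("inner entries must be 0 or 1")
  if (any(diag(inner) != 0)) stopf("inner must have a zero diagonal")
  check_dag(inner)
  all_ind <- unlist(blocks)
  if (anyDuplicated(all_ind)) stopf("each indicator may appear in exactly one block")
  miss <- setdiff(all_ind, colnames(data))
  if (length(miss)) stopf("indicators missing from data: %s",
                          paste(miss, collapse = ", "))
  X <- as.matrix(data[, all_ind, drop = FALSE])
  check_numeric_finite(X, "indicator data")
  if (any(apply(X, 2, stats::sd) == 0)) stopf("constant indicator column")
  X <- scale(X)
  n <- nrow(X)

  idx <- lapply(blocks, function(b) match(b, all_ind))
  w <- lapply(blocks, function(b) rep(1, length(b)))
  latent_scores <- function(w) {
    Y <- vapply(lat, function(l) {
      y <- X[, idx[[l]], drop = FALSE] %*% w[[l]]
      y <- drop(scale(y))
      if (stats::cor(y, X[, idx[[l]][1]]) < 0) y <- -y
      y
    }, numeric(n))
    colnames(Y) <- lat
    Y
  }

  delta <- Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    Y <- latent_scores(w)
    # inner proxies under the path scheme
    Z <- Y
    for (l in lat) {
      pred <- lat[inner[l, ] == 1]
      succ <- lat[inner[, l] == 1]
      e <- numeric(0); nb <- character(0)
      if (length(pred)) {
        fit <- stats::lm.fit(cbind(1, Y[, pred, drop = FALSE]), Y[, l])
        if (anyNA(fit$coefficients)) stopf("singular inner regression for latent '%s'", l)
        e <- c(e, fit$coefficients[-1]); nb <- c(nb, pred)
      }
      if (length(succ)) {
        e <- c(e, stats::cor(Y[, succ, drop = FALSE], Y[, l])[, 1])
        nb <- c(nb, succ)
      }
      if (!length(nb)) stopf("latent '%s' is disconnected in the inner model", l)
      Z[, l] <- Y[, nb, drop = FALSE] %*% e
    }
    # mode A outer update: correlations of indicators with the inner proxy
    w_new <- lapply(lat, function(l) {
      drop(stats::cor(X[, idx[[l]], drop = FALSE], Z[, l]))
    })
    names(w_new) <- lat
    # compare on the normalized scale actually used for scores
    norm_w <- function(w) unlist(lapply(lat, function(l) {
      y <- X[, idx[[l]], drop = FALSE] %*% w[[l]]
      s <- stats::sd(y)
      wl <- w[[l]] / s
      if (stats::cor(drop(y), X[, idx[[l]][1]]) < 0) wl <- -wl
      wl
    }))
    delta <- max(abs(norm_w(w_new) - norm_w(w)))
    w <- w_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stopf("PLS-PM did not converge after %d iterations (last delta %.3g)",
            max_iter, delta)
    }
  }

  Y <- latent_scores(w)
  B <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  r2 <- stats::setNames(rep(NA_real_, length(lat)), lat)
  for (l in lat) {
    pred <- lat[inner[l, ] == 1]
    if (!length(pred)) next
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Y[, pred, drop = FALSE]),
                         Y[, l])
    if (anyNA(fit$coefficients)) stopf("singular path regression for latent '%s'", l)
    B[l, pred] <- fit$coefficients[pred]
    r2[l] <- 1 - sum(fit$residuals^2) / sum((Y[, l] - mean(Y[, l]))^2)
  }
  loadings <- lapply(lat, function(l) {
    drop(stats::cor(X[, idx[[l]], drop = FALSE], Y[, l]))
  })
  names(loadings) <- lat
  communality <- unlist(loadings)^2
  gof <- sqrt(mean(communality) * mean(r2, na.rm = TRUE))

  fitobj <- structure(list(
    blocks = blocks, inner = inner, scores = Y, weights = w,
    loadings = loadings, path_coefficients = B, r_squared = r2,
    communality = communality, gof = gof, iterations = iter,
    delta = delta, n = n), class = "plspm_fit")
  fitobj$effects <- plspm_effects(fitobj)
  fitobj
}

check_dag <- function(inner) {
  remaining <- seq_len(nrow(inner))
  while (length(remaining)) {
    sub <- inner[remaining, remaining, drop = FALSE]
    free <- remaining[rowSums(sub) == 0]
    if (!length(free)) stopf("inner model must be acyclic")
    remaining <- setdiff(remaining, free)
  }
  invisible(TRUE)
}

#' Direct, indirect and total effects of a fitted path model
#'
#' Direct effects are the path coefficients; indirect effects sum the
#' coefficient products over all directed paths of length >= 2, via the
#' identity `total = (I - B)^-1 - I`.
#'
#' @param fit a [fit_plspm()] object.
#' @return Data frame with `from`, `to`, `direct`, `indirect`, `total`
#'   for every ancestor-descendant latent pair.
#' @export
plspm_effects <- function(fit) {
  if (!inherits(fit, "plspm_fit")) stopf("effects need a fitted plspm_fit")
  B <- fit$path_coefficients
  lat <- rownames(B)
  total <- solve(diag(nrow(B)) - B) - diag(nrow(B))
  indirect <- total - B
  rows <- list()
  for (to in lat) for (from in lat) {
    if (from == to) next
    if (fit$inner[to, from] == 0 && abs(total[to, from]) < 1e-12) next
    rows[[length(rows) + 1L]] <- data.frame(
      from = from, to = to, direct = B[to, from],
      indirect = indirect[to, from], total = total[to, from],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Bootstrap confidence intervals for path coefficients
#'
#' Case resampling: refits the model on bootstrap resamples of the
#' samples, collecting every inner path coefficient. Resamples in which
#' an indicator becomes constant are redrawn (and counted). Percentile
#' CIs; two-sided p-values from the sign of the resampled coefficients
#' with add-one smoothing.
#'
#' @param data,blocks,inner as in [fit_plspm()].
#' @param n_boot number of bootstrap resamples (>= 199).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return Data frame: `from`, `to`, `estimate`, `lower`, `upper`, `p`,
#'   with attribute `redraws`.
#' @export
bootstrap_paths <- function(data, blocks, inner, n_boot = 500, seed = 1L,
                            conf = 0.95) {
  if (n_boot < 199) stopf("n_boot must be >= 199")
  data <- as.data.frame(data)
  point <- fit_plspm(data, blocks, inner)
  B0 <- point$path_coefficients
  paths <- which(point$inner == 1, arr.ind = TRUE)
  draws <- matrix(NA_real_, n_boot, nrow(paths))
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        take <- sample.int(nrow(data), replace = TRUE)
        boot <- data[take, , drop = FALSE]
        ok <- all(apply(as.matrix(boot[, unlist(blocks), drop = FALSE]),
                        2, stats::sd) > 0)
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > 100L * n_boot) stopf("too many degenerate resamples")
      }
      fitb <- tryCatch(fit_plspm(boot, blocks, inner), error = function(e) NULL)
      if (is.null(fitb)) { redraws <- redraws + 1L; next }
      draws[b, ] <- fitb$path_coefficients[paths]
    }
  })
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  a <- (1 - conf) / 2
  out <- data.frame(
    from = colnames(B0)[paths[, 2]], to = rownames(B0)[paths[, 1]],
    estimate = B0[paths],
    lower = apply(draws, 2, stats::quantile, probs = a),
    upper = apply(draws, 2, stats::quantile, probs = 1 - a),
    p = vapply(seq_len(ncol(draws)), function(k) {
      b <- draws[, k]
      2 * min((1 + sum(b <= 0)) / (1 + length(b)),
              (1 + sum(b >= 0)) / (1 + length(b)))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "redraws") <- redraws
  attr(out, "n_boot") <- nrow(draws)
  out
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("PLS path model: %d latents, %d samples, %d iterations (delta %.2g)\n",
              length(x$blocks), x$n, x$iterations, x$delta))
  cat(sprintf("GOF = %.3f\n", x$gof))
  cat("Path coefficients (row ~ column):\n")
  print(round(x$path_coefficients, 3))
  invisible(x)
}

#' @export
coef.plspm_fit <- function(object, ...) object$path_coefficients

#' @export
summary.plspm_fit <- function(object, ...) {
  cat("Inner model R-squared:\n")
  print(round(object$r_squared, 3))
  cat("\nEffects on each endogenous latent:\n")
  print(object$effects, digits = 3)
  cat(sprintf("\nGOF = %.3f (mean communality %.3f, mean R2 %.3f)\n",
              object$gof, mean(object$communality),
              mean(object$r_squared, na.rm = TRUE)))
  invisible(object)
}
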