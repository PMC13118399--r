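chain_inner <- function(lat) {
  k <- length(lat)
  inner <- matrix(0, k, k, dimnames = list(lat, lat))
  for (i in 2:k) inner[i, i - 1] <- 1
  inner
}

test_that("single-indicator X -> Y collapses to the Pearson correlation", {
  set.seed(31)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  dat <- data.frame(x = x, y = y)
  fit <- fit_plspm(dat, list(X = "x", Y = "y"), chain_inner(c("X", "Y")))
  expect_equal(unname(fit$path_coefficients["Y", "X"]), cor(x, y),
               tolerance = 1e-9)
  expect_equal(unname(fit$r_squared["Y"]), cor(x, y)^2, tolerance = 1e-9)
})

test_that("single-indicator chains collapse to standardized OLS path analysis", {
  set.seed(32)
  n <- 20
  x <- rnorm(n)
  m <- 0.7 * x + rnorm(n, 0, 0.5)
  y <- 0.5 * m + rnorm(n, 0, 0.5)
  dat <- data.frame(x = x, m = m, y = y)
  fit <- fit_plspm(dat, list(X = "x", M = "m", Y = "y"),
                   chain_inner(c("X", "M", "Y")))
  B <- fit$path_coefficients
  # oracle: OLS on standardized observed variables
  b1 <- unname(coef(lm(scale(m) ~ scale(x)))[2])
  b2 <- unname(coef(lm(scale(y) ~ scale(m)))[2])
  expect_equal(unname(B["M", "X"]), b1, tolerance = 1e-6)
  expect_equal(unname(B["Y", "M"]), b2, tolerance = 1e-6)
  # total effect of X on Y is the product along the only path
  eff <- fit$effects
  tot <- eff$total[eff$from == "X" & eff$to == "Y"]
  expect_equal(tot, b1 * b2, tolerance = 1e-6)
  expect_equal(eff$direct[eff$from == "X" & eff$to == "Y"], 0)
})

test_that("effects obey the (I - B)^-1 - I identity on a random DAG", {
  set.seed(33)
  n <- 60
  a <- rnorm(n); b <- 0.5 * a + rnorm(n); c_ <- 0.4 * a - 0.3 * b + rnorm(n)
  d <- 0.6 * c_ + 0.2 * a + rnorm(n)
  dat <- data.frame(a = a, b = b, c = c_, d = d)
  lat <- c("A", "B", "C", "D")
  inner <- matrix(0, 4, 4, dimnames = list(lat, lat))
  inner["B", "A"] <- 1
  inner["C", c("A", "B")] <- 1
  inner["D", c("A", "C")] <- 1
  fit <- fit_plspm(dat, list(A = "a", B = "b", C = "c", D = "d"), inner)
  B <- fit$path_coefficients
  total_oracle <- solve(diag(4) - B) - diag(4)
  for (r in seq_len(nrow(fit$effects))) {
    e <- fit$effects[r, ]
    expect_equal(e$total, total_oracle[e$to, e$from], tolerance = 1e-12)
    expect_equal(e$total, e$direct + e$indirect, tolerance = 1e-12)
  }
  # hand-checkable chain arithmetic on a frozen coefficient matrix
  B2 <- matrix(0, 3, 3, dimnames = list(c("X", "M", "Y"), c("X", "M", "Y")))
  B2["M", "X"] <- 0.5; B2["Y", "M"] <- 0.4
  tot2 <- solve(diag(3) - B2) - diag(3)
  expect_equal(tot2["Y", "X"], 0.20)
  B2["Y", "X"] <- 0.3
  tot3 <- solve(diag(3) - B2) - diag(3)
  expect_equal(tot3["Y", "X"], 0.50)
})

test_that("duplicated indicators load equally and latents keep unit variance", {
  set.seed(34)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  dat <- data.frame(x1 = x, x2 = x, y = y)
  fit <- fit_plspm(dat, list(X = c("x1", "x2"), Y = "y"),
                   chain_inner(c("X", "Y")))
  expect_equal(unname(fit$loadings$X[1]), unname(fit$loadings$X[2]),
               tolerance = 1e-9)
  expect_equal(abs(cor(fit$scores[, "X"], x)), 1, tolerance = 1e-9)
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1), tolerance = 1e-9)
  # path coefficients are invariant to indicator rescaling
  dat2 <- data.frame(x1 = 100 * x, x2 = x, y = y / 7)
  fit2 <- fit_plspm(dat2, list(X = c("x1", "x2"), Y = "y"),
                    chain_inner(c("X", "Y")))
  expect_equal(fit2$path_coefficients, fit$path_coefficients,
               tolerance = 1e-7)
  expect_true(fit$gof >= 0 && fit$gof <= 1)
})

test_that("model validation rejects cyclic or malformed specifications", {
  dat <- data.frame(x = rnorm(10), y = rnorm(10))
  cyc <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_error(fit_plspm(dat, list(X = "x", Y = "y"), cyc), "acyclic")
  expect_error(fit_plspm(dat, list(X = "x", Y = "x"), chain_inner(c("X", "Y"))),
               "exactly one block")
  dat$z <- 1
  expect_error(fit_plspm(dat, list(X = "x", Y = "z"), chain_inner(c("X", "Y"))),
               "constant indicator")
})

test_that("PC1 scores match an eigendecomposition oracle", {
  set.seed(35)
  mat <- matrix(runif(5 * 12), 5, 12,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  pc <- pc1_scores(mat, rownames(mat))
  ev <- eigen(cov(scale(t(mat))))
  expect_equal(pc$var_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-9)
  oracle_scores <- scale(t(mat)) %*% ev$vectors[, 1]
  expect_equal(abs(cor(pc$scores, oracle_scores[, 1])), 1, tolerance = 1e-9)
  expect_equal(mean(pc$scores), 0, tolerance = 1e-9)
  # rank-1 input: PC1 explains everything
  m2 <- rbind(g1 = 1:12, g2 = 2 * (1:12) + 3)
  colnames(m2) <- paste0("s", 1:12)
  expect_equal(pc1_scores(m2, c("g1", "g2"))$var_explained, 1,
               tolerance = 1e-9)
  # orthogonal equal-variance genera: share 1/k in expectation; here exact
  # symmetry via a balanced design
  m3 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  colnames(m3) <- paste0("s", 1:4)
  expect_equal(pc1_scores(m3, c("g1", "g2"))$var_explained, 0.5,
               tolerance = 1e-9)
  expect_warning(pc1_scores(rbind(m2, gc = rep(1, 12)),
                            c("g1", "g2", "gc")), "constant")
  expect_error(pc1_scores(rbind(ga = rep(1, 12), gb = rep(2, 12)),
                          c("ga", "gb")), "constant")
})

test_that("bootstrap separates strong paths from null paths", {
  set.seed(36)
  n <- 30
  x <- rnorm(n)
  m <- 0.9 * x + rnorm(n, 0, 0.3)   # strong path
  y <- rnorm(n)                     # null path M -> Y
  dat <- data.frame(x = x, m = m, y = y)
  blocks <- list(X = "x", M = "m", Y = "y")
  inner <- chain_inner(c("X", "M", "Y"))
  strong_excl <- 0; null_cover <- 0
  for (i in 1:10) {
    set.seed(400 + i)
    dat_i <- within(dat, {
      m <- 0.9 * x + rnorm(n, 0, 0.3)
      y <- rnorm(n)
    })
    bs <- bootstrap_paths(dat_i, blocks, inner, n_boot = 199, seed = i)
    s <- bs[bs$from == "X" & bs$to == "M", ]
    nl <- bs[bs$from == "M" & bs$to == "Y", ]
    strong_excl <- strong_excl + (s$lower > 0)
    null_cover <- null_cover + (nl$lower <= 0 && nl$upper >= 0)
  }
  expect_gte(strong_excl, 9)
  expect_gte(null_cover, 8)
  expect_error(bootstrap_paths(dat, blocks, inner, n_boot = 0), ">= 199")
})
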