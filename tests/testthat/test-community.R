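test_that("Glomeromycota removal matches an independent set filter", {
  set.seed(7)
  mat <- matrix(rpois(5 * 4, 20), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  tb <- abundance_table(mat, "non_amf")
  tax <- c(g1 = "Glomeromycota", g2 = "Ascomycota", g3 = "Glomeromycota",
           g4 = "Basidiomycota")
  out <- remove_amf_from_its(tb, tax)
  expect_equal(nrow(out$mat), 3)  # g5 unknown -> kept
  keep_oracle <- setdiff(rownames(tb$mat),
                         paste0("F_", names(tax)[tax == "Glomeromycota"]))
  expect_setequal(rownames(out$mat), keep_oracle)
  # no Glomeromycota -> identity
  out2 <- remove_amf_from_its(tb, c(g1 = "Ascomycota"))
  expect_equal(out2$mat, tb$mat)
  expect_warning(remove_amf_from_its(tb, stats::setNames(
    rep("Glomeromycota", 5), paste0("g", 1:5))), "empty")
})

test_that("rarefaction preserves zeros, hits the depth exactly, and is forced when trivial", {
  mat <- matrix(c(10, 0, 4, 6, 8, 2), 2,
                dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  tb <- abundance_table(mat, "bacteria")
  r <- rarefy_counts(tb, 5, seed = 1)
  expect_equal(unname(colSums(r$mat)), rep(5, 3))
  expect_true(all(r$mat[tb$mat == 0] == 0))
  expect_equal(unname(r$mat[, "s1"]), c(5, 0))  # forced subsample
  # depth = column sums leaves the table unchanged
  eq <- matrix(c(3, 7, 6, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  tbe <- abundance_table(eq, "bacteria")
  expect_equal(rarefy_counts(tbe, 10, seed = 2)$mat, tbe$mat)
  expect_error(rarefy_counts(tb, 11), "exceeds")
  expect_error(rarefy_counts(relative_abundance(tbe)), "counts table")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- c(400, 120, 60, 15, 5)
  mat <- matrix(counts, 5, 1, dimnames = list(paste0("g", 1:5), "s1"))
  tb <- abundance_table(mat, "bacteria")
  depth <- 200
  n_draws <- 1000
  draws <- vapply(seq_len(n_draws), function(i) {
    rarefy_counts(tb, depth, seed = i)$mat[, 1]
  }, numeric(5))
  total <- sum(counts)
  expected <- depth * counts / total
  # hypergeometric variance for sampling without replacement
  v <- depth * (counts / total) * (1 - counts / total) *
    (total - depth) / (total - 1)
  se <- sqrt(v / n_draws)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se + 1e-9))
})

test_that("dominant-genus filter uses a strict mean-abundance cutoff", {
  mat <- matrix(c(0.001, 0.001, 0.0015, 0.0005, 0.9975, 0.9985), 3, 2,
                byrow = TRUE, dimnames = list(c("g1", "g2", "g3"),
                                              c("s1", "s2")))
  tb <- abundance_table(mat, "bacteria", type = "relative", prefix = FALSE)
  expect_equal(dominant_genera(tb, 0.001), "g3")  # g1 exactly at cutoff: out
  set.seed(8)
  m2 <- matrix(runif(50 * 6), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  tb2 <- rel_table(m2)
  expect_setequal(dominant_genera(tb2, 0.02),
                  rownames(m2)[rowMeans(sweep(m2, 2, colSums(m2), "/")) > 0.02])
})

test_that("Bray-Curtis matches the hand formula and its bounds", {
  mat <- cbind(s1 = c(1, 2, 0), s2 = c(2, 1, 1), s3 = c(0, 0, 7),
               s4 = c(1, 2, 0))
  rownames(mat) <- paste0("g", 1:3)
  tb <- abundance_table(mat, "bacteria", prefix = FALSE)
  d <- bray_curtis(tb)
  expect_equal(d["s1", "s4"], 0)      # identical samples
  expect_equal(d["s1", "s3"], 1)      # disjoint support
  # manual formula for a generic pair
  x <- mat[, "s1"]; y <- mat[, "s2"]
  expect_equal(d["s1", "s2"], sum(abs(x - y)) / sum(x + y))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  # genus order must not matter
  tb2 <- abundance_table(mat[c(3, 1, 2), ], "bacteria", prefix = FALSE)
  expect_equal(bray_curtis(tb2), d)
  zz <- matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 1), 3, 3,
               dimnames = list(paste0("g", 1:3), c("s1", "s2", "s3")))
  expect_error(bray_curtis(abundance_table(zz, "bacteria", prefix = FALSE)),
               "all-zero")
})

test_that("PCoA recovers collinear configurations and degenerate inputs", {
  pos <- c(0, 1, 3, 6)
  d <- as.matrix(dist(pos))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ord <- pcoa_ord(d)
  expect_equal(abs(cor(ord$points[, 1], pos)), 1, tolerance = 1e-9)
  expect_equal(sum(ord$var_explained), 1, tolerance = 1e-9)
  expect_equal(ord$var_explained[1], 1, tolerance = 1e-9)
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ordz <- pcoa_ord(z)
  expect_true(all(ordz$points == 0))
  asym <- d; asym[1, 2] <- 99
  expect_error(pcoa_ord(asym), "symmetric")
})

test_that("PERMANOVA saturates for separated clusters and is seed-reproducible", {
  set.seed(9)
  a <- matrix(rnorm(10 * 4, 0), 10, 4)
  b <- matrix(rnorm(10 * 4, 8), 10, 4)
  mat <- abs(cbind(a, b))
  dimnames(mat) <- list(paste0("g", 1:10), paste0("s", 1:8))
  d <- bray_curtis(abundance_table(mat, "bacteria", prefix = FALSE))
  g <- rep(c("lo", "hi"), each = 4)
  # fixed permutations that neither preserve the partition nor repeat the
  # identity: every permuted F falls below the observed one
  set.seed(101)
  perms <- t(replicate(200, sample(8)))
  keep <- apply(perms, 1, function(p) {
    length(unique(g[p][1:4])) > 1  # mixes the clusters
  })
  perms <- perms[keep, ][1:99, ]
  res <- permanova_test(d, g, permutations = perms)
  expect_equal(res$p, 1 / 100)
  res2 <- permanova_test(d, g, n_perm = 99, seed = 1)
  res3 <- permanova_test(d, g, n_perm = 99, seed = 1)
  expect_identical(res2, res3)
  expect_error(permanova_test(d, rep("one", 8)), "2 groups")
})

test_that("PERMANOVA type-I error is near nominal under the null", {
  set.seed(10)
  n_sim <- 300
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    mat <- matrix(rexp(12 * 9), 12, 9,
                  dimnames = list(paste0("g", 1:12), paste0("s", 1:9)))
    d <- bray_curtis(abundance_table(mat, "bacteria", prefix = FALSE))
    g <- rep(c("a", "b", "c"), each = 3)
    rej[i] <- permanova_test(d, g, n_perm = 99, seed = i)$p <= 0.05
  }
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(rate, 0.05 + 4 * se)
})
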