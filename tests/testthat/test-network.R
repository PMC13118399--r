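# relative table with two rho = 1 cliques (g1-g4 copy latent u, g5-g8 copy
# latent v) that are rank-uncorrelated with each other; columns sum to 1 so
# compositional closure cannot couple the cliques
clique_tables <- function(seed = 1) {
  set.seed(seed)
  vals <- seq(0.01, 0.09, length.out = 12)
  u <- vals
  v <- vals[c(3, 11, 5, 6, 1, 12, 7, 10, 9, 2, 8, 4)]  # spearman(u, v) = 0
  stopifnot(abs(cor(u, v, method = "spearman")) < 1e-12)
  remainder <- 1 - 4 * u - 4 * v
  w <- matrix(runif(8 * 12), 8)
  noise <- sweep(sweep(w, 2, colSums(w), "/"), 2, remainder, "*")
  mat <- rbind(matrix(u, 4, 12, byrow = TRUE),
               matrix(v, 4, 12, byrow = TRUE),
               noise)
  rownames(mat) <- paste0("g", 1:16)
  colnames(mat) <- paste0("s", 1:12)
  abundance_table(mat, "bacteria", type = "relative", prefix = FALSE)
}

test_that("identical abundance vectors yield a rho = 1 edge", {
  tabs <- list(bacteria = clique_tables())
  net <- build_network(tabs, run_config())
  e <- net$edges
  pair <- e[(e$source == "g1" & e$target == "g2") |
            (e$source == "g2" & e$target == "g1"), ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$rho, 1, tolerance = 1e-12)
  expect_equal(pair$sign, "+")
  # all retained edges satisfy the configured thresholds
  expect_true(all(abs(e$rho) > 0.7 & e$p_adj < 0.05))
  # symmetric, no self edges
  expect_false(any(e$source == e$target))
})

test_that("fewer than 4 shared samples is rejected", {
  m <- matrix(runif(9), 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_error(build_network(list(rel_table(m)), run_config()), "4 samples")
})

test_that("two disconnected cliques resolve into exactly two modules", {
  tabs <- list(bacteria = clique_tables())
  net <- build_network(tabs, run_config())
  net <- detect_modules(net)
  memb <- split(net$nodes$genus, net$nodes$module)
  clique1 <- paste0("g", 1:4); clique2 <- paste0("g", 5:8)
  expect_equal(length(memb), 2)
  expect_true(any(vapply(memb, setequal, logical(1), clique1)))
  expect_true(any(vapply(memb, setequal, logical(1), clique2)))
  # partition covers every node exactly once; sizes sum to node count
  expect_equal(sum(net$modules$size), nrow(net$nodes))
  # modularity beats the all-singleton partition
  g <- igraph::graph_from_data_frame(net$edges[, 1:3], directed = FALSE,
                                     vertices = net$nodes$genus)
  q_singleton <- igraph::modularity(g, seq_len(nrow(net$nodes)),
                                    weights = abs(igraph::E(g)$rho))
  expect_gte(net$modularity, q_singleton)
  expect_error(detect_modules(structure(list(edges = data.frame()),
                                        class = "cooc_network")),
               "empty edge set")
})

test_that("module detection is deterministic and recovers planted modules", {
  skip_if_not_installed("mclust")
  aris <- numeric(30)
  for (i in seq_len(30)) {
    sim <- simulate_study(sim_spec(), seed = 100 + i)
    rel <- lapply(sim$tables, relative_abundance)
    net <- build_network(rel, run_config(), dominant = TRUE)
    net1 <- detect_modules(net)
    if (i <= 3) expect_identical(net1$nodes, detect_modules(net)$nodes)
    truth_lab <- rep("none", nrow(net1$nodes))
    for (m in names(sim$truth$members)) {
      truth_lab[net1$nodes$genus %in% sim$truth$members[[m]]] <- m
    }
    keep <- truth_lab != "none"
    aris[i] <- mclust::adjustedRandIndex(truth_lab[keep],
                                         net1$nodes$module[keep])
  }
  expect_gt(mean(aris), 0.9)
})

test_that("major-module rule applies strict threshold arithmetic", {
  sizes <- c(40, 30, 15, 9, 6)
  fake <- structure(list(
    nodes = data.frame(genus = paste0("g", 1:100),
                       module = rep(roman_labels <- as.character(utils::as.roman(1:5)),
                                    times = sizes)),
    modules = data.frame(module = as.character(utils::as.roman(1:5)),
                         size = sizes),
    config = run_config()), class = "cooc_network")
  out <- major_modules(fake, 0.10)
  expect_equal(out$modules$major, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  fake$modules$size <- c(10, 10, 10, 10, 10)  # none strictly > 10
  fake$nodes$module <- rep(out$modules$module, times = fake$modules$size)
  expect_warning(major_modules(fake, 0.10), "no module")
})

test_that("module abundance profiles are z-scored sums of member abundances", {
  tabs <- list(bacteria = clique_tables())
  net <- detect_modules(build_network(tabs, run_config()))
  mab <- module_abundance(net)
  expect_equal(unname(rowMeans(mab$z)), rep(0, nrow(mab$z)), tolerance = 1e-9)
  expect_equal(unname(apply(mab$z, 1, sd)), rep(1, nrow(mab$z)),
               tolerance = 1e-9)
  # raw profile equals the direct member sum (oracle recomputation)
  m1 <- net$modules$module[1]
  members <- net$nodes$genus[net$nodes$module == m1]
  expect_equal(mab$raw[m1, ],
               colSums(net$abundance[members, , drop = FALSE]))
  expect_error(module_abundance(net, "XL"), "no members")
})

test_that("planted module z-profiles track the latent activity", {
  sim <- simulate_study(sim_spec(), seed = 11)
  rel <- lapply(sim$tables, relative_abundance)
  net <- detect_modules(build_network(rel, run_config(), dominant = TRUE))
  mab <- module_abundance(net)
  mem <- intersect(sim$truth$members$planted_intercrop, net$nodes$genus)
  mod <- names(which.max(table(net$nodes$module[match(mem, net$nodes$genus)])))
  r <- cor(mab$z[mod, ], sim$truth$activity["planted_intercrop", ])
  expect_gt(r, 0.8)
})

test_that("independent genera produce essentially no edges (null control)", {
  null_spec <- sim_spec(n_bacteria = 40, n_fungi = 20, n_amf = 10,
                        modules = list(), loading = 0)
  n_seeds <- 30
  edges <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- simulate_abundances(null_spec, seed = 1000 + i)
    rel <- lapply(sim$tables, relative_abundance)
    net <- tryCatch(build_network(rel, run_config(), dominant = TRUE),
                    error = function(e) NULL)
    edges[i] <- if (is.null(net)) 0L else nrow(net$edges)
  }
  # BH over the joint pair set keeps the family-wise discovery rate near
  # alpha: seeds with any edge should be rare
  expect_lte(mean(edges > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / n_seeds))
})
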