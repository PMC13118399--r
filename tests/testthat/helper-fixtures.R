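# shared fixtures, built in code

ref <- study_reference()
CLS <- c("gt2", "m025_2", "m0053_025", "lt0053")

# one profile row from mass + soc vectors
make_profile <- function(mass, soc = rep(1, 4), id = "s1", bulk = 1) {
  df <- data.frame(sample_id = id, stringsAsFactors = FALSE)
  df[paste0("mass_", CLS)] <- as.list(unname(mass))
  df[paste0("soc_", CLS)] <- as.list(unname(soc))
  df$bulk_soc <- bulk
  aggregate_profiles(df)
}

# 21-sample profiles whose replicates sit exactly at the treatment means
# (masses = printed mass proportions as grams, conc = printed SOC conc);
# optional jitter avoids degenerate zero within-treatment variance
mean_profiles <- function(design = default_design(), jitter_sd = 0,
                          soc_from = ref$soc_mean, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    tr <- design$treatment[i]
    mass <- ref$mass_mean[tr, ] + stats::rnorm(4, 0, jitter_sd)
    soc <- soc_from[tr, ] + stats::rnorm(4, 0, jitter_sd)
    df <- data.frame(sample_id = design$sample_id[i], stringsAsFactors = FALSE)
    df[paste0("mass_", CLS)] <- as.list(unname(mass))
    df[paste0("soc_", CLS)] <- as.list(unname(soc))
    df$bulk_soc <- ref$total_soc_mean[tr] + stats::rnorm(1, 0, jitter_sd)
    df
  })
  aggregate_profiles(do.call(rbind, rows))
}

# profiles engineered so c_distribution reproduces the printed C
# distribution exactly: conc_i = cdist_i / massprop_i
cdist_profiles <- function(design = default_design()) {
  rows <- lapply(seq_len(nrow(design)), function(i) {
    tr <- design$treatment[i]
    mass <- ref$mass_mean[tr, ]
    soc <- ref$cdist_mean[tr, ] / mass
    df <- data.frame(sample_id = design$sample_id[i], stringsAsFactors = FALSE)
    df[paste0("mass_", CLS)] <- as.list(unname(mass))
    df[paste0("soc_", CLS)] <- as.list(unname(soc))
    df$bulk_soc <- ref$total_soc_mean[tr]
    df
  })
  aggregate_profiles(do.call(rbind, rows))
}

# small relative abundance table from a genus x sample matrix
rel_table <- function(mat, kingdom = "bacteria") {
  mat <- sweep(mat, 2, colSums(mat), "/")
  abundance_table(mat, kingdom = kingdom, type = "relative", prefix = FALSE)
}

# a small sim_spec that runs fast in unit tests
small_spec <- function(...) {
  sim_spec(n_bacteria = 40, n_fungi = 20, n_amf = 10,
           modules = list(
             list(name = "m1",
                  members = c(paste0("B_bg", sprintf("%03d", 1:6)),
                              paste0("F_fg", sprintf("%03d", 1:3)),
                              "AMF_ag001"),
                  multipliers = stats::setNames(
                    ifelse(ref$treatments %in% c("MI3", "MI4", "MI5", "MI6"),
                           4, 0.2), ref$treatments),
                  couple = "m025_2", beta = 3.5)),
           ...)
}

# reduced analysis settings for tests (permutation counts at their floor)
test_config <- function(seed = 1, ...) {
  run_config(rf_trees = 200, rf_perm = 99, n_perm = 199, seed = seed, ...)
}
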