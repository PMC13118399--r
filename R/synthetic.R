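#' Specification for the synthetic study generator
#'
#' Describes a synthetic version of the study the pipeline analyses:
#' seven cropping systems x three replicates, three marker sets
#' (bacteria, non-AMF fungi, AMF), planted correlated genus modules with
#' treatment-structured activity, and per-sample aggregate profiles whose
#' treatment targets default to the reference trial's printed means and
#' SDs. Module activity can be coupled to the mass proportion of a named
#' size class, which propagates into the aggregate-associated C
#' distribution - the ground truth the keystone analysis must recover.
#'
#' Generative model: each module m has a latent per-sample activity
#' `a_m ~ Normal(multiplier[treatment], 1)`; a member genus g has
#' log-abundance `baseline_g + loading * a_m + Normal(0, noise_sd)`,
#' non-members `baseline_g + Normal(0, noise_sd)`. Per kingdom the
#' log-abundances are softmax-transformed to compositions and sampled
#' multinomially at a depth drawn uniformly from `depth_range`. Aggregate
#' mass proportions are the treatment targets, shifted by
#' `beta * a_m` percentage points in the coupled class, plus Gaussian
#' noise, renormalized to 100.
#'
#' @param design a [study_design()].
#' @param n_bacteria,n_fungi,n_amf genus counts per kingdom.
#' @param modules list of planted modules; each a list with `name`,
#'   `members` (prefixed genus ids), `multipliers` (named per treatment,
#'   all > 0), `couple` (size-class code or `NA`) and `beta` (percentage
#'   points of mass proportion per unit activity).
#' @param loading common module loading on member log-abundance.
#' @param noise_sd SD of the genus-level log-abundance noise.
#' @param member_offset additive log-abundance offset for module members;
#'   the negative default keeps the planted members' combined share of
#'   each composition modest, so the correlation induced among
#'   non-members by compositional closure stays negligible.
#' @param baseline_sd SD of the per-genus log-abundance baseline.
#' @param depth_range sequencing depth range (uniform draw per sample).
#' @param mass_mean,mass_sd treatment x class targets for mass
#'   proportions (%); defaults: the reference trial.
#' @param soc_mean,soc_sd treatment x class targets for SOC
#'   concentration (g kg^-1); defaults: the reference trial.
#' @param bulk_sd SD of the bulk-SOC measurement noise (g kg^-1).
#' @return A validated list of class `"sim_spec"`.
#' @export
sim_spec <- function(design = default_design(),
                     n_bacteria = 120, n_fungi = 60, n_amf = 25,
                     modules = default_modules(),
                     loading = 0.5, noise_sd = 0.4, baseline_sd = 1.0,
                     member_offset = -0.8,
                     depth_range = c(10000, 15000),
                     mass_mean = study_reference()$mass_mean,
                     mass_sd = study_reference()$mass_sd,
                     soc_mean = study_reference()$soc_mean,
                     soc_sd = study_reference()$soc_sd,
                     bulk_sd = 0.5) {
  spec <- list(design = design, n_bacteria = n_bacteria, n_fungi = n_fungi,
               n_amf = n_amf, modules = modules, loading = loading,
               noise_sd = noise_sd, baseline_sd = baseline_sd,
               member_offset = member_offset,
               depth_range = depth_range, mass_mean = as.matrix(mass_mean),
               mass_sd = as.matrix(mass_sd), soc_mean = as.matrix(soc_mean),
               soc_sd = as.matrix(soc_sd), bulk_sd = bulk_sd)
  validate_sim_spec(spec)
  class(spec) <- "sim_spec"
  spec
}

#' Default planted modules
#'
#' Three modules emulating the ecological clusters the analysis targets:
#' an intercropping-enriched module coupled positively to small
#' macroaggregate (0.25-2 mm) mass, a monoculture-type module coupled
#' negatively to the >2 mm class, and an uncoupled module enriched under
#' a single treatment. Member ids use the kingdom prefixes.
#'
#' @return List of module definitions for [sim_spec()].
#' @export
default_modules <- function() {
  mult <- function(high, base = 0.2, hi = 4) {
    tr <- study_reference()$treatments
    stats::setNames(ifelse(tr %in% high, hi, base), tr)
  }
  list(
    list(name = "planted_intercrop",
         members = c(paste0("B_bg", sprintf("%03d", 1:8)),
                     paste0("F_fg", sprintf("%03d", 1:4)),
                     paste0("AMF_ag", sprintf("%03d", 1:2))),
         multipliers = mult(c("MI3", "MI4", "MI5", "MI6")),
         couple = "m025_2", beta = 3.5),
    list(name = "planted_monoculture",
         members = c(paste0("B_bg", sprintf("%03d", 9:16)),
                     paste0("F_fg", sprintf("%03d", 5:7)),
                     "AMF_ag003"),
         multipliers = mult(c("MM", "MI1")),
         couple = "gt2", beta = -1.0),
    list(name = "planted_neutral",
         members = c(paste0("B_bg", sprintf("%03d", 17:22)),
                     paste0("F_fg", sprintf("%03d", 8:10)),
                     "AMF_ag004"),
         multipliers = mult("MI6"),
         couple = NA_character_, beta = 0)
  )
}

sim_genus_ids <- function(spec) {
  list(bacteria = paste0("B_bg", sprintf("%03d", seq_len(spec$n_bacteria))),
       non_amf = paste0("F_fg", sprintf("%03d", seq_len(spec$n_fungi))),
       amf = paste0("AMF_ag", sprintf("%03d", seq_len(spec$n_amf))))
}

validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec$design, "study_design"))
  tr <- unique(spec$design$treatment)
  ids <- unlist(sim_genus_ids(spec))
  for (m in spec$modules) {
    unknown <- setdiff(m$members, ids)
    if (length(unknown)) stopf("module '%s' references unknown genus: %s",
                               m$name, paste(unknown, collapse = ", "))
    if (!all(tr %in% names(m$multipliers))) {
      stopf("module '%s' lacks multipliers for all treatments", m$name)
    }
    if (any(m$multipliers <= 0)) stopf("module multipliers must be > 0")
    if (!is.na(m$couple) && !m$couple %in% class_codes()) {
      stopf("unknown coupled size class '%s'", m$couple)
    }
  }
  members <- unlist(lapply(spec$modules, `[[`, "members"))
  if (anyDuplicated(members)) stopf("modules must not share member genera")
  if (spec$loading < 0) stopf("loading must be >= 0")
  if (any(spec$depth_range <= 0) || spec$depth_range[1] > spec$depth_range[2]) {
    stopf("depth_range must be positive and increasing")
  }
  if (!all(rownames(spec$mass_mean) %in% tr) || !all(tr %in% rownames(spec$mass_mean))) {
    stopf("mass targets must cover exactly the design treatments")
  }
  bad <- abs(rowSums(spec$mass_mean) - 100) > 0.5
  if (any(bad)) stopf("mass-proportion targets must sum to 100 +/- 0.5%% (violated: %s)",
                      paste(rownames(spec$mass_mean)[bad], collapse = ", "))
  invisible(spec)
}

#' Simulate the three genus abundance tables
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed; identical spec + seed gives identical tables.
#' @return List with `tables` (named list of counts
#'   [abundance_table()]s), and `truth`: module membership, the latent
#'   activity matrix (modules x samples), couplings and `drivers` (the
#'   members of coupled modules).
#' @export
simulate_abundances <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  ids <- sim_genus_ids(spec)
  samples <- spec$design$sample_id
  n_s <- length(samples)
  with_seed(stage_seed(seed, "abundances"), {
    activity <- t(vapply(spec$modules, function(m) {
      stats::rnorm(n_s, mean = m$multipliers[spec$design$treatment], sd = 1)
    }, numeric(n_s)))
    rownames(activity) <- vapply(spec$modules, `[[`, "", "name")
    colnames(activity) <- samples
    tables <- lapply(names(ids), function(kd) {
      g <- ids[[kd]]
      baseline <- stats::rnorm(length(g), 0, spec$baseline_sd)
      logab <- matrix(baseline, length(g), n_s) +
        matrix(stats::rnorm(length(g) * n_s, 0, spec$noise_sd), length(g), n_s)
      for (mi in seq_along(spec$modules)) {
        m <- spec$modules[[mi]]
        rows <- match(intersect(m$members, g), g)
        if (length(rows)) {
          logab[rows, ] <- logab[rows, ] + spec$member_offset +
            spec$loading * matrix(activity[mi, ], length(rows), n_s, byrow = TRUE)
        }
      }
      prob <- apply(logab, 2, function(v) { e <- exp(v - max(v)); e / sum(e) })
      depth <- round(stats::runif(n_s, spec$depth_range[1], spec$depth_range[2]))
      counts <- vapply(seq_len(n_s), function(s) {
        drop(stats::rmultinom(1, depth[s], prob[, s]))
      }, numeric(length(g)))
      dimnames(counts) <- list(g, samples)
      abundance_table(counts, kingdom = kd, type = "counts", prefix = FALSE)
    })
    names(tables) <- names(ids)
    drivers <- unlist(lapply(spec$modules, function(m) {
      if (!is.na(m$couple) && m$beta != 0) m$members else character(0)
    }))
    list(tables = tables,
         truth = list(
           members = stats::setNames(lapply(spec$modules, `[[`, "members"),
                                     rownames(activity)),
           activity = activity,
           couplings = data.frame(
             module = rownames(activity),
             couple = vapply(spec$modules, `[[`, "", "couple"),
             beta = vapply(spec$modules, `[[`, 0, "beta"),
             stringsAsFactors = FALSE),
           drivers = drivers))
  })
}

#' Simulate per-sample aggregate profiles
#'
#' Fraction mass proportions start from the treatment target means,
#' coupled classes are shifted by `beta * a_m` percentage points, noise
#' is added with the treatment target SDs, and each sample is
#' renormalized onto the 100% simplex (redrawn up to 100 times if a
#' proportion leaves \[0, 100\]). SOC concentrations are targets plus
#' noise; bulk SOC is the mass-weighted mean of the fraction
#' concentrations plus measurement noise.
#'
#' @param spec a [sim_spec()].
#' @param truth the `truth` component of [simulate_abundances()] (its
#'   `activity` matrix drives the coupling); pass `NULL` for no coupling.
#' @param seed integer seed.
#' @return An [aggregate_profiles()] data frame.
#' @export
simulate_aggregates <- function(spec, truth = NULL, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  samples <- spec$design$sample_id
  tr <- spec$design$treatment
  if (!is.null(truth) && !identical(colnames(truth$activity), samples)) {
    stopf("activities must cover every design sample")
  }
  cls <- class_codes()
  with_seed(stage_seed(seed, "aggregates"), {
    prop <- matrix(NA_real_, length(samples), 4,
                   dimnames = list(samples, cls))
    for (s in seq_along(samples)) {
      target <- spec$mass_mean[tr[s], ]
      if (!is.null(truth)) {
        for (mi in seq_len(nrow(truth$activity))) {
          cp <- truth$couplings$couple[mi]
          if (!is.na(cp)) {
            target[cp] <- target[cp] +
              truth$couplings$beta[mi] * truth$activity[mi, s]
          }
        }
      }
      ok <- FALSE
      for (try in 1:100) {
        p <- target + stats::rnorm(4, 0, spec$mass_sd[tr[s], ])
        if (all(p > 0 & p < 100)) { ok <- TRUE; break }
      }
      if (!ok) stopf("infeasible spec: proportions outside [0, 100] after 100 redraws")
      prop[s, ] <- 100 * p / sum(p)
    }
    soc <- matrix(NA_real_, length(samples), 4, dimnames = list(samples, cls))
    for (s in seq_along(samples)) {
      for (try in 1:100) {
        v <- spec$soc_mean[tr[s], ] + stats::rnorm(4, 0, spec$soc_sd[tr[s], ])
        if (all(v > 0)) break
        if (try == 100) stopf("infeasible spec: negative SOC after 100 redraws")
      }
      soc[s, ] <- v
    }
    bulk <- rowSums(prop / 100 * soc) + stats::rnorm(length(samples), 0, spec$bulk_sd)
    mass <- prop / 100 * 60  # grams, on the 60 g wet-sieving input scale
    df <- data.frame(sample_id = samples,
                     stats::setNames(as.data.frame(mass), paste0("mass_", cls)),
                     stats::setNames(as.data.frame(soc), paste0("soc_", cls)),
                     bulk_soc = bulk, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    aggregate_profiles(df)
  })
}

#' Simulate a complete synthetic study
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed.
#' @return List: `design`, `tables`, `profiles`, `truth`.
#' @export
simulate_study <- function(spec = sim_spec(), seed = 1L) {
  ab <- simulate_abundances(spec, seed)
  profiles <- simulate_aggregates(spec, ab$truth, seed)
  list(design = spec$design, tables = ab$tables, profiles = profiles,
       truth = ab$truth)
}

#' Write a simulated study to disk
#'
#' Emits the pipeline's input TSV formats plus `truth.json` (module
#' membership, activities, couplings).
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kd in names(sim$tables)) {
    write_abundance_table(sim$tables[[kd]],
                          file.path(dir, paste0("abundance_", kd, ".tsv")))
  }
  write_aggregate_profiles(sim$profiles, file.path(dir, "aggregates.tsv"))
  utils::write.table(as.data.frame(sim$design), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$activity <- as.data.frame(t(truth$activity))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
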