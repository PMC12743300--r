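## Seeded synthetic-data generators. Each generator is a pure function of
## (parameters, seed): identical inputs give identical outputs. Defaults
## emulate the experiment the package targets: a 3e5 cells/ml inoculum with
## a ~3-day lag, nine assay temperatures between 16 and 38 degC, ASV
## communities of 13-22 taxa with one ~40-50% dominant genus over 3
## replicates, and lognormal metabolite concentrations with class-level
## group effects.

#' Trajectory model for a simulated cell-count time series
#'
#' Lag/exponential/stationary trajectory: flat at `n0` until `lag_days`,
#' then logistic growth towards `carrying_capacity` at rate `mu`.
#' Measurement noise is multiplicative lognormal with log-sd `noise_sigma`
#' (flow-cytometry counting error scales with magnitude).
#'
#' @param n0 initial cell density (cells/ml), > 0. Default 3e5, the
#'   experiment's inoculation density.
#' @param mu specific growth rate (day^-1).
#' @param carrying_capacity stationary ceiling (cells/ml), >= `n0`.
#' @param lag_days lag duration (days), >= 0.
#' @param noise_sigma sd of the lognormal noise on the log scale, >= 0.
#' @return An object of class `trajectory_model`.
#' @export
trajectory_model <- function(n0 = 3e5, mu = 0.7, carrying_capacity = 1e8,
                             lag_days = 3, noise_sigma = 0.05) {
  check_number(n0, "n0", lower = 0, strict_lower = TRUE)
  check_number(mu, "mu")
  check_number(carrying_capacity, "carrying_capacity", lower = n0)
  check_number(lag_days, "lag_days", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  structure(list(n0 = n0, mu = mu, carrying_capacity = carrying_capacity,
                 lag_days = lag_days, noise_sigma = noise_sigma),
            class = "trajectory_model")
}

## noise-free expectation of the trajectory
trajectory_expectation <- function(model, days) {
  t_eff <- pmax(days - model$lag_days, 0)
  K <- model$carrying_capacity; n0 <- model$n0
  e <- exp(model$mu * t_eff)
  K * n0 * e / (K + n0 * (e - 1))
}

#' Simulate a cell-count growth series
#'
#' Deterministic lag-logistic expectation (see [trajectory_model()])
#' multiplied by lognormal measurement noise. Counts are strictly positive.
#'
#' @param model a [trajectory_model()].
#' @param days sampling times (days), non-empty, non-decreasing, >= 0.
#'   Duplicated days are allowed (repeated measurements).
#' @param seed integer seed.
#' @param sample_id,replicate,temperature_c series metadata.
#' @return A [growth_series()].
#' @export
simulate_growth_series <- function(model, days = 0:10, seed = 1L,
                                   sample_id = "S1", replicate = 1L,
                                   temperature_c = 26) {
  if (!inherits(model, "trajectory_model")) model <- do.call(trajectory_model, model)
  days <- as.numeric(days)
  if (length(days) == 0L || any(days < 0) || any(diff(days) < 0))
    stop_pt("days must be non-empty, non-decreasing and >= 0",
            class = "invalid_parameter")
  expectation <- trajectory_expectation(model, days)
  counts <- if (model$noise_sigma > 0) {
    withr_seed(seed, expectation * exp(stats::rnorm(length(days),
                                                    0, model$noise_sigma)))
  } else expectation
  ## strictly increasing days are required downstream; jitter exact
  ## duplicates by a half-sample offset only if the caller passed them
  if (any(diff(days) == 0)) days <- days + seq_along(days) * 1e-9
  growth_series(days, counts, sample_id = sample_id, replicate = replicate,
                temperature_c = temperature_c)
}

## evaluate `expr` under a local RNG state; `seed` is forced BEFORE the
## RNG snapshot so that a caller passing e.g. seed = sample.int(n, 1) does
## not have its own draw rolled back by the restore
withr_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate growth-rate observations along a thermal performance curve
#'
#' Each observation is `norberg_growth(T, params)` plus Gaussian noise.
#'
#' @param params a [norberg_params()] object.
#' @param temps assay temperatures (deg C); default the experiment's nine
#'   assay temperatures.
#' @param n_reps replicates per temperature (default 3).
#' @param noise_sd Gaussian noise sd (day^-1); 0 gives the exact curve.
#' @param seed integer seed.
#' @return data.frame with columns `temperature_c`, `replicate`,
#'   `growth_rate_per_day`.
#' @export
simulate_thermal_observations <- function(params,
                                          temps = c(16, 18, 22, 24, 26,
                                                    30, 34, 36, 38),
                                          n_reps = 3L, noise_sd = 0.1,
                                          seed = 1L) {
  if (length(temps) == 0L)
    stop_pt("temperature list must be non-empty", class = "invalid_parameter")
  if (n_reps < 1L)
    stop_pt("n_reps must be >= 1", class = "invalid_parameter")
  check_number(noise_sd, "noise_sd", lower = 0)
  tab <- expand.grid(replicate = seq_len(n_reps),
                     temperature_c = as.numeric(temps))[, 2:1]
  mu <- norberg_growth(tab$temperature_c, params)
  tab$growth_rate_per_day <- if (noise_sd > 0) {
    withr_seed(seed, mu + stats::rnorm(nrow(tab), 0, noise_sd))
  } else mu
  tab
}

#' Community profile for a synthetic ASV table
#'
#' Expected rank-abundance structure of one group's microbiome: a dominant
#' taxon at `dominant_fraction` plus a geometric low-abundance tail over
#' the remaining ranks. Defaults emulate a diatom microbiome with a ~45%
#' dominant genus, ~17 ASVs and 3 replicate cultures.
#'
#' @param n_asvs number of ASVs with nonzero expected abundance.
#' @param dominant_fraction expected relative abundance of the top ASV,
#'   in (0, 1).
#' @param tail_decay geometric decay rate of the rank-abundance tail,
#'   in (0, 1].
#' @param depth reads per sample.
#' @param n_replicates samples in the group.
#' @return An object of class `community_profile` including the expected
#'   relative abundances (`expected`, sums to 1).
#' @export
community_profile <- function(n_asvs = 17L, dominant_fraction = 0.45,
                              tail_decay = 0.7, depth = 10000L,
                              n_replicates = 3L) {
  check_number(n_asvs, "n_asvs", lower = 1)
  check_number(dominant_fraction, "dominant_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (dominant_fraction >= 1)
    stop_pt("dominant_fraction must be < 1", class = "invalid_parameter")
  check_number(tail_decay, "tail_decay", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(depth, "depth", lower = 1)
  check_number(n_replicates, "n_replicates", lower = 1)
  if (n_asvs < 2L)
    stop_pt("dominant fraction < 1 with no tail ranks is infeasible",
            class = "invalid_parameter")
  tail <- tail_decay^(0:(n_asvs - 2L))
  expected <- c(dominant_fraction,
                (1 - dominant_fraction) * tail / sum(tail))
  structure(list(n_asvs = as.integer(n_asvs),
                 dominant_fraction = dominant_fraction,
                 tail_decay = tail_decay, depth = as.integer(depth),
                 n_replicates = as.integer(n_replicates),
                 expected = expected),
            class = "community_profile")
}

#' Simulate an ASV count table for one or more groups
#'
#' Groups draw their per-sample counts multinomially at the profile's depth
#' from the profile's expected relative abundances (dominant taxon at rank
#' 1, geometric tail over the remaining ranks). All groups share one ASV
#' pool ordered by rank, so a group with fewer ASVs than another lacks the
#' deepest tail ranks — which is what makes extinction accounting between
#' synthetic groups meaningful. A synthetic genus/family/order/phylum
#' taxonomy and a sample-to-group map are attached.
#'
#' @param profiles named list: group label -> [community_profile()].
#' @param seed integer seed.
#' @return An [asv_table()].
#' @examples
#' tab <- simulate_asv_table(list(LA = community_profile(n_asvs = 13),
#'                                LW = community_profile(n_asvs = 17)),
#'                           seed = 1)
#' @export
simulate_asv_table <- function(profiles, seed = 1L) {
  if (length(profiles) < 1L || is.null(names(profiles)) ||
      any(!nzchar(names(profiles))))
    stop_pt("profiles must be a named list with at least one group",
            class = "invalid_parameter")
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "community_profile")) p else do.call(community_profile, p))
  pool <- max(vapply(profiles, `[[`, integer(1), "n_asvs"))
  asv_ids <- sprintf("ASV%03d", seq_len(pool))

  counts_rows <- list()
  sample_map <- list()
  withr_seed(seed, {
    for (g in names(profiles)) {
      pr <- profiles[[g]]
      p <- c(pr$expected, rep(0, pool - pr$n_asvs))
      for (r in seq_len(pr$n_replicates)) {
        sid <- sprintf("%s_r%d", g, r)
        counts_rows[[sid]] <- as.integer(stats::rmultinom(1, pr$depth, p))
        sample_map[[sid]] <- data.frame(sample_id = sid, group = g,
                                        replicate = r)
      }
    }
  })
  counts <- do.call(rbind, counts_rows)
  colnames(counts) <- asv_ids
  taxonomy <- synthetic_taxonomy(asv_ids)
  asv_table(counts, taxonomy, do.call(rbind, sample_map))
}

## deterministic synthetic taxonomy: a dominant genus at rank 1, distinct
## genera down the tail, coarser ranks shared in blocks
synthetic_taxonomy <- function(asv_ids) {
  n <- length(asv_ids)
  data.frame(
    asv_id = asv_ids,
    genus = sprintf("Genus%02d", seq_len(n)),
    family = sprintf("Family%02d", (seq_len(n) - 1L) %/% 3L + 1L),
    order = sprintf("Order%02d", (seq_len(n) - 1L) %/% 6L + 1L),
    phylum = ifelse(seq_len(n) <= ceiling(0.9 * n), "Phylum01", "Phylum02"))
}

#' Effect specification for a synthetic metabolite table
#'
#' @param class_map named character vector: metabolite -> class label
#'   (e.g. `amino_acid`, `carbohydrate`, `other`).
#' @param baseline_mean named numeric: per-metabolite lognormal location
#'   (meanlog); names must match `class_map`.
#' @param group_fold named numeric: per-class multiplicative effect of the
#'   second group relative to the first; every class in `class_map` must
#'   appear; all folds > 0.
#' @param cv coefficient of variation of replicate noise, >= 0.
#' @return An object of class `metabolite_effect_spec`.
#' @export
metabolite_effect_spec <- function(class_map, baseline_mean, group_fold,
                                   cv = 0.1) {
  if (is.null(names(class_map)) || any(!nzchar(names(class_map))))
    stop_pt("class_map must be a named vector (metabolite -> class)",
            class = "invalid_parameter")
  unknown <- setdiff(unique(class_map), names(group_fold))
  if (length(unknown) > 0L)
    stop_pt("class(es) %s missing from group_fold",
            paste(unknown, collapse = ", "), class = "unknown_class")
  if (any(group_fold <= 0))
    stop_pt("group_fold values must be > 0", class = "invalid_parameter")
  check_number(cv, "cv", lower = 0)
  if (is.null(names(baseline_mean)))
    names(baseline_mean) <- names(class_map)
  if (!setequal(names(baseline_mean), names(class_map)))
    stop_pt("baseline_mean names must match class_map names",
            class = "invalid_parameter")
  structure(list(class_map = class_map,
                 baseline_mean = baseline_mean[names(class_map)],
                 group_fold = group_fold, cv = cv),
            class = "metabolite_effect_spec")
}

#' Simulate a metabolite concentration table for two groups
#'
#' Concentrations are lognormal around each metabolite's baseline; samples
#' in the second group are additionally multiplied by their class's
#' `group_fold`. All values are strictly positive.
#'
#' @param spec a [metabolite_effect_spec()].
#' @param n_per_group samples per group, >= 1.
#' @param seed integer seed.
#' @param groups the two group labels (fold applies to the second).
#' @return A [metabolite_table()].
#' @export
simulate_metabolite_table <- function(spec, n_per_group = 3L, seed = 1L,
                                      groups = c("A", "B")) {
  if (!inherits(spec, "metabolite_effect_spec"))
    stop_pt("spec must be a metabolite_effect_spec",
            class = "invalid_parameter")
  if (n_per_group < 1L)
    stop_pt("n_per_group must be >= 1", class = "invalid_parameter")
  if (length(groups) != 2L)
    stop_pt("exactly two group labels required", class = "invalid_parameter")
  mets <- names(spec$class_map)
  sdlog <- sqrt(log(1 + spec$cv^2))
  samples <- c(sprintf("%s_r%d", groups[1], seq_len(n_per_group)),
               sprintf("%s_r%d", groups[2], seq_len(n_per_group)))
  grp <- rep(groups, each = n_per_group)
  fold <- spec$group_fold[spec$class_map]      # per metabolite
  conc <- withr_seed(seed, {
    m <- matrix(exp(stats::rnorm(length(samples) * length(mets),
                                 mean = rep(spec$baseline_mean,
                                            each = length(samples)),
                                 sd = sdlog)),
                nrow = length(samples), ncol = length(mets),
                dimnames = list(samples, mets))
    m[grp == groups[2], ] <-
      sweep(m[grp == groups[2], , drop = FALSE], 2, fold, "*")
    m
  })
  metabolite_table(conc, spec$class_map,
                   data.frame(sample_id = samples, group = grp))
}
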