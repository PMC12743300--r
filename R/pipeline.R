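## Configuration-driven pipeline: simulate -> growth -> tpc -> diversity ->
## metabolites, each stage reading/writing TSV under one output directory
## and recording itself in a JSON run manifest.

STAGE_ORDER <- c("simulate", "growth", "tpc", "diversity", "metabolites")

log_msg <- function(level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)
  threshold <- getOption("phycotherm.log_level", "info")
  if (levels[[level]] >= levels[[threshold]])
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  invisible(NULL)
}

#' Validate a pipeline run configuration
#'
#' Checks the configuration (a nested list, usually parsed from a JSON
#' file) and returns it normalised; on failure, errors with the complete
#' list of problems rather than the first one.
#'
#' @param config a list, or path to a JSON configuration file.
#' @return The normalised configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_pt("config file not found: %s", config, class = "config_error")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  problems <- character()
  stages <- config$stages %||% "all"
  if (identical(stages, "all") || "all" %in% stages) stages <- STAGE_ORDER
  unknown <- setdiff(stages, STAGE_ORDER)
  if (length(unknown) > 0L)
    problems <- c(problems, sprintf("unknown stage name(s): %s",
                                    paste(unknown, collapse = ", ")))
  config$stages <- intersect(STAGE_ORDER, stages)
  if (is.null(config$outdir))
    problems <- c(problems, "`outdir` is required")
  stochastic <- any(c("simulate", "diversity") %in% config$stages)
  if (stochastic && is.null(config$seed))
    problems <- c(problems, "`seed` is required when a stochastic stage is enabled")
  if (!"simulate" %in% config$stages) {
    for (st in intersect(c("growth", "tpc", "diversity", "metabolites"),
                         config$stages)) {
      ins <- stage_inputs(config, st)
      miss <- ins[!vapply(ins, file.exists, logical(1))]
      if (length(miss) > 0L)
        problems <- c(problems, sprintf(
          "stage `%s` input(s) missing: %s", st,
          paste(unlist(miss), collapse = ", ")))
    }
  }
  if (length(problems) > 0L)
    stop_pt("invalid configuration:\n- %s",
            paste(problems, collapse = "\n- "), class = "config_error")
  config
}

stage_inputs <- function(config, stage) {
  out <- function(f) file.path(config$outdir %||% ".", f)
  switch(stage,
    growth = list(config$growth$input %||% out("growth_series.tsv")),
    tpc = list(config$tpc$input %||% out("thermal_observations.tsv")),
    diversity = list(
      config$diversity$counts %||% out("asv_counts.tsv"),
      config$diversity$taxonomy %||% out("asv_taxonomy.tsv"),
      config$diversity$samples %||% out("asv_samples.tsv")),
    metabolites = list(
      config$metabolites$concentrations %||% out("metabolite_concentrations.tsv"),
      config$metabolites$classes %||% out("metabolite_classes.tsv"),
      config$metabolites$samples %||% out("metabolite_samples.tsv")),
    list())
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the selected stages in dependency order
#' (simulate, growth, tpc, diversity, metabolites), writes every stage
#' output as TSV under `config$outdir`, and writes a `manifest.json`
#' recording inputs, parameters, seed, outputs and timings. Re-running
#' with the same configuration and seed reproduces identical numeric
#' outputs.
#'
#' @param config a list or path to a JSON config file; see the package
#'   vignette for the schema. Minimal example:
#'   `list(stages = "all", seed = 1, outdir = tempdir())`.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "phycotherm",
                   version = as.character(utils::packageVersion("phycotherm")),
                   seed = config$seed, stages = list())
  for (st in config$stages) {
    log_msg("info", "stage `%s` starting", st)
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(
      switch(st,
             simulate = stage_simulate(config),
             growth = stage_growth(config),
             tpc = stage_tpc(config),
             diversity = stage_diversity(config),
             metabolites = stage_metabolites(config)),
      error = function(e) {
        stop_pt("stage `%s` failed: %s", st, conditionMessage(e),
                class = "stage_failure")
      })
    manifest$stages[[st]] <- list(
      outputs = outputs$files,
      parameters = outputs$parameters,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    log_msg("info", "stage `%s` done (%d outputs)", st,
            length(outputs$files))
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg("info", "manifest written to %s", manifest_path)
  invisible(manifest)
}

## ---- simulate ----

default_sim_config <- function() {
  list(
    thermal = list(
      groups = list(
        LA = list(traits = list(mu_max = 2.09, t_opt = 28.74,
                                ct_min = 14.2, ct_max = 38.19)),
        LW = list(traits = list(mu_max = 2.41, t_opt = 28.95,
                                ct_min = 14.2, ct_max = 38.39))),
      temps = c(16, 18, 22, 24, 26, 30, 34, 36, 38),
      n_reps = 3, noise_sd = 0.1),
    growth = list(
      groups = list(
        LA = list(n0 = 3e5, mu = 0.9, carrying_capacity = 5e7,
                  lag_days = 3, noise_sigma = 0.05),
        LW = list(n0 = 3e5, mu = 1.0, carrying_capacity = 2e7,
                  lag_days = 4, noise_sigma = 0.05)),
      days = 0:10, n_reps = 3, temperature_c = 26),
    community = list(
      groups = list(
        LA = list(n_asvs = 13, dominant_fraction = 0.50, tail_decay = 0.7,
                  depth = 10000, n_replicates = 3),
        LW = list(n_asvs = 17, dominant_fraction = 0.43, tail_decay = 0.7,
                  depth = 10000, n_replicates = 3))),
    metabolites = list(
      n_per_group = 3, cv = 0.1, groups = c("LA", "LW"),
      n_amino = 10, n_carb = 5, n_other = 12,
      group_fold = list(amino_acid = 1.6, carbohydrate = 0.35, other = 1.0)))
}

merge_config <- function(default, user) {
  if (is.null(user)) return(default)
  for (k in names(user)) {
    default[[k]] <- if (is.list(default[[k]]) && is.list(user[[k]]))
      merge_config(default[[k]], user[[k]]) else user[[k]]
  }
  default
}

group_params <- function(g) {
  if (!is.null(g$params)) as_norberg_params(g$params)
  else if (!is.null(g$traits)) params_from_traits(g$traits)
  else stop_pt("thermal group needs `params` or `traits`",
               class = "config_error")
}

stage_simulate <- function(config) {
  sim <- merge_config(default_sim_config(), config$simulate)
  outdir <- config$outdir
  seed <- config$seed
  files <- character()
  out <- function(f) file.path(outdir, f)

  ## thermal observations per group
  th <- sim$thermal
  obs <- do.call(rbind, lapply(names(th$groups), function(g) {
    tab <- simulate_thermal_observations(
      group_params(th$groups[[g]]), temps = unlist(th$temps),
      n_reps = th$n_reps, noise_sd = th$noise_sd,
      seed = derive_stream_seed(seed, paste0("thermal_", g)))
    cbind(group = g, tab)
  }))
  files <- c(files, write_thermal_observations(obs, out("thermal_observations.tsv")))

  ## cell-count trajectories per group x replicate
  gr <- sim$growth
  series <- list()
  for (g in names(gr$groups)) {
    model <- do.call(trajectory_model, gr$groups[[g]])
    for (r in seq_len(gr$n_reps)) {
      series[[paste0(g, r)]] <- simulate_growth_series(
        model, days = unlist(gr$days),
        seed = derive_stream_seed(seed, paste0("growth_", g, "_", r)),
        sample_id = g, replicate = r, temperature_c = gr$temperature_c)
    }
  }
  files <- c(files, write_growth_series(series, out("growth_series.tsv")))

  ## ASV community
  profiles <- lapply(sim$community$groups, function(p)
    do.call(community_profile, p))
  tab <- simulate_asv_table(profiles,
                            seed = derive_stream_seed(seed, "community"))
  files <- c(files, write_asv_table(tab, out("asv_counts.tsv"),
                                    out("asv_taxonomy.tsv"),
                                    out("asv_samples.tsv")))

  ## metabolites
  mb <- sim$metabolites
  spec <- build_metabolite_spec(mb)
  met <- simulate_metabolite_table(spec, n_per_group = mb$n_per_group,
                                   seed = derive_stream_seed(seed, "metabolites"),
                                   groups = unlist(mb$groups))
  files <- c(files, write_metabolite_table(met,
                                           out("metabolite_concentrations.tsv"),
                                           out("metabolite_classes.tsv"),
                                           out("metabolite_samples.tsv")))
  list(files = unname(files), parameters = sim)
}

build_metabolite_spec <- function(mb) {
  if (!is.null(mb$class_map)) {
    class_map <- unlist(mb$class_map)
    baseline <- unlist(mb$baseline_mean %||%
                         stats::setNames(rep(0, length(class_map)),
                                         names(class_map)))
  } else {
    class_map <- c(
      stats::setNames(rep("amino_acid", mb$n_amino),
                      sprintf("aa_%02d", seq_len(mb$n_amino))),
      stats::setNames(rep("carbohydrate", mb$n_carb),
                      sprintf("carb_%02d", seq_len(mb$n_carb))),
      stats::setNames(rep("other", mb$n_other),
                      sprintf("org_%02d", seq_len(mb$n_other))))
    baseline <- stats::setNames(rep(0, length(class_map)), names(class_map))
  }
  metabolite_effect_spec(class_map, baseline, unlist(mb$group_fold),
                         cv = mb$cv)
}

## ---- growth ----

stage_growth <- function(config) {
  out <- function(f) file.path(config$outdir, f)
  opt <- config$growth
  input <- opt$input %||% out("growth_series.tsv")
  series <- read_growth_series(input)
  rows <- lapply(series, function(s) {
    est <- growth_rate(s, min_points = opt$min_points %||% 3L,
                       r2_threshold = opt$r2_threshold %||% 0.95)
    lag <- lag_time(s, fold_threshold = opt$fold_threshold %||% 2.0)
    if (!lag$reached)
      log_msg("warning", "series %s rep %d: lag threshold never reached",
              s$sample_id, s$replicate)
    data.frame(sample_id = s$sample_id, temperature_c = s$temperature_c,
               replicate = s$replicate, mu = est$mu, stderr = est$stderr,
               r2 = est$r_squared, window_start = est$window[1],
               window_end = est$window[2], lag_days = lag$days,
               lag_reached = lag$reached, max_cells = stationary_max(s))
  })
  f <- write_tsv(do.call(rbind, rows), out("growth_estimates.tsv"))
  list(files = unname(f),
       parameters = list(input = input,
                         min_points = opt$min_points %||% 3L,
                         r2_threshold = opt$r2_threshold %||% 0.95,
                         fold_threshold = opt$fold_threshold %||% 2.0))
}

## ---- tpc ----

stage_tpc <- function(config) {
  out <- function(f) file.path(config$outdir, f)
  opt <- config$tpc
  input <- opt$input %||% out("thermal_observations.tsv")
  obs <- read_thermal_observations(input)
  if (is.null(obs$group)) obs$group <- "all"
  fraction <- opt$fraction %||% 0.8
  fits <- do.call(rbind, lapply(split(obs, list(obs$group, obs$replicate),
                                      drop = TRUE), function(d) {
    fit <- fit_norberg(data.frame(temperature = d$temperature_c,
                                  growth_rate = d$growth_rate_per_day))
    tr <- derive_traits(fit$params, fraction = fraction)
    data.frame(group = d$group[1], replicate = d$replicate[1],
               a = fit$params$a, b = fit$params$b, z = fit$params$z,
               w = fit$params$w, ssr = fit$ssr, converged = fit$converged,
               mu_max = tr$mu_max, t_opt = tr$t_opt, ct_min = tr$ct_min,
               ct_max = tr$ct_max, b80 = tr$b80)
  }))
  files <- write_tsv(fits, out("tpc_fits.tsv"))
  groups <- unique(fits$group)
  if (length(groups) >= 2L &&
      all(table(fits$group)[groups[1:2]] >= 2L)) {
    cmp <- compare_traits(fits[fits$group == groups[1], ],
                          fits[fits$group == groups[2], ])
    cmp <- cbind(group_a = groups[1], group_b = groups[2], cmp)
    files <- c(files, write_tsv(cmp, out("tpc_comparison.tsv")))
  }
  list(files = unname(files),
       parameters = list(input = input, fraction = fraction))
}

## ---- diversity ----

stage_diversity <- function(config) {
  out <- function(f) file.path(config$outdir, f)
  opt <- config$diversity
  tab <- read_asv_table(opt$counts %||% out("asv_counts.tsv"),
                        opt$taxonomy %||% out("asv_taxonomy.tsv"),
                        opt$samples %||% out("asv_samples.tsv"))
  tab <- filter_table(tab,
                      drop_singletons = opt$drop_singletons %||% TRUE,
                      drop_taxa = unlist(opt$drop_taxa %||% character()))
  files <- character()

  alpha <- alpha_diversity(tab)
  files <- c(files, write_tsv(alpha$per_sample, out("diversity_per_sample.tsv")),
             write_tsv(alpha$summary, out("diversity_summary.tsv")))

  ra <- relative_abundance(tab, rank = opt$rank %||% "genus")
  files <- c(files, write_tsv(ra$summary, out("relative_abundance.tsv")))

  d <- bray_curtis(tab)
  dm <- data.frame(sample_id = rownames(d), as.data.frame(d),
                   check.names = FALSE)
  files <- c(files, write_tsv(dm, out("bray_curtis.tsv")))

  groups <- unique(sample_groups(tab))
  pm <- permanova(d, sample_groups(tab),
                  n_permutations = opt$n_permutations %||% 999L,
                  seed = derive_stream_seed(config$seed %||% 1L, "permanova"))
  files <- c(files, write_tsv(data.frame(pseudo_f = pm$pseudo_f,
                                         df_among = pm$df_among,
                                         df_within = pm$df_within,
                                         p = pm$p,
                                         n_permutations = pm$n_permutations),
                              out("permanova.tsv")))

  if (length(groups) >= 2L) {
    ref <- opt$reference_group %||% groups[1]
    ext <- do.call(rbind, lapply(setdiff(groups, ref), function(g) {
      e <- extinctions(tab, ref, g)
      data.frame(reference = ref, target = g, extinctions = e$count,
                 asvs = paste(e$asvs, collapse = ","))
    }))
    files <- c(files, write_tsv(ext, out("extinctions.tsv")))
    sh <- shared_asvs(tab, groups)
    files <- c(files, write_tsv(
      data.frame(region = names(sh$regions),
                 count = as.integer(sh$regions)),
      out("shared_asvs.tsv")))
  }
  list(files = unname(files),
       parameters = list(rank = opt$rank %||% "genus",
                         drop_singletons = opt$drop_singletons %||% TRUE,
                         n_permutations = opt$n_permutations %||% 999L))
}

## ---- metabolites ----

stage_metabolites <- function(config) {
  out <- function(f) file.path(config$outdir, f)
  opt <- config$metabolites
  tab <- read_metabolite_table(opt$concentrations %||% out("metabolite_concentrations.tsv"),
                               opt$classes %||% out("metabolite_classes.tsv"),
                               opt$samples %||% out("metabolite_samples.tsv"))
  files <- character()
  fr <- class_fractions(tab)
  files <- c(files, write_tsv(fr$summary, out("metabolite_fractions.tsv")))

  groups <- unique(met_groups(tab))
  if (length(groups) >= 2L) {
    fg <- unlist(opt$fold_groups %||% groups[c(2, 1)])
    fc <- fold_change(tab, fg[1], fg[2],
                      pseudocount = opt$pseudocount %||% 0)
    if (any(fc$error))
      log_msg("warning", "%d metabolite(s) with zero denominator mean",
              sum(fc$error))
    files <- c(files, write_tsv(fc, out("metabolite_fold_change.tsv")))
    tests <- do.call(rbind, lapply(unique(tab$class_map), function(cl) {
      ct <- class_group_test(tab, cl, groups = groups[1:2])
      data.frame(class = cl, F = ct$F, df_num = ct$df_num,
                 df_den = ct$df_den, p = ct$p)
    }))
    files <- c(files, write_tsv(tests, out("metabolite_class_tests.tsv")))
  }
  list(files = unname(files),
       parameters = list(pseudocount = opt$pseudocount %||% 0))
}
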