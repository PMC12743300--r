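## Tab-separated I/O. All tables are written with a one-line header, no
## quoting, no row names.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required = character()) {
  if (!file.exists(path))
    stop_pt("input file not found: %s", path, class = "io_error")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_pt("%s lacks column(s): %s", path, paste(missing, collapse = ", "),
            class = "io_error")
  df
}

#' Write growth series to a TSV file
#'
#' Long format with columns `sample_id`, `replicate`, `temperature_c`,
#' `day`, `cells_per_ml`.
#'
#' @param series a [growth_series()] or list of them.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_growth_series <- function(series, path) {
  if (inherits(series, "growth_series")) series <- list(series)
  long <- do.call(rbind, lapply(series, function(s)
    data.frame(sample_id = s$sample_id, replicate = s$replicate,
               temperature_c = s$temperature_c,
               day = s$observations$day,
               cells_per_ml = s$observations$cells_per_ml)))
  write_tsv(long, path)
}

#' Read growth series from a TSV file
#'
#' @param path file written by [write_growth_series()] (columns
#'   `sample_id`, `replicate`, `temperature_c`, `day`, `cells_per_ml`).
#' @return A list of [growth_series()], one per
#'   (sample_id, replicate, temperature_c) combination.
#' @export
read_growth_series <- function(path) {
  df <- read_tsv(path, c("sample_id", "replicate", "temperature_c",
                         "day", "cells_per_ml"))
  key <- interaction(df$sample_id, df$replicate, df$temperature_c,
                     drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$day), ]
    growth_series(d$day, d$cells_per_ml, sample_id = d$sample_id[1],
                  replicate = d$replicate[1],
                  temperature_c = d$temperature_c[1])
  })
}

#' Write thermal growth-rate observations to TSV
#'
#' @param observations data.frame as returned by
#'   [simulate_thermal_observations()], plus an optional `group` column.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_thermal_observations <- function(observations, path) {
  write_tsv(observations, path)
}

#' Read thermal growth-rate observations from TSV
#'
#' @param path file with columns `temperature_c`, `replicate`,
#'   `growth_rate_per_day` and optionally `group`.
#' @return data.frame.
#' @export
read_thermal_observations <- function(path) {
  read_tsv(path, c("temperature_c", "replicate", "growth_rate_per_day"))
}

#' Write an ASV table as three TSV files
#'
#' Long-format counts (`sample_id`, `asv_id`, `count`), sidecar taxonomy
#' (`asv_id`, `genus`, `family`, `order`, `phylum`) and sample map
#' (`sample_id`, `group`, `replicate`).
#'
#' @param table an [asv_table()].
#' @param counts_path,taxonomy_path,samples_path output files.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_asv_table <- function(table, counts_path, taxonomy_path,
                            samples_path) {
  long <- data.frame(
    sample_id = rep(rownames(table$counts), times = ncol(table$counts)),
    asv_id = rep(colnames(table$counts), each = nrow(table$counts)),
    count = as.vector(table$counts))
  long <- long[long$count > 0, ]
  write_tsv(long, counts_path)
  write_tsv(table$taxonomy, taxonomy_path)
  write_tsv(table$sample_map[, c("sample_id", "group", "replicate")],
            samples_path)
  invisible(c(counts = counts_path, taxonomy = taxonomy_path,
              samples = samples_path))
}

#' Read an ASV table from its three TSV files
#'
#' @param counts_path,taxonomy_path,samples_path files written by
#'   [write_asv_table()].
#' @return An [asv_table()].
#' @export
read_asv_table <- function(counts_path, taxonomy_path, samples_path) {
  long <- read_tsv(counts_path, c("sample_id", "asv_id", "count"))
  taxonomy <- read_tsv(taxonomy_path, c("asv_id"))
  samples <- read_tsv(samples_path, c("sample_id", "group"))
  asv_ids <- taxonomy$asv_id
  sample_ids <- samples$sample_id
  counts <- matrix(0L, length(sample_ids), length(asv_ids),
                   dimnames = list(sample_ids, asv_ids))
  counts[cbind(match(long$sample_id, sample_ids),
               match(long$asv_id, asv_ids))] <- as.integer(long$count)
  asv_table(counts, taxonomy, samples)
}

#' Write a metabolite table as three TSV files
#'
#' Long-format concentrations (`sample_id`, `metabolite`,
#' `concentration`), class map (`metabolite`, `class`) and sample map
#' (`sample_id`, `group`).
#'
#' @param table a [metabolite_table()].
#' @param conc_path,classes_path,samples_path output files.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_metabolite_table <- function(table, conc_path, classes_path,
                                   samples_path) {
  long <- data.frame(
    sample_id = rep(rownames(table$concentrations),
                    times = ncol(table$concentrations)),
    metabolite = rep(colnames(table$concentrations),
                     each = nrow(table$concentrations)),
    concentration = as.vector(table$concentrations))
  write_tsv(long, conc_path)
  write_tsv(data.frame(metabolite = names(table$class_map),
                       class = unname(table$class_map)), classes_path)
  write_tsv(table$sample_map[, c("sample_id", "group")], samples_path)
  invisible(c(concentrations = conc_path, classes = classes_path,
              samples = samples_path))
}

#' Read a metabolite table from its three TSV files
#'
#' @param conc_path,classes_path,samples_path files written by
#'   [write_metabolite_table()].
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(conc_path, classes_path, samples_path) {
  long <- read_tsv(conc_path, c("sample_id", "metabolite", "concentration"))
  classes <- read_tsv(classes_path, c("metabolite", "class"))
  samples <- read_tsv(samples_path, c("sample_id", "group"))
  mets <- classes$metabolite
  sample_ids <- samples$sample_id
  m <- matrix(0, length(sample_ids), length(mets),
              dimnames = list(sample_ids, mets))
  m[cbind(match(long$sample_id, sample_ids),
          match(long$metabolite, mets))] <- long$concentration
  metabolite_table(m, stats::setNames(classes$class, classes$metabolite),
                   samples)
}
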