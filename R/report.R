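## Summary report tables: per-group trait means with significance letters
## (traits table layout) and a diversity table (richness / Shannon / Evar /
## extinctions).

#' Assign compact significance letters from pairwise p-values
#'
#' Greedy compact-letter-display: groups are processed in order of
#' decreasing mean; each group reuses the first existing letter whose
#' current holders are all non-significantly different from it, otherwise
#' it opens a new letter. Groups that do not share a letter differ
#' significantly at `alpha`.
#'
#' @param means named numeric vector of group means.
#' @param pmat symmetric matrix of pairwise p-values (dimnames = group
#'   names).
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
significance_letters <- function(means, pmat, alpha = 0.05) {
  groups <- names(sort(means, decreasing = TRUE))
  letters_held <- stats::setNames(vector("list", length(groups)), groups)
  pool <- character()   # letter -> member groups
  members <- list()
  for (g in groups) {
    placed <- FALSE
    for (L in pool) {
      ok <- all(vapply(members[[L]], function(h)
        pmat[g, h] >= alpha, logical(1)))
      if (ok) {
        members[[L]] <- c(members[[L]], g)
        letters_held[[g]] <- c(letters_held[[g]], L)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      L <- letters[length(pool) + 1L]
      pool <- c(pool, L)
      members[[L]] <- g
      letters_held[[g]] <- L
    }
  }
  ## a significant pair must never share a letter; the greedy insert
  ## guarantees that because sharing required pairwise non-significance
  vapply(letters_held, paste, character(1), collapse = "")[names(means)]
}

#' Build summary report tables from pipeline outputs
#'
#' Reads the trait fits (and, when present, the diversity outputs) from a
#' pipeline output directory and writes two report tables: a traits table
#' (per-group mean +/- SE for each thermal trait with significance letters
#' from pairwise pooled t-tests at `alpha`) and a diversity table
#' (per-group richness / Shannon / Evar with extinction counts).
#'
#' @param outdir pipeline output directory (must contain `tpc_fits.tsv`;
#'   `diversity_summary.tsv` and `extinctions.tsv` are used when present).
#' @param alpha significance level for the letter assignment.
#' @return List with `traits` and (possibly NULL) `diversity` data.frames;
#'   also written as `report_traits.tsv` / `report_diversity.tsv`.
#' @export
make_report <- function(outdir, alpha = 0.05) {
  fits_path <- file.path(outdir, "tpc_fits.tsv")
  if (!file.exists(fits_path))
    stop_pt("missing upstream output of stage `tpc`: %s", fits_path,
            class = "missing_stage_output")
  fits <- read_tsv(fits_path, c("group", "mu_max", "t_opt", "ct_min",
                                "ct_max", "b80"))
  groups <- unique(fits$group)
  traits <- c("mu_max", "t_opt", "ct_min", "ct_max", "b80")
  rows <- list()
  for (tr in traits) {
    vals <- split(fits[[tr]], fits$group)[groups]
    means <- vapply(vals, mean, numeric(1))
    ses <- vapply(vals, function(v) stats::sd(v) / sqrt(length(v)),
                  numeric(1))
    pmat <- matrix(1, length(groups), length(groups),
                   dimnames = list(groups, groups))
    if (length(groups) >= 2L && all(lengths(vals) >= 2L)) {
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (i < j) {
          p <- pooled_t_test(vals[[i]], vals[[j]])$p
          pmat[i, j] <- pmat[j, i] <- p
        }
      }
    }
    lets <- significance_letters(means, pmat, alpha)
    rows[[tr]] <- data.frame(trait = tr, group = groups,
                             mean = unname(means), se = unname(ses),
                             letter = unname(lets[groups]),
                             row.names = NULL)
  }
  traits_tab <- do.call(rbind, rows)
  rownames(traits_tab) <- NULL
  write_tsv(traits_tab, file.path(outdir, "report_traits.tsv"))

  diversity_tab <- NULL
  div_path <- file.path(outdir, "diversity_summary.tsv")
  if (file.exists(div_path)) {
    div <- read_tsv(div_path, c("group", "index", "mean", "se"))
    diversity_tab <- stats::reshape(
      div, direction = "wide", idvar = "group", timevar = "index")
    ext_path <- file.path(outdir, "extinctions.tsv")
    if (file.exists(ext_path)) {
      ext <- read_tsv(ext_path, c("reference", "target", "extinctions"))
      diversity_tab$extinctions <-
        ext$extinctions[match(diversity_tab$group, ext$target)]
    }
    rownames(diversity_tab) <- NULL
    write_tsv(diversity_tab, file.path(outdir, "report_diversity.tsv"))
  }
  list(traits = traits_tab, diversity = diversity_tab)
}
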