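## Metabolite concentration tables: class fractions, fold changes and
## class-level group tests.

#' Construct a metabolite concentration table
#'
#' @param concentrations samples x metabolites matrix of non-negative
#'   concentrations (arbitrary but internally consistent units), with
#'   sample rownames and metabolite colnames.
#' @param class_map named character vector: metabolite -> class label
#'   (e.g. `amino_acid`, `carbohydrate`, `other`); every metabolite column
#'   must have an entry.
#' @param sample_map data.frame with columns `sample_id` and `group`.
#' @return An object of class `metabolite_table`.
#' @export
metabolite_table <- function(concentrations, class_map, sample_map) {
  m <- as.matrix(concentrations)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_pt("concentrations must have sample rownames and metabolite colnames",
            class = "invalid_parameter")
  if (any(!is.finite(m)) || any(m < 0))
    stop_pt("concentrations must be finite and >= 0",
            class = "invalid_parameter")
  missing_cls <- setdiff(colnames(m), names(class_map))
  if (length(missing_cls) > 0L)
    stop_pt("metabolites without a class: %s",
            paste(utils::head(missing_cls, 5), collapse = ", "),
            class = "unknown_class")
  sample_map <- as.data.frame(sample_map)
  missing_smp <- setdiff(rownames(m), sample_map$sample_id)
  if (length(missing_smp) > 0L)
    stop_pt("samples without group labels: %s",
            paste(utils::head(missing_smp, 5), collapse = ", "),
            class = "invalid_parameter")
  rownames(sample_map) <- sample_map$sample_id
  structure(list(concentrations = m,
                 class_map = class_map[colnames(m)],
                 sample_map = sample_map[rownames(m), , drop = FALSE]),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("Metabolite table: %d samples x %d metabolites, classes: %s\n",
              nrow(x$concentrations), ncol(x$concentrations),
              paste(unique(x$class_map), collapse = ", ")))
  invisible(x)
}

met_groups <- function(table) table$sample_map[rownames(table$concentrations), "group"]

## per-sample class totals (samples x classes)
class_sums <- function(table) {
  t(rowsum(t(table$concentrations), group = table$class_map))
}

#' Metabolite class fractions
#'
#' Percent contribution of each metabolite class to each sample's total
#' concentration, with per-group means and standard errors. Per-sample
#' fractions sum to 100.
#'
#' @param table a [metabolite_table()].
#' @return List with `per_sample` (samples x classes percent matrix) and
#'   `summary` (data.frame `group`, `class`, `mean`, `se`).
#' @export
class_fractions <- function(table) {
  cs <- class_sums(table)
  totals <- rowSums(cs)
  if (any(totals == 0))
    stop_pt("sample(s) with zero total concentration",
            class = "invalid_data")
  pct <- sweep(cs, 1, totals, "/") * 100
  grp <- met_groups(table)
  summ <- do.call(rbind, lapply(unique(grp), function(g) {
    sub <- pct[grp == g, , drop = FALSE]
    data.frame(group = g, class = colnames(sub),
               mean = colMeans(sub),
               se = apply(sub, 2, function(v)
                 if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_),
               row.names = NULL)
  }))
  list(per_sample = pct, summary = summ)
}

#' Per-metabolite fold change between two groups
#'
#' FC = mean(numerator group) / mean(denominator group) per metabolite,
#' with log2(FC). A metabolite whose denominator mean is zero (with
#' `pseudocount = 0`) is reported with `error = TRUE` and NA fold change —
#' surfaced, not silently dropped. A positive `pseudocount` is added to
#' both group means before the ratio.
#'
#' @param table a [metabolite_table()].
#' @param group_num,group_den group labels for numerator and denominator.
#' @param pseudocount value added to both means (default 0).
#' @return data.frame `metabolite`, `class`, `mean_num`, `mean_den`,
#'   `fc`, `log2fc`, `error`.
#' @export
fold_change <- function(table, group_num, group_den, pseudocount = 0) {
  grp <- met_groups(table)
  for (g in c(group_num, group_den))
    if (!g %in% grp)
      stop_pt("unknown group label: %s", g, class = "unknown_group")
  check_number(pseudocount, "pseudocount", lower = 0)
  mn <- colMeans(table$concentrations[grp == group_num, , drop = FALSE])
  md <- colMeans(table$concentrations[grp == group_den, , drop = FALSE])
  mn_p <- mn + pseudocount
  md_p <- md + pseudocount
  bad <- md_p == 0
  fc <- ifelse(bad, NA_real_, mn_p / md_p)
  data.frame(metabolite = colnames(table$concentrations),
             class = unname(table$class_map),
             mean_num = unname(mn), mean_den = unname(md),
             fc = unname(fc), log2fc = unname(log2(fc)),
             error = unname(bad), row.names = NULL)
}

#' One-way ANOVA on per-sample class totals
#'
#' Tests whether the total concentration of one metabolite class differs
#' between groups (for two groups, F equals the square of the pooled
#' Student's t statistic).
#'
#' @param table a [metabolite_table()].
#' @param class_label one class from the class map.
#' @param groups group labels to compare (default: the two groups of the
#'   table); each must have >= 2 samples.
#' @return List with `F`, `df_num`, `df_den`, `p`.
#' @export
class_group_test <- function(table, class_label, groups = NULL) {
  cs <- class_sums(table)
  if (!class_label %in% colnames(cs))
    stop_pt("unknown class label: %s", class_label, class = "unknown_class")
  grp <- met_groups(table)
  if (is.null(groups)) groups <- unique(grp)
  sel <- grp %in% groups
  y <- cs[sel, class_label]
  f <- factor(grp[sel], levels = groups)
  sizes <- table(f)
  if (any(sizes < 2L))
    stop_pt("need >= 2 samples per group", class = "insufficient_data")
  k <- nlevels(f); n <- length(y)
  gm <- mean(y)
  mg <- tapply(y, f, mean)
  ss_b <- sum(sizes * (mg - gm)^2)
  ss_w <- sum((y - mg[f])^2)
  df1 <- k - 1L; df2 <- n - k
  Fval <- if (ss_b == 0) 0 else if (ss_w == 0) Inf else
    (ss_b / df1) / (ss_w / df2)
  p <- if (Fval == 0) 1 else if (is.infinite(Fval)) 0 else
    stats::pf(Fval, df1, df2, lower.tail = FALSE)
  list(F = Fval, df_num = df1, df_den = df2, p = p)
}
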