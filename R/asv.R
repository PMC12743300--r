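## ASV count-table container and community-diversity operations.

#' Construct an ASV count table
#'
#' Samples-by-ASVs integer count matrix with a taxonomy map and a
#' sample-to-group map.
#'
#' @param counts matrix of non-negative integer read counts, samples in
#'   rows (rownames = sample ids), ASVs in columns (colnames = ASV ids).
#' @param taxonomy data.frame with columns `asv_id`, `genus`, `family`,
#'   `order`, `phylum`; every ASV column must have an entry (use
#'   `"unclassified"` where unknown).
#' @param sample_map data.frame with columns `sample_id`, `group` and
#'   optionally `replicate`; every sample row must have a group.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy, sample_map) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_pt("counts must have sample rownames and ASV colnames",
            class = "invalid_parameter")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_pt("counts must be non-negative integers", class = "invalid_parameter")
  storage.mode(counts) <- "integer"
  taxonomy <- as.data.frame(taxonomy)
  sample_map <- as.data.frame(sample_map)
  missing_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(missing_tax) > 0L)
    stop_pt("ASVs without taxonomy entries: %s",
            paste(utils::head(missing_tax, 5), collapse = ", "),
            class = "invalid_parameter")
  missing_smp <- setdiff(rownames(counts), sample_map$sample_id)
  if (length(missing_smp) > 0L)
    stop_pt("samples without group labels: %s",
            paste(utils::head(missing_smp, 5), collapse = ", "),
            class = "invalid_parameter")
  if (is.null(sample_map$replicate)) {
    sample_map$replicate <- stats::ave(seq_len(nrow(sample_map)),
                                       sample_map$group, FUN = seq_along)
  }
  rownames(taxonomy) <- taxonomy$asv_id
  rownames(sample_map) <- sample_map$sample_id
  structure(list(counts = counts,
                 taxonomy = taxonomy[colnames(counts), , drop = FALSE],
                 sample_map = sample_map[rownames(counts), , drop = FALSE]),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d samples x %d ASVs, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_map$group), collapse = ", ")))
  invisible(x)
}

sample_groups <- function(table) table$sample_map[rownames(table$counts), "group"]

group_rows <- function(table, group) {
  rows <- which(sample_groups(table) == group)
  if (length(rows) == 0L)
    stop_pt("unknown group label: %s", group, class = "unknown_group")
  rows
}

## presence of each ASV in a group: >= 1 read in >= 1 replicate
group_presence <- function(table, group) {
  colSums(table$counts[group_rows(table, group), , drop = FALSE]) > 0
}

#' Filter an ASV table
#'
#' Drops singleton ASVs (dataset-wide total count <= 1) and/or ASVs whose
#' taxonomy matches any label in `drop_taxa` at any rank — the table-level
#' analogue of excluding singletons and mitochondrial / chloroplast /
#' eukaryote reads upstream.
#'
#' @param table an [asv_table()].
#' @param drop_singletons drop ASVs with total count <= 1 (default TRUE).
#' @param drop_taxa character vector of taxonomy labels to exclude
#'   (matched against genus, family, order and phylum).
#' @return A filtered [asv_table()].
#' @export
filter_table <- function(table, drop_singletons = TRUE,
                         drop_taxa = character()) {
  keep <- rep(TRUE, ncol(table$counts))
  if (isTRUE(drop_singletons))
    keep <- keep & colSums(table$counts) > 1L
  if (length(drop_taxa) > 0L) {
    tax <- table$taxonomy[, c("genus", "family", "order", "phylum"),
                          drop = FALSE]
    hit <- apply(tax, 1L, function(r) any(r %in% drop_taxa))
    keep <- keep & !hit
  }
  asv_table(table$counts[, keep, drop = FALSE],
            table$taxonomy[keep, , drop = FALSE],
            table$sample_map)
}

#' Per-sample relative abundance aggregated at a taxonomic rank
#'
#' Aggregates counts at the requested rank, converts to percent of each
#' sample's total, and summarises per group (mean and SE over replicates).
#'
#' @param table an [asv_table()].
#' @param rank one of `"asv"`, `"genus"`, `"family"`, `"order"`,
#'   `"phylum"`.
#' @return List with `per_sample` (samples x taxa percent matrix, rows sum
#'   to 100) and `summary` (data.frame `group`, `taxon`, `mean`, `se`).
#' @export
relative_abundance <- function(table, rank = "genus") {
  rank <- match.arg(rank, c("asv", "genus", "family", "order", "phylum"))
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop_pt("sample(s) with zero total count: %s",
            paste(rownames(table$counts)[totals == 0], collapse = ", "),
            class = "invalid_data")
  agg <- if (rank == "asv") table$counts else {
    labels <- table$taxonomy[[rank]]
    t(rowsum(t(table$counts), group = labels))
  }
  pct <- sweep(agg, 1, totals, "/") * 100
  grp <- sample_groups(table)
  summ <- do.call(rbind, lapply(unique(grp), function(g) {
    sub <- pct[grp == g, , drop = FALSE]
    data.frame(group = g, taxon = colnames(sub),
               mean = colMeans(sub),
               se = apply(sub, 2, function(v)
                 if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_),
               row.names = NULL)
  }))
  list(per_sample = pct, summary = summ)
}

#' Shannon diversity index of an abundance vector
#'
#' \eqn{H = -\sum p_i \ln p_i} (nats) over the nonzero proportions.
#'
#' @param x non-negative abundances (counts or concentrations).
#' @return Shannon entropy in nats; 0 for a single-taxon vector.
#' @examples
#' shannon_index(c(25, 25, 25, 25))  # ln 4
#' @export
shannon_index <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L)
    stop_pt("no positive abundances", class = "invalid_data")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Smith-Wilson evenness index (Evar) of an abundance vector
#'
#' \eqn{E_{var} = 1 - (2/\pi) \arctan(V)} with \eqn{V} the population
#' variance of log abundances over the S nonzero taxa. 1 for a perfectly
#' even community; decreases towards 0 as log-abundance variance grows.
#'
#' @param x non-negative abundances.
#' @return Evar in `[0, 1]`.
#' @examples
#' evenness_evar(c(1, exp(2)))  # log-variance 1 -> 1 - (2/pi) arctan(1) = 0.5
#' @export
evenness_evar <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L)
    stop_pt("no positive abundances", class = "invalid_data")
  lx <- log(x)
  1 - (2 / pi) * atan(mean((lx - mean(lx))^2))
}

#' Alpha diversity: richness, Shannon index and Smith-Wilson evenness
#'
#' Per sample: richness (number of ASVs with nonzero count), Shannon
#' entropy \eqn{H = -\sum p_i \ln p_i} (nats) over nonzero proportions,
#' and the Smith-Wilson evenness index
#' \eqn{E_{var} = 1 - (2/\pi)\,\arctan(V)} where \eqn{V} is the population
#' variance of the log abundances of the \eqn{S} nonzero ASVs. Group means
#' and standard errors over replicates are attached.
#'
#' @param table an [asv_table()].
#' @return List with `per_sample` (data.frame `sample_id`, `group`,
#'   `richness`, `shannon`, `evar`) and `summary` (per-group mean and SE of
#'   each index).
#' @export
alpha_diversity <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop_pt("sample(s) with zero total count", class = "invalid_data")
  per <- data.frame(
    sample_id = rownames(table$counts),
    group = sample_groups(table),
    richness = apply(table$counts, 1, function(x) sum(x > 0)),
    shannon = apply(table$counts, 1, shannon_index),
    evar = apply(table$counts, 1, evenness_evar),
    row.names = NULL)
  summ <- do.call(rbind, lapply(split(per, per$group), function(d) {
    do.call(rbind, lapply(c("richness", "shannon", "evar"), function(k) {
      ms <- mean_se(d[[k]])
      data.frame(group = d$group[1], index = k,
                 mean = unname(ms["mean"]), se = unname(ms["se"]))
    }))
  }))
  rownames(summ) <- NULL
  list(per_sample = per, summary = summ)
}

#' Extinction accounting between two groups
#'
#' Counts ASVs present in the reference group (>= 1 read in >= 1
#' replicate, after whatever filtering has been applied) but absent from
#' every replicate of the target group — "disappearance below detection"
#' relative to the reference community.
#'
#' @param table an [asv_table()].
#' @param reference_group,target_group group labels in the sample map.
#' @return List with `count` and `asvs` (the extinct ASV ids).
#' @export
extinctions <- function(table, reference_group, target_group) {
  ref <- group_presence(table, reference_group)
  tgt <- group_presence(table, target_group)
  ext <- ref & !tgt
  list(count = sum(ext), asvs = colnames(table$counts)[ext])
}

#' Shared-ASV accounting across groups
#'
#' Presence is defined per group as in [extinctions()]. Returns the
#' Venn-style exclusive count for every non-empty subset of groups (ASVs
#' present in exactly those groups), the full intersection, and the mean
#' number of ASVs shared between pairs of replicate samples across each
#' group pair.
#'
#' @param table an [asv_table()].
#' @param groups two or more group labels.
#' @return List with `regions` (named exclusive counts, names like
#'   `"LA&LW"`), `intersection` (count shared by all groups), and
#'   `pairwise_mean_shared` (data.frame `group_a`, `group_b`,
#'   `mean_shared` over replicate pairs).
#' @export
shared_asvs <- function(table, groups) {
  if (length(groups) < 2L)
    stop_pt("need >= 2 groups", class = "invalid_parameter")
  pres <- vapply(groups, function(g) group_presence(table, g),
                 logical(ncol(table$counts)))
  membership <- apply(pres, 1, function(r) paste(groups[r], collapse = "&"))
  membership <- membership[nzchar(membership)]
  regions <- table(membership)
  regions <- stats::setNames(as.integer(regions), names(regions))
  inter <- sum(rowSums(pres) == length(groups))

  pairs <- utils::combn(groups, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    ra <- group_rows(table, ga); rb <- group_rows(table, gb)
    shared <- outer(ra, rb, Vectorize(function(i, j)
      sum(table$counts[i, ] > 0 & table$counts[j, ] > 0)))
    data.frame(group_a = ga, group_b = gb, mean_shared = mean(shared))
  }))
  list(regions = regions, intersection = inter, pairwise_mean_shared = pw)
}

#' Per-taxon group comparison of relative abundances
#'
#' Two-sided pooled-variance Student's t-test per taxon on per-sample
#' percent relative abundances, for two groups. Taxa absent (all zero) in
#' both groups are excluded. No multiple-testing correction by default;
#' `bonferroni = TRUE` multiplies p by the number of taxa tested.
#'
#' @param rel_abund samples x taxa percent matrix (e.g.
#'   `relative_abundance(...)$per_sample`).
#' @param sample_groups group label per row of `rel_abund`.
#' @param groups the two group labels to compare.
#' @param bonferroni apply Bonferroni correction (default FALSE).
#' @return data.frame `taxon`, `mean_a`, `se_a`, `mean_b`, `se_b`, `t`,
#'   `df`, `p`.
#' @export
taxon_group_test <- function(rel_abund, sample_groups, groups,
                             bonferroni = FALSE) {
  if (length(groups) != 2L)
    stop_pt("exactly two groups required", class = "invalid_parameter")
  a <- rel_abund[sample_groups == groups[1], , drop = FALSE]
  b <- rel_abund[sample_groups == groups[2], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop_pt("need >= 2 replicates per group", class = "insufficient_data")
  keep <- colSums(a) > 0 | colSums(b) > 0
  res <- do.call(rbind, lapply(colnames(rel_abund)[keep], function(tx) {
    tt <- pooled_t_test(a[, tx], b[, tx])
    data.frame(taxon = tx, mean_a = tt$mean_x, se_a = tt$se_x,
               mean_b = tt$mean_y, se_b = tt$se_y,
               t = tt$t, df = tt$df, p = tt$p)
  }))
  if (isTRUE(bonferroni)) res$p <- pmin(1, res$p * nrow(res))
  res
}
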