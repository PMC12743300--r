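## Bray-Curtis dissimilarity and permutation PERMANOVA, implemented from
## their definitions (vegan serves only as a test oracle).

#' Bray-Curtis distance matrix between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed by
#' default on per-sample proportions so that unequal sequencing depths do
#' not masquerade as community differences; `use_proportions = FALSE`
#' computes it on raw counts.
#'
#' @param x an [asv_table()] or a samples x features numeric matrix with
#'   rownames.
#' @param use_proportions normalise each row to proportions first
#'   (default TRUE).
#' @return Symmetric numeric matrix of distances in `[0, 1]` with zero
#'   diagonal and sample ids as dimnames.
#' @export
bray_curtis <- function(x, use_proportions = TRUE) {
  m <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop_pt("sample(s) with zero total", class = "invalid_data")
  if (isTRUE(use_proportions)) m <- sweep(m, 1, totals, "/")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <-
        sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  d
}

#' Permutation PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance. With
#' \eqn{n} samples in \eqn{g} groups the sums of squares are computed from
#' squared distances:
#' \deqn{SS_{total} = \frac{1}{n} \sum_{i<j} d_{ij}^2, \qquad
#'       SS_{within} = \sum_{groups} \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2,}
#' \eqn{SS_{among} = SS_{total} - SS_{within}}, and
#' \eqn{F = (SS_{among}/(g-1)) / (SS_{within}/(n-g))}. The p-value is the
#' permutation estimate \eqn{(b + 1)/(m + 1)} where \eqn{b} counts label
#' permutations with \eqn{F_{perm} \ge F_{obs}}; labels are permuted
#' freely (no strata).
#'
#' @param dist symmetric distance matrix (or `dist` object).
#' @param groups group label per sample; >= 2 groups, each with >= 2
#'   samples.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `permanova_result`: list with `pseudo_f`,
#'   `df_among`, `df_within`, `p`, `n_permutations`, `ss_among`,
#'   `ss_within`, `ss_total`.
#' @export
permanova <- function(dist, groups, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n)
    stop_pt("length(groups) must equal the number of samples",
            class = "invalid_parameter")
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop_pt("need >= 2 groups with >= 2 samples each",
            class = "invalid_parameter")
  g <- length(sizes)
  d2 <- d^2

  pseudo_f <- function(lab) {
    ss_within <- 0
    for (gr in unique(lab)) {
      idx <- which(lab == gr)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_total <- sum(d2[upper.tri(d2)]) / n
    ss_among <- ss_total - ss_within
    list(f = (ss_among / (g - 1)) / (ss_within / (n - g)),
         ss_among = ss_among, ss_within = ss_within, ss_total = ss_total)
  }

  obs <- pseudo_f(groups)
  b <- withr_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(k) {
      pseudo_f(sample(groups))$f >= obs$f - 1e-12
    }, logical(1)))
  })
  structure(list(pseudo_f = obs$f,
                 df_among = g - 1L, df_within = n - g,
                 p = (b + 1) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 ss_among = obs$ss_among, ss_within = obs$ss_within,
                 ss_total = obs$ss_total),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4g, p = %.4g (%d permutations)\n",
              x$df_among, x$df_within, x$pseudo_f, x$p, x$n_permutations))
  invisible(x)
}
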