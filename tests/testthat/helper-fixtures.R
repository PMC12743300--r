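# Shared fixtures: published trait rows, small deterministic tables, and
# brute-force oracles used across test files.

# Published trait table rows (means) and the Norberg parameters obtained
# by closed-form inversion of (mu_max, t_opt, ct_min, ct_max).
table1_rows <- list(
  bacteria_ambient = list(
    traits = list(mu_max = 2.09, t_opt = 28.74, ct_min = 14.2,
                  ct_max = 38.19, b80 = 10.10),
    params = list(a = 0.7548, b = 0.03704, z = 26.195, w = 23.99)),
  bacteria_warming = list(
    traits = list(mu_max = 2.41, t_opt = 28.95, ct_min = 14.2,
                  ct_max = 38.39, b80 = 10.00),
    params = list(a = 0.8394, b = 0.03814, z = 26.295, w = 24.19)),
  diatom_ambient = list(
    traits = list(mu_max = 2.41, t_opt = 29.9, ct_min = 10.4,
                  ct_max = 41.31, b80 = 12.66),
    params = list(a = 0.8723, b = 0.03636, z = 25.855, w = 30.91)),
  diatom_warming = list(
    traits = list(mu_max = 2.50, t_opt = 31.1, ct_min = 13.4,
                  ct_max = 41.66, b80 = 11.71),
    params = list(a = 0.8140, b = 0.03820, z = 27.53, w = 28.26)))

assay_temps <- c(16, 18, 22, 24, 26, 30, 34, 36, 38)

# random valid warm-skewed Norberg parameters
random_params <- function() {
  norberg_params(a = runif(1, 0.2, 2), b = runif(1, 0, 0.1),
                 z = runif(1, 15, 30), w = runif(1, 10, 35))
}

# small deterministic ASV table: 2 groups x 3 replicates, 6 ASVs
toy_asv_table <- function() {
  counts <- rbind(
    LA_r1 = c(50, 30, 10, 5, 4, 1),
    LA_r2 = c(55, 25, 12, 4, 4, 0),
    LA_r3 = c(48, 32, 11, 6, 3, 0),
    LW_r1 = c(60, 25, 15, 0, 0, 0),
    LW_r2 = c(58, 27, 14, 0, 1, 0),
    LW_r3 = c(62, 24, 13, 0, 1, 0))
  colnames(counts) <- sprintf("ASV%03d", 1:6)
  asv_table(counts,
            taxonomy = data.frame(
              asv_id = colnames(counts),
              genus = c("Roseo", "Thala", "Cogna", "Mari", "Lewi", "Phyci"),
              family = c("F1", "F1", "F2", "F2", "F3", "F3"),
              order = c("O1", "O1", "O1", "O2", "O2", "O2"),
              phylum = rep("Proteobacteria", 6)),
            sample_map = data.frame(
              sample_id = rownames(counts),
              group = rep(c("LA", "LW"), each = 3),
              replicate = rep(1:3, 2)))
}

toy_metabolite_table <- function() {
  conc <- rbind(
    LA_r1 = c(aa1 = 10, aa2 = 8, carb1 = 6, other1 = 20, other2 = 7),
    LA_r2 = c(11, 7, 5, 21, 8),
    LA_r3 = c(9, 9, 7, 19, 6),
    LW_r1 = c(20, 15, 2, 18, 9),
    LW_r2 = c(22, 14, 1, 20, 8),
    LW_r3 = c(21, 16, 2, 19, 10))
  metabolite_table(conc,
                   class_map = c(aa1 = "amino_acid", aa2 = "amino_acid",
                                 carb1 = "carbohydrate",
                                 other1 = "other", other2 = "other"),
                   sample_map = data.frame(
                     sample_id = rownames(conc),
                     group = rep(c("LA", "LW"), each = 3)))
}

# brute-force Bray-Curtis on a matrix of counts/proportions
bc_brute <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

# brute-force exponential-window selection mirroring the documented rule,
# written independently (data.frame scan, different tie handling code path)
detect_window_brute <- function(day, cells, min_points = 3,
                                r2_threshold = 0.95) {
  n <- length(day)
  best <- NULL
  consider <- function(i, j, qualified_only) {
    y <- log(cells[i:j]); x <- day[i:j]
    fit <- stats::lm(y ~ x)
    r2 <- if (stats::var(y) == 0) 1 else summary(fit)$r.squared
    slope <- unname(stats::coef(fit)[2])
    list(i = i, j = j, slope = slope, r2 = r2)
  }
  all_w <- list()
  for (i in 1:(n - min_points + 1)) for (j in (i + min_points - 1):n)
    all_w[[length(all_w) + 1]] <- consider(i, j)
  q <- Filter(function(w) w$r2 >= r2_threshold, all_w)
  cand <- if (length(q) > 0) q else all_w
  key <- if (length(q) > 0) "slope" else "r2"
  vals <- vapply(cand, `[[`, numeric(1), key)
  cand <- cand[abs(vals - max(vals)) <= 1e-12]
  lens <- vapply(cand, function(w) w$j - w$i, numeric(1))
  cand <- cand[lens == max(lens)]
  starts <- vapply(cand, `[[`, numeric(1), "i")
  w <- cand[[which.min(starts)]]
  c(first_day = day[w$i], last_day = day[w$j])
}
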