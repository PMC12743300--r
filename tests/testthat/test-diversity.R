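test_that("filter_table drops singletons and flagged taxa", {
  # per-ASV totals: 1, 2, 5, 9, 100, 1
  counts <- rbind(s1 = c(1, 1, 4, 5, 60, 0),
                  s2 = c(0, 1, 1, 4, 40, 1))
  colnames(counts) <- sprintf("ASV%03d", 1:6)
  tax <- data.frame(asv_id = colnames(counts),
                    genus = c("g1", "g2", "g3", "g4", "g5", "Chloroplast"),
                    family = "f", order = "o", phylum = "p")
  smp <- data.frame(sample_id = c("s1", "s2"), group = c("A", "A"))
  tab <- asv_table(counts, tax, smp)

  filt <- filter_table(tab)
  expect_equal(ncol(filt$counts), 4L)            # totals (2, 5, 9, 100)
  expect_false("ASV001" %in% colnames(filt$counts))

  ident <- filter_table(tab, drop_singletons = FALSE)
  expect_identical(ident$counts, tab$counts)

  no_chloro <- filter_table(tab, drop_singletons = FALSE,
                            drop_taxa = "Chloroplast")
  expect_equal(ncol(no_chloro$counts), 5L)
})

test_that("relative abundance aggregates by rank and normalises to 100", {
  tab <- toy_asv_table()
  ra <- relative_abundance(tab, rank = "asv")
  expect_equal(unname(rowSums(ra$per_sample)), rep(100, 6),
               tolerance = 1e-9)

  counts <- rbind(s1 = c(30, 20, 50))
  colnames(counts) <- c("ASV001", "ASV002", "ASV003")
  tax <- data.frame(asv_id = colnames(counts),
                    genus = c("G1", "G1", "G2"),
                    family = "f", order = "o", phylum = "p")
  one <- asv_table(counts, tax,
                   data.frame(sample_id = "s1", group = "A"))
  rg <- relative_abundance(one, rank = "genus")
  expect_equal(rg$per_sample[1, "G1"], 50)       # (30 + 20) / 100

  single <- asv_table(matrix(7, 1, 1, dimnames = list("s1", "ASV001")),
                      data.frame(asv_id = "ASV001", genus = "g",
                                 family = "f", order = "o", phylum = "p"),
                      data.frame(sample_id = "s1", group = "A"))
  expect_equal(unname(relative_abundance(single)$per_sample[1, 1]), 100)
})

test_that("alpha diversity identities: uniform, single-ASV, frozen Shannon/Evar", {
  mk <- function(x) {
    m <- matrix(x, 1, length(x),
                dimnames = list("s1", sprintf("ASV%03d", seq_along(x))))
    asv_table(m, data.frame(asv_id = colnames(m), genus = "g",
                            family = "f", order = "o", phylum = "p"),
              data.frame(sample_id = "s1", group = "A"))
  }
  u <- alpha_diversity(mk(c(25, 25, 25, 25)))$per_sample
  expect_equal(u$richness, 4L)
  expect_equal(u$shannon, log(4), tolerance = 1e-12)
  expect_equal(u$evar, 1)

  s <- alpha_diversity(mk(c(0, 42, 0)))$per_sample
  expect_equal(s$richness, 1L)
  expect_equal(s$shannon, 0)

  # proportions (0.5, 0.25, 0.25): H = 1.5 * ln 2 = 1.0397
  h <- alpha_diversity(mk(c(2, 1, 1)))$per_sample
  expect_equal(h$shannon, 1.0397, tolerance = 1e-4)

  # abundances (1, e^2): log-variance 1, Evar = 1 - (2/pi) arctan(1) = 0.5
  expect_equal(evenness_evar(c(1, exp(2))), 0.5, tolerance = 1e-12)
  expect_equal(shannon_index(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
})

test_that("Evar decreases as log-abundance variance grows", {
  mk <- function(x) {
    m <- matrix(round(x), 1, length(x),
                dimnames = list("s1", sprintf("ASV%03d", seq_along(x))))
    asv_table(m, data.frame(asv_id = colnames(m), genus = "g",
                            family = "f", order = "o", phylum = "p"),
              data.frame(sample_id = "s1", group = "A"))
  }
  evars <- vapply(c(1, 2, 4, 8), function(k)
    alpha_diversity(mk(c(10, 10 * k, 10 * k^2)))$per_sample$evar,
    numeric(1))
  expect_true(all(diff(evars) < 0))
})

test_that("extinction accounting follows the presence rule", {
  tab <- toy_asv_table()
  # LA presence: all 6 ASVs; LW presence: ASV1-3 and ASV5
  ext <- extinctions(tab, "LA", "LW")
  expect_equal(ext$count, 2L)
  expect_setequal(ext$asvs, c("ASV004", "ASV006"))
  # target superset of reference -> 0
  expect_equal(extinctions(tab, "LW", "LA")$count, 0L)
  expect_error(extinctions(tab, "LA", "nope"), class = "unknown_group")
})

test_that("extinctions + shared presence = reference richness (conservation)", {
  set.seed(23)
  for (k in 1:10) {
    tab <- simulate_asv_table(
      list(A = community_profile(n_asvs = sample(8:17, 1), depth = 500),
           B = community_profile(n_asvs = sample(8:17, 1), depth = 500)),
      seed = k)
    pa <- colSums(tab$counts[tab$sample_map$group == "A", ]) > 0
    ext <- extinctions(tab, "A", "B")$count
    shared <- shared_asvs(tab, c("A", "B"))
    shared_ab <- shared$intersection
    expect_equal(ext + shared_ab, sum(pa))
  }
})

test_that("shared_asvs set algebra on constructed presence sets", {
  tab <- toy_asv_table()
  sh <- shared_asvs(tab, c("LA", "LW"))
  expect_equal(sh$intersection, 4L)              # ASV1, 2, 3, 5
  expect_equal(unname(sh$regions["LA"]), 2L)     # ASV4, ASV6 exclusive
  expect_false("LW" %in% names(sh$regions))      # nothing LW-exclusive
  expect_equal(nrow(sh$pairwise_mean_shared), 1L)
  expect_error(shared_asvs(tab, "LA"), class = "invalid_parameter")

  # identical groups: intersection = richness, no exclusives
  both <- toy_asv_table()
  both$sample_map$group <- rep(c("X", "Y"), each = 3)
  both$counts[4:6, ] <- both$counts[1:3, ]
  sh2 <- shared_asvs(asv_table(both$counts, both$taxonomy, both$sample_map),
                     c("X", "Y"))
  expect_equal(sh2$intersection, 6L)
  expect_equal(length(setdiff(names(sh2$regions), "X&Y")), 0L)
})

test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  x <- rbind(a = c(2, 0, 2), b = c(1, 1, 0))
  expect_equal(bray_curtis(x, use_proportions = FALSE)["a", "b"], 4 / 6,
               tolerance = 1e-12)
  same <- rbind(a = c(3, 1), b = c(3, 1))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(bray_curtis(disj)["a", "b"], 1)

  set.seed(31)
  for (k in 1:10) {
    m <- matrix(rpois(6 * 8, 5), nrow = 6,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:8)))
    m[m == 0] <- 1   # keep totals positive
    d <- bray_curtis(m, use_proportions = FALSE)
    expect_equal(d, bc_brute(m), tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
  }
})

test_that("Bray-Curtis agrees with vegan on proportion and raw modes", {
  skip_if_not_installed("vegan")
  set.seed(37)
  m <- matrix(rpois(5 * 12, 8) + 1, nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:12)))
  expect_equal(bray_curtis(m, use_proportions = FALSE),
               as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-10, ignore_attr = TRUE)
  prop <- sweep(m, 1, rowSums(m), "/")
  expect_equal(bray_curtis(m, use_proportions = TRUE),
               as.matrix(vegan::vegdist(prop, "bray")),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("taxon_group_test computes pooled t per taxon and drops absent taxa", {
  ra <- rbind(c(10, 0), c(12, 0), c(14, 0),
              c(40, 0), c(42, 0), c(44, 0))
  colnames(ra) <- c("tx1", "absent")
  rownames(ra) <- paste0("s", 1:6)
  grp <- rep(c("A", "B"), each = 3)
  res <- taxon_group_test(ra, grp, c("A", "B"))
  expect_equal(nrow(res), 1L)                    # absent taxon excluded
  expect_equal(res$t, -18.37, tolerance = 1e-3)
  expect_equal(res$df, 4)

  same <- matrix(c(5, 5, 6, 5, 5, 6), ncol = 1,
                 dimnames = list(paste0("s", 1:6), "tx"))
  ident <- taxon_group_test(same, grp, c("A", "B"))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})
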