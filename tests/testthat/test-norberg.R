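test_that("norberg_growth matches direct evaluation and its bracket roots", {
  p <- do.call(norberg_params, table1_rows$bacteria_ambient$params)
  # frozen from direct evaluation of a*exp(b*T)*(1-((T-z)/(w/2))^2)
  expect_equal(norberg_growth(26, p), 1.976788, tolerance = 1e-6)
  expect_equal(norberg_growth(16, p), 0.379002, tolerance = 1e-6)
  # roots at z +/- w/2, exactly
  expect_equal(norberg_growth(p$z + p$w / 2, p), 0)
  expect_equal(norberg_growth(p$z - p$w / 2, p), 0)
  # symmetric case: maximum a at T = z when b = 0
  ps <- norberg_params(a = 1.3, b = 0, z = 20, w = 10)
  expect_equal(norberg_growth(20, ps), 1.3)
})

test_that("roots hold for random parameters (property)", {
  set.seed(42)
  for (k in 1:50) {
    p <- random_params()
    expect_equal(norberg_growth(c(p$z - p$w / 2, p$z + p$w / 2), p),
                 c(0, 0), tolerance = 1e-12)
  }
})

test_that("derive_traits agrees with an independent numerical maximisation", {
  set.seed(7)
  for (k in 1:40) {
    p <- random_params()
    tr <- derive_traits(p)
    # independent oracle: golden-section maximisation over the niche
    num <- optimize(function(T) norberg_growth(T, p),
                    c(p$z - p$w / 2, p$z + p$w / 2),
                    maximum = TRUE, tol = 1e-10)
    expect_lt(abs(tr$t_opt - num$maximum), 1e-6)
    expect_equal(tr$mu_max, num$objective, tolerance = 1e-9)
    expect_equal(tr$ct_min, p$z - p$w / 2)
    expect_equal(tr$ct_max, p$z + p$w / 2)
    expect_true(tr$ct_min < tr$t_opt && tr$t_opt < tr$ct_max)
    expect_lt(tr$b80, tr$ct_max - tr$ct_min)
  }
})

test_that("b80 behaves: symmetric case, degenerate fraction, monotonicity", {
  ps <- norberg_params(a = 1, b = 0, z = 20, w = 10)
  tr <- derive_traits(ps)
  expect_equal(tr$t_opt, 20)
  # symmetric curve: 80% points equidistant from z, b80 = w*sqrt(0.2)
  expect_equal(tr$b80, 10 * sqrt(0.2), tolerance = 1e-6)
  expect_equal(derive_traits(ps, fraction = 1)$b80, 0)
  p <- do.call(norberg_params, table1_rows$diatom_warming$params)
  fr <- seq(0.5, 0.95, by = 0.05)
  breadths <- vapply(fr, function(f) derive_traits(p, f)$b80, numeric(1))
  expect_true(all(diff(breadths) < 0))
})

test_that("params_from_traits inverts the published trait rows", {
  for (row in table1_rows) {
    p <- params_from_traits(row$traits)
    expect_equal(p$a, row$params$a, tolerance = 1e-3)
    expect_equal(p$b, row$params$b, tolerance = 1e-3)
    expect_equal(p$z, row$params$z, tolerance = 1e-9)
    expect_equal(p$w, row$params$w, tolerance = 1e-9)
    # forward check: curve maximum reproduces the stated mu_max and t_opt
    tr <- derive_traits(p)
    expect_equal(tr$mu_max, row$traits$mu_max, tolerance = 1e-6)
    expect_equal(tr$t_opt, row$traits$t_opt, tolerance = 1e-6)
  }
})

test_that("params_from_traits handles symmetry and rejects bad inputs", {
  p <- params_from_traits(list(mu_max = 1.5, t_opt = 20, ct_min = 10,
                               ct_max = 30))
  expect_equal(p$b, 0)
  expect_equal(p$a, 1.5)
  expect_error(params_from_traits(list(mu_max = 1, t_opt = 31, ct_min = 10,
                                       ct_max = 30)),
               class = "invalid_parameter")
  expect_error(params_from_traits(list(mu_max = 1, t_opt = 15, ct_min = 10,
                                       ct_max = 30)),
               class = "unsupported_skew")
})

test_that("trait <-> parameter round trips are identities (property)", {
  set.seed(11)
  for (k in 1:30) {
    p <- random_params()
    tr <- derive_traits(p)
    p2 <- params_from_traits(tr)
    expect_equal(unlist(p2), unlist(p), tolerance = 1e-6)
    tr2 <- derive_traits(p2)
    expect_equal(unlist(tr2[1:5]), unlist(tr[1:5]), tolerance = 1e-6)
  }
})

test_that("thermal_reaction_norm tabulates the curve", {
  ps <- norberg_params(a = 0.9, b = 0, z = 22, w = 12)
  tab <- thermal_reaction_norm(ps, 22)
  expect_equal(dim(tab), c(1L, 2L))
  expect_equal(tab$growth_rate_per_day, 0.9)
  tab2 <- thermal_reaction_norm(ps, c(16, 28))   # the curve roots
  expect_equal(tab2$growth_rate_per_day, c(0, 0))
  p <- do.call(norberg_params, table1_rows$bacteria_ambient$params)
  grid <- seq(14.2, 38.19, by = 0.005)
  dense <- thermal_reaction_norm(p, grid)
  expect_lt(abs(grid[which.max(dense$growth_rate_per_day)] -
                  derive_traits(p)$t_opt), 0.01)
  expect_error(thermal_reaction_norm(p, numeric()),
               class = "invalid_parameter")
})

test_that("compare_traits runs pooled Student's t per trait", {
  ga <- data.frame(mu_max = c(1, 2, 3), t_opt = c(28, 29, 30))
  gb <- data.frame(mu_max = c(4, 5, 6), t_opt = c(28, 29, 30))
  res <- compare_traits(ga, gb)
  mu <- res[res$trait == "mu_max", ]
  expect_equal(mu$t, -3.674, tolerance = 1e-3)
  expect_equal(mu$df, 4)
  ident <- res[res$trait == "t_opt", ]
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(compare_traits(ga[1, , drop = FALSE], gb),
               class = "insufficient_data")
})
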