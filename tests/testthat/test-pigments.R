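simple_table <- function(masses, basis = "per_extract", n = 100L,
                         species = "hg", replicate = 1L) {
  pigment_profile(
    data.frame(replicate = replicate, species = species, n_specimens = n,
               pigment = names(masses), mass_ng = unname(masses)),
    basis = basis)
}

test_that("per-cell conversion divides by specimen count once", {
  p <- simple_table(c(chl_a = 1456, chl_c = 160, phaeophytins = 0))
  pc <- per_cell(p)
  expect_equal(pc$mass_ng[pc$pigment == "chl_a"], 14.56)
  expect_equal(pc$mass_ng[pc$pigment == "phaeophytins"], 0)
  # basis flag blocks re-application
  expect_error(per_cell(pc), "already")
  expect_error(pigment_profile(data.frame(replicate = 1, species = "x",
                                          n_specimens = 0, pigment = "chl_a",
                                          mass_ng = 1)), "n_specimens")
})

test_that("degradation-pigment totals respect the membership list", {
  p <- per_cell(simple_table(c(chl_a = 1000, phaeophytins = 300,
                               fuco_like_1 = 150, fuco_like_2 = 75)))
  expect_equal(deg_pig(p)$deg_pig, 5.25)
  expect_equal(deg_pig(p, members = c("fuco_like_1", "fuco_like_2"))$deg_pig,
               2.25)
  none <- per_cell(simple_table(c(chl_a = 1000, phaeophytins = 0,
                                  fuco_like_1 = 0, fuco_like_2 = 0)))
  expect_equal(deg_pig(none)$deg_pig, 0)
})

test_that("ratio indices reproduce the reference species values at 2 dp", {
  idx <- pigment_indices(reference_mean_profile())
  hg <- idx[idx$species == "hg", ]
  ew <- idx[idx$species == "ew", ]
  expect_equal(round(hg$chlc_chla, 2), 0.11)   # 1.60 / 14.56
  expect_equal(round(hg$deps, 2), 0.35)        # 0.55 / (0.55 + 1.03)
  expect_equal(round(hg$xcp_chla, 2), 0.11)
  expect_equal(round(ew$chlc_chla, 2), 0.06)
  expect_equal(round(ew$fuco_chla, 2), 0.28)
  expect_equal(round(ew$deps, 2), 0.29)        # 0.56 / (0.56 + 1.36)
  expect_equal(round(ew$xcp_chla, 2), 0.10)
  expect_equal(round(ew$deg_chla, 2), 0.10)
  expect_equal(hg$deg_pig, 5.25)
  expect_equal(ew$deg_pig, 1.92)
})

test_that("indices are scale-invariant and internally consistent", {
  p <- per_cell(simple_table(c(chl_a = 1000, chl_c = 120, fuco = 400,
                               dd = 90, dt = 90, phaeophytins = 50,
                               fuco_like_1 = 20, fuco_like_2 = 10)))
  i1 <- pigment_indices(p)
  p3 <- p; p3$mass_ng <- p3$mass_ng * 3.3
  i3 <- pigment_indices(p3)
  ratio_cols <- c("chlc_chla", "fuco_chla", "dt_dd", "deps", "xcp_chla",
                  "deg_chla")
  expect_equal(i3[, ratio_cols], i1[, ratio_cols], tolerance = 1e-12)
  # DT = DD: dt_dd = 1, deps = 0.5; and deps = dt_dd/(1 + dt_dd) always
  expect_equal(i1$dt_dd, 1)
  expect_equal(i1$deps, 0.5)
  set.seed(3)
  for (k in 1:20) {
    dd <- runif(1, 0.1, 3); dt <- runif(1, 0.01, 2)
    q <- per_cell(simple_table(c(chl_a = 500, dd = dd * 100, dt = dt * 100)))
    iq <- pigment_indices(q)
    expect_equal(iq$deps, iq$dt_dd / (1 + iq$dt_dd), tolerance = 1e-12)
  }
  expect_error(pigment_indices(per_cell(simple_table(c(chl_a = 0, dd = 1)))),
               "chl_a")
})

test_that("per-cell conversion commutes with group averaging", {
  t1 <- simple_table(c(chl_a = 1400, dd = 100), replicate = 1L)
  t2 <- simple_table(c(chl_a = 1600, dd = 120), replicate = 2L)
  both <- pigment_profile(rbind(as.data.frame(t1), as.data.frame(t2)),
                          basis = "per_extract")
  pc <- per_cell(both)
  mean_then <- tapply(pc$mass_ng, pc$pigment, mean)
  then_mean <- tapply(both$mass_ng, both$pigment, mean) / 100
  expect_equal(mean_then[order(names(mean_then))],
               then_mean[order(names(then_mean))], tolerance = 1e-12)
})

test_that("species comparisons use the exact rank-sum where possible", {
  idx <- data.frame(replicate = rep(1:3, 2),
                    species = rep(c("a", "b"), each = 3),
                    chlc_chla = c(0.10, 0.11, 0.12, 0.35, 0.37, 0.40))
  res <- compare_pigment_groups(idx)
  # fully separated n = 3 vs 3: minimum attainable two-sided exact p = 0.1
  expect_equal(res$p.value[res$index == "chlc_chla"], 0.1)
  expect_false(res$significant[res$index == "chlc_chla"])
  same <- idx; same$chlc_chla <- rep(c(0.1, 0.2, 0.3), 2)
  expect_equal(compare_pigment_groups(same)$p.value, 1)
  expect_error(compare_pigment_groups(idx[idx$species == "a", ]),
               "2 species")
})

test_that("synthetic pigment tables honour their moments and determinism", {
  ref <- foram_pigment_reference()
  zero <- make_pigment_table(species_ses = lapply(ref, function(x) x$se * 0),
                             seed = 4)
  idx <- pigment_indices(per_cell(zero))
  # SE = 0: per-cell means reproduce the reference inputs exactly
  pc <- per_cell(zero)
  for (sp in names(ref)) {
    got <- pc[pc$species == sp & pc$replicate == 1, ]
    expect_equal(stats::setNames(got$mass_ng, got$pigment),
                 ref[[sp]]$mean[got$pigment])
  }
  expect_equal(round(idx$chlc_chla[idx$species == "hg"][1], 2), 0.11)
  a <- make_pigment_table(seed = 11)
  b <- make_pigment_table(seed = 11)
  c <- make_pigment_table(seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a$mass_ng >= 0))
})
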