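test_that("relative yields and RYT follow their definitions", {
  expect_equal(relative_yields(60, 100), 0.6)
  expect_equal(relative_yields(100, 100), 1)       # monoculture identity
  expect_equal(relative_yields(0, 100), 0)
  expect_error(relative_yields(10, 0, species = "spX"), "spX")
  expect_equal(relative_yield_total(c(0.6, 0.6)), 1.2)
  expect_equal(relative_yield_total(c(0.5, 0.5)), 1)
  expect_equal(relative_yield_total(c(0.3, 0.7, 0.2, 0.1)), 1.3)
  expect_error(relative_yield_total(numeric(0)), "empty")
})

test_that("overyielding indices match their closed forms", {
  expect_equal(overyield_mean(180, 150), 0.2)
  expect_equal(overyield_mean(150, 150), 0)
  expect_error(overyield_mean(100, 0))
  expect_equal(overyield_max(180, c(100, 200)), -0.1)
  expect_equal(overyield_max(250, c(100, 200)), 0.25)
  expect_equal(corrected_relative_yield(0.6, 2), 1.2)
  expect_equal(corrected_relative_yield(0.25, 4), 1)
  expect_equal(corrected_relative_yield(0.1, 2), 0.2)
})

test_that("D_mean relates to RYT and dominates D_max", {
  set.seed(21)
  for (r in 1:200) {
    mx <- random_mixture()
    # D_max <= D_mean always (max monoculture >= mean monoculture)
    expect_lte(overyield_max(sum(mx$y), mx$bm),
               overyield_mean(sum(mx$y), mean(mx$bm)) + 1e-12)
    # D_mean = RYT - 1 when monoculture biomasses are equal ...
    bm_eq <- rep(mx$bm[1], length(mx$y))
    expect_equal(overyield_mean(sum(mx$y), mean(bm_eq)),
                 sum(mx$y / bm_eq) - 1)
    # ... and when relative yields are uniform across species
    y_unif <- 0.8 * mx$bm
    expect_equal(overyield_mean(sum(y_unif), mean(mx$bm)),
                 sum(y_unif / mx$bm) - 1)
  }
})

test_that("tripartite partition reproduces the worked examples", {
  # pure complementarity: uniform relative-yield increase
  p <- tripartite_partition(c(60, 120), c(100, 200))
  expect_equal(c(p$ne, p$tice, p$tdce, p$de), c(30, 30, 0, 0))
  # pure dominance: RYT = 1, high-BM species gains at the other's expense
  p <- tripartite_partition(c(30, 140), c(100, 200))
  expect_equal(c(p$ne, p$tice, p$tdce, p$de), c(20, 0, 0, 20))
  # mixed case evaluated from the component definitions
  p <- tripartite_partition(c(50, 200), c(100, 200))
  expect_equal(p$ne, 100)
  expect_equal(p$tice, 75)
  expect_equal(p$tdce, 25 / 3)
  expect_equal(p$de, 50 / 3)
  expect_equal(p$ne, p$tice + p$tdce + p$de)
})

test_that("partition matches an independent summed-deviation oracle", {
  set.seed(31)
  for (r in 1:300) {
    mx <- random_mixture()
    p <- tripartite_partition(mx$y, mx$bm)
    bf <- brute_partition(mx$y, mx$bm)
    expect_equal(p$ne, bf$ne)
    expect_equal(p$tice, bf$tice)
    expect_equal(p$tdce, bf$tdce)
    expect_equal(p$de, bf$de)
    # printed covariance argument (delta-RY / RYT) is equivalent
    expect_equal(bf$de, bf$de_printed)
    # additive-partition cross-check: CE = TICE, SE = TDCE + DE
    ap <- additive_partition(mx$y, mx$bm)
    expect_equal(ap$ce, p$tice)
    expect_lt(abs(ap$se - (p$tdce + p$de)), 1e-9)
    # exact identity at relative tolerance
    expect_lt(abs(p$ne - (p$tice + p$tdce + p$de)),
              1e-9 * max(1, abs(p$ne)))
  }
})

test_that("partition scales with biomass and is unit-consistent", {
  set.seed(41)
  mx <- random_mixture(4)
  p1 <- tripartite_partition(mx$y, mx$bm)
  p2 <- tripartite_partition(3.7 * mx$y, 3.7 * mx$bm)
  for (f in c("ne", "tice", "tdce", "de")) {
    expect_equal(p2[[f]], 3.7 * p1[[f]])
  }
  for (f in c("ry", "ryt", "d_mean", "d_max")) {
    expect_equal(p2[[f]], p1[[f]])
  }
  # constant RY/RYT across species => DE = 0 (covariance with a constant)
  p <- tripartite_partition(c(50, 100), c(100, 200))  # RY identical
  expect_equal(p$de, 0)
  expect_equal(p$tdce, 0)
})

test_that("partition errors on degenerate mixtures", {
  expect_error(tripartite_partition(c(0, 0), c(100, 200)), "RYT = 0")
  expect_error(tripartite_partition(c(10, 10), c(100, 200),
                                    sown_prop = c(0.7, 0.6)), "sum to 1")
})

test_that("partition_table covers all mixtures and handles exclusions", {
  e <- default_experiment()
  pt <- partition_table(e$biomass, e$design)
  expect_equal(nrow(pt), 64L)
  expect_true(all(is.na(pt$exclude_reason)))
  # permuting input row order leaves the result unchanged
  set.seed(7)
  shuf <- e$biomass[sample(nrow(e$biomass)), ]
  expect_equal(partition_table(shuf, e$design), pt)
  # a zero monoculture invalidates only the mixtures that reference it
  zero <- e$biomass
  mono <- e$design[e$design$richness == 1, ][1, ]
  zero$biomass[zero$plot_id == mono$plot_id] <- 0
  pt0 <- partition_table(zero, e$design)
  hit <- vapply(pt0$composition, function(cc) {
    mono$composition %in% composition_species(cc)
  }, logical(1)) & pt0$environment == mono$environment
  expect_true(all(!is.na(pt0$exclude_reason[hit])))
  expect_true(all(is.na(pt0$exclude_reason[!hit])))
  expect_true(all(grepl("zero monoculture", pt0$exclude_reason[hit])))
  expect_false(any(is.na(pt0$ne[!hit])))
})

test_that("percent gain summary follows the ratio-of-means convention", {
  pt <- data.frame(environment = "F-S-", y_e = 150, ne = 30, tice = 30,
                   tdce = 0, de = 0, exclude_reason = NA_character_)
  g <- percent_gain_summary(pt)
  expect_equal(g$ne_pct, 20)
  expect_equal(g$tdce_pct, 0)
  # a known uniform proportional gain is recovered from noise-free data
  cfg <- generator_config(seed = 3, delta_c = 0.15, delta_d = 0,
                          delta_t = 0, noise_sd = 0, block_sd = 0,
                          n_species_dropouts = 0)
  e <- generate_experiment(cfg)
  g <- percent_gain_summary(partition_table(e$biomass, e$design),
                            by = NULL)
  expect_equal(g$ne_pct, 15, tolerance = 1e-10)
  expect_equal(g$tice_pct, 15, tolerance = 1e-10)
  # both conventions agree when every mixture has the same proportional
  # gain
  g2 <- percent_gain_summary(partition_table(e$biomass, e$design),
                             by = NULL, method = "mean_of_ratios")
  expect_equal(g2$ne_pct, g$ne_pct)
})
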