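test_that("constructed design reproduces the experimental layout", {
  d <- build_design(default_species_pools(), seed = 5)
  expect_equal(nrow(d), 96L)
  expect_equal(as.integer(table(d$richness)), c(32L, 48L, 16L))
  expect_equal(sum(d$richness > 1), 64L)
  expect_true(all(table(d$block) == 12L))
  # within each block: 4 monocultures, 6 pairs, 2 four-species mixtures
  per_block <- table(d$block, d$richness)
  expect_true(all(per_block[, "1"] == 4L))
  expect_true(all(per_block[, "2"] == 6L))
  expect_true(all(per_block[, "4"] == 2L))
  # every species occurs exactly three times per block
  for (b in unique(d$block)) {
    sp <- unlist(lapply(d$composition[d$block == b], composition_species))
    expect_true(all(table(sp) == 3L))
  }
  # each composition appears once per environment (four-species: twice)
  for (cmp in unique(d$composition)) {
    n_env <- table(factor(d$environment[d$composition == cmp],
                          levels = environment_levels()))
    want <- if (length(composition_species(cmp)) == 4L) 2L else 1L
    expect_true(all(n_env == want))
  }
  # shading at block level, 4 shaded blocks; fertilization balanced within
  # block x richness
  expect_equal(length(unique(d$block[d$shade])), 4L)
  fb <- aggregate(fertilized ~ block + richness, d, sum)
  want_f <- c(`1` = 2L, `2` = 3L, `4` = 1L)
  expect_equal(fb$fertilized, unname(want_f[as.character(fb$richness)]))
})

test_that("design randomization is seed-deterministic and seed-sensitive", {
  expect_identical(build_design(seed = 11), build_design(seed = 11))
  expect_false(identical(build_design(seed = 11), build_design(seed = 12)))
})

test_that("malformed species pools are rejected", {
  pools <- default_species_pools()
  pools$stature[1] <- "tall"   # pool A loses its small grass
  expect_error(build_design(pools, seed = 1), "functional-group x stature")
  expect_error(build_design(pools[-1, ], seed = 1), "exactly 4 species")
})

test_that("monoculture references are environment-specific lookups", {
  d <- tiny_design()
  tab <- tiny_table(mA = 300)
  expect_equal(monoculture_reference(tab, d, "spA", "F-S-"), 300)
  # replicated monocultures (generalization): arithmetic mean
  d2 <- rbind(d, within(d[1, ], plot_id <- "m1b"))
  tab2 <- rbind(tab, data.frame(plot_id = "m1b", species_id = "spA",
                                biomass = 500))
  expect_equal(monoculture_reference(tab2, d2, "spA", "F-S-"), 400)
  expect_error(monoculture_reference(tab, d, "spA", "F+S+"),
               "no monoculture")
  # permuting biomass across environments moves the reference with it
  e <- default_experiment()
  sp <- e$design$composition[e$design$richness == 1][1]
  refs <- vapply(environment_levels(), function(env) {
    monoculture_reference(e$biomass, e$design, sp, env)
  }, numeric(1))
  swapped <- e$biomass
  m_plots <- e$design$plot_id[e$design$richness == 1 &
                                e$design$composition == sp]
  envs <- e$design$environment[match(m_plots, e$design$plot_id)]
  i1 <- which(swapped$plot_id == m_plots[1])
  i2 <- which(swapped$plot_id == m_plots[2])
  tmp <- swapped$biomass[i1]
  swapped$biomass[i1] <- swapped$biomass[i2]
  swapped$biomass[i2] <- tmp
  expect_equal(monoculture_reference(swapped, e$design, sp, envs[1]),
               refs[envs[2]], ignore_attr = TRUE)
})

test_that("table validation separates hard violations from warnings", {
  d <- tiny_design()
  expect_equal(nrow(validate_table(tiny_table(), d)), 0L)
  bad <- tiny_table()
  bad$biomass[3] <- -1
  rep_ <- validate_table(bad, d)
  expect_true(any(rep_$severity == "hard" &
                    rep_$problem == "negative or non-finite biomass"))
  missing <- tiny_table()[-4, ]  # drop the sown spB row of the mixture
  rep_ <- validate_table(missing, d)
  expect_true(any(rep_$severity == "warning" &
                    rep_$problem == "missing row for sown species" &
                    rep_$plot_id == "x1" & rep_$species_id == "spB"))
  dup <- rbind(tiny_table(), tiny_table()[1, ])
  expect_true(any(validate_table(dup, d)$problem == "duplicated row"))
  unk <- tiny_table()
  unk$plot_id[1] <- "nope"
  expect_true(any(validate_table(unk, d)$problem == "unknown plot"))
})
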