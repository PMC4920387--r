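test_that("one-sample tests against reference values are exact", {
  r <- test_mean_against(c(1.1, 1.2, 1.3), 1)
  expect_equal(r$estimate, 1.2)
  expect_equal(r$t, 2 * sqrt(3))          # (x-mu)/(s/sqrt(n)) closed form
  same <- test_mean_against(rep(2, 5), 2)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$note, "zero variance")
  # shifting values and reference together leaves the test unchanged
  v <- c(0.9, 1.4, 1.1, 1.3)
  a <- test_mean_against(v, 1)
  b <- test_mean_against(v + 5, 6)
  expect_equal(a$t, b$t)
  expect_equal(b$estimate, a$estimate + 5)
  # block-aware variant averages within blocks first
  blk <- c(1, 1, 2, 2)
  ba <- test_mean_against(v, 1, block = blk)
  expect_equal(ba$n, 2L)
  expect_equal(ba$estimate, mean(tapply(v, blk, mean)))
})

test_that("species-level preparation applies the richness correction", {
  e <- default_experiment()
  sl <- species_level_prepare(e$biomass, e$design)
  expect_equal(nrow(sl), sum(e$design$richness))   # one row per sown slot
  mono <- sl[sl$richness == 1, ]
  expect_equal(mono$ry_s, rep(1, nrow(mono)))      # RY x S = 1 by definition
  expect_equal(sl$ry_s, sl$ry * sl$richness)
  expect_equal(sl$biomass_s, sl$biomass * sl$richness)
  expect_true(all(sl$fg_id %in% c("grass", "forb")))
  expect_true(all(sl$gs_id %in% c("small", "tall")))
})

test_that("sequential ANOVA is scale invariant and reports directions", {
  e <- default_experiment()
  d <- community_biomass_data(e$biomass, e$design)
  a1 <- fit_sequential_anova(d, "community_biomass")
  expect_equal(attr(a1, "method"), "satterthwaite")
  expect_equal(a1$term, default_fixed_terms("community"))
  d$scaled <- d$community_biomass * 12.5
  a2 <- fit_sequential_anova(d, "scaled")
  expect_equal(a2$F, a1$F, tolerance = 1e-6)
  expect_equal(a2$p, a1$p, tolerance = 1e-6)
  # defaults: shade decreases and fertilization increases biomass
  expect_equal(a1$direction[a1$term == "shade"], -1)
  expect_equal(a1$direction[a1$term == "fertilized"], 1)
})

test_that("Kenward-Roger and Satterthwaite df approximations agree here", {
  skip_if_not_installed("pbkrtest")
  e <- default_experiment()
  d <- community_biomass_data(e$biomass, e$design)
  few <- c("shade", "fertilized", "log_sr", "shade:fertilized")
  s <- fit_sequential_anova(d, "community_biomass", fixed = few,
                            random = "block")
  k <- fit_sequential_anova(d, "community_biomass", fixed = few,
                            random = "block", method = "kenward-roger")
  expect_equal(attr(k, "method"), "kenward-roger")
  expect_equal(k$F, s$F, tolerance = 0.05)
})

test_that("re-randomization inference covers treatment terms only", {
  e <- default_experiment()
  d <- community_biomass_data(e$biomass, e$design)
  set.seed(1)
  a <- fit_sequential_anova(d, "community_biomass", method = "permutation",
                            nperm = 99)
  expect_equal(attr(a, "method"), "permutation")
  treat <- grepl("shade|fertilized", a$term)
  expect_true(all(!is.na(a$p[treat])))
  expect_true(all(is.na(a$p[!treat])))
  expect_true(all(a$p[treat] > 0 & a$p[treat] <= 1))
  # the strong fertilization effect of the default generator is detected
  expect_lt(a$p[a$term == "fertilized"], 0.05)
})

test_that("fertilization effect is detected in most replicates", {
  # power at the design size under the default effect (x1.36)
  hits <- 0L
  for (i in 1:25) {
    e <- generate_experiment(generator_config(seed = 400 + i))
    d <- community_biomass_data(e$biomass, e$design)
    set.seed(i)
    a <- rerandomization_anova(d, "community_biomass", nperm = 99)
    hits <- hits + (a$p[a$term == "fertilized"] < 0.05)
  }
  expect_gte(hits / 25, 0.8)
})

test_that("post-hoc LS-mean differences have pairwise structure", {
  e <- default_experiment()
  d <- community_biomass_data(e$biomass, e$design)
  m <- attr(fit_sequential_anova(
    d, "community_biomass",
    fixed = c("shade", "fertilized", "gs_composition")), "model")
  ph <- posthoc_lsmeans_diff(m, "gs_composition")
  expect_equal(nrow(ph), 3L)                   # k(k-1)/2 for k = 3
  two <- posthoc_lsmeans_diff(m, "shade")
  expect_equal(nrow(two), 1L)                  # 2-level factor
  # antisymmetry: reversing the factor's level order flips the sign
  d2 <- d
  d2$gs_rev <- factor(d$gs_composition,
                      levels = rev(sort(unique(d$gs_composition))))
  m2 <- attr(fit_sequential_anova(
    d2, "community_biomass",
    fixed = c("shade", "fertilized", "gs_rev")), "model")
  ph2 <- posthoc_lsmeans_diff(m2, "gs_rev")
  expect_equal(sort(abs(ph2$estimate)), sort(abs(ph$estimate)),
               tolerance = 1e-6)
})

test_that("noiseless equal group means give zero post-hoc differences", {
  set.seed(3)
  d <- expand.grid(g = c("a", "b", "c"), block = factor(1:8), rep = 1:2)
  # block effects, no group effect; trace noise keeps the fit non-singular
  d$y <- 5 + as.numeric(d$block) * 0.5 + rnorm(nrow(d), sd = 1e-8)
  m <- suppressWarnings(lmerTest::lmer(y ~ g + (1 | block), data = d))
  ph <- posthoc_lsmeans_diff(m, "g")
  expect_equal(ph$estimate, rep(0, 3), tolerance = 1e-6)
})
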