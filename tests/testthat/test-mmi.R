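test_that("all-subsets screening enumerates the candidate set", {
  set.seed(5)
  X <- matrix(rnorm(62 * 12), 62, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  y <- rnorm(62)
  blk <- rep(1:8, length.out = 62)
  m <- all_subsets_mmi(y, X, blk)
  expect_equal(nrow(m$models), 1 + 12 + 66 + 220)   # C(12, 0..3)
  expect_equal(sum(m$models$weight), 1)
  expect_equal(m$models$delta[1], 0)
  av <- model_average(m)
  expect_equal(nrow(av), 12L)
  expect_true(all(av$importance >= 0 & av$importance <= 1))
})

test_that("Akaike weights follow exp(-delta/2) normalization", {
  expect_equal(akaike_weights(c(0, 2)), c(0.7311, 0.2689),
               tolerance = 1e-4)
  expect_equal(sum(akaike_weights(runif(10, 0, 8))), 1)
  # a duplicate of the best model gets the best model's weight
  w <- akaike_weights(c(0, 0, 2))
  expect_equal(w[1], w[2])
})

test_that("internal ML fitter agrees with lme4", {
  set.seed(6)
  X <- matrix(rnorm(62 * 4), 62, 4, dimnames = list(NULL, paste0("v", 1:4)))
  blk <- rep(1:8, length.out = 62)
  y <- 1 + X[, 1] + 0.6 * rnorm(8)[blk] + rnorm(62)
  fast <- all_subsets_mmi(y, X, blk, max_terms = 2, engine = "fast")
  slow <- all_subsets_mmi(y, X, blk, max_terms = 2, engine = "lmer")
  i <- match(fast$models$terms, slow$models$terms)
  expect_equal(fast$models$aic, slow$models$aic[i], tolerance = 1e-5)
  expect_equal(fast$models$logLik, slow$models$logLik[i],
               tolerance = 1e-5)
  cf <- fast$coefs[[1]]
  cs <- slow$coefs[[i[1]]]
  expect_equal(cf, cs[names(cf)], tolerance = 1e-4)
  expect_equal(fast$ses[[1]], slow$ses[[i[1]]][names(fast$ses[[1]])],
               tolerance = 1e-3)
})

test_that("full model averaging uses zero substitution", {
  # hand-built two-model set: weights (0.6, 0.4); predictor only in model 1
  mmi <- structure(list(
    models = data.frame(model_id = 1:2, terms = c("a", "(null)"),
                        k = c(3, 2), logLik = c(0, 0),
                        aic = c(0, 2 * log(0.6 / 0.4)),
                        delta = c(0, 2 * log(0.6 / 0.4)),
                        weight = c(0.6, 0.4)),
    coefs = list(c(`(Intercept)` = 1, a = 10), c(`(Intercept)` = 1)),
    ses = list(c(`(Intercept)` = 0.1, a = 2), c(`(Intercept)` = 0.1)),
    predictors = c("a", "b"), n = 62, criterion = "AIC"),
    class = "befpart_mmi")
  av <- model_average(mmi, delta_max = 10)
  expect_equal(av$estimate[av$predictor == "a"], 6)     # 0.6 x 10
  expect_equal(av$importance[av$predictor == "a"], 0.6)
  expect_equal(av$estimate[av$predictor == "b"], 0)
  expect_equal(av$importance[av$predictor == "b"], 0)
  # delta filter keeping only the first model: estimates are that model's
  av1 <- model_average(mmi, delta_max = 1e-6)
  expect_equal(av1$estimate[av1$predictor == "a"], 10)
  expect_equal(av1$importance[av1$predictor == "a"], 1)
  expect_error(model_average(mmi, delta_max = -1), "delta_max")
})

test_that("weights renormalize after the delta-window filter", {
  set.seed(8)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- X[, 2] * 2 + rnorm(50)
  m <- all_subsets_mmi(y, X, rep(1:5, each = 10), max_terms = 2)
  keep <- m$models$delta < 4
  w <- m$models$weight[keep] / sum(m$models$weight[keep])
  expect_equal(sum(w), 1)
  av <- model_average(m, delta_max = 4)
  # the dominant predictor is in every retained model here
  expect_gt(av$importance[av$predictor == "v2"], 0.99)
})

test_that("synthetic trait responses drive predictor recovery", {
  e <- default_experiment()
  tc <- trait_composition(e$biomass, e$design, e$traits)
  pm <- build_predictor_matrix(tc, e$design, e$biomass)
  blk <- e$design$block[match(pm$plot_id, e$design$plot_id)]
  tr <- generate_trait_response(pm, c(FD_LNC = 1), blk,
                                block_sd = 0.3, noise_sd = 1, seed = 2)
  expect_equal(length(tr$response), nrow(pm))
  expect_equal(sum(tr$coefficients != 0), 1L)
  av <- model_average(all_subsets_mmi(tr$response, pm, blk))
  expect_gt(av$importance[av$predictor == "FD_LNC"], 0.9)
  expect_error(generate_trait_response(pm, c(nope = 1), blk), "unknown")
  # determinism under seed
  tr2 <- generate_trait_response(pm, c(FD_LNC = 1), blk,
                                 block_sd = 0.3, noise_sd = 1, seed = 2)
  expect_identical(tr$response, tr2$response)
})
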