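# Synthetic biodiversity experiments with known ground-truth diversity
# effects.

#' Generator configuration
#'
#' Study conditions for the synthetic experiment.  Defaults reproduce the
#' reference design and effect sizes: 8 blocks x 12 plots, shade reducing
#' expected biomass to 0.76 of control, fertilization raising it to 1.36,
#' monoculture lognormal coefficient of variation 0.26 (matching
#' monoculture means of order 900 +/- 240 g m^-2), and diversity-effect
#' couplings calibrated so that the mean percent biomass gain decomposes
#' approximately as the reference experiment's headline values (TICE ~
#' +21%, DE ~ +12%, TDCE minor, NE ~ +34%).
#'
#' @param seed integer; drives all randomness of the generator.
#' @param n_blocks number of blocks (the constructive design requires 8).
#' @param shade_mult multiplicative shade effect on expected biomass (> 0).
#' @param fert_mult multiplicative fertilization effect (> 0).
#' @param shade_fert_mult additional multiplier applied when both
#'   treatments act (1 = no interaction).
#' @param baseline baseline species biomass (g m^-2) before offsets.
#' @param stature_mult named multipliers for growth stature
#'   (tall > small by default).
#' @param fg_mult named multipliers for functional group.
#' @param pool_mult named multipliers distinguishing the two pools.
#' @param mono_cv lognormal coefficient of variation of the monoculture
#'   biomass draws.
#' @param noise_sd lognormal sd (log scale) of per-species mixture noise.
#' @param block_sd lognormal sd (log scale) of the block multiplier applied
#'   to mixture plots.
#' @param delta_c uniform complementarity shift: every species' true
#'   relative yield exceeds its sown proportion by `delta_c / S`
#'   (so the trait-independent complementarity gain is ~100*delta_c %).
#' @param delta_d dominance coupling: a zero-sum relative-yield transfer of
#'   magnitude `delta_d / S` toward species with higher monoculture
#'   biomass (gain at the expense of others).
#' @param delta_t trait-dependent coupling: non-zero-sum relative-yield
#'   inflation of magnitude `delta_t / S` proportional to monoculture
#'   biomass rank (gain without expense of others).
#' @param n_species_dropouts number of two-species mixture plots in which
#'   one species dies out (biomass 0), as observed in the field.
#' @param trait_cv lognormal CV of species x environment trait values.
#' @return list of class `befpart_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_blocks = 8L,
                             shade_mult = 0.76,
                             fert_mult = 1.36,
                             shade_fert_mult = 1,
                             baseline = 400,
                             stature_mult = c(small = 0.8, tall = 1.6),
                             fg_mult = c(grass = 1.15, forb = 0.9),
                             pool_mult = c(A = 1, B = 1.05),
                             mono_cv = 0.26,
                             noise_sd = 0.2,
                             block_sd = 0.15,
                             delta_c = 0.21,
                             delta_d = 0.5,
                             delta_t = 0,
                             n_species_dropouts = 2L,
                             trait_cv = 0.05) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(shade_mult > 0, fert_mult > 0, shade_fert_mult > 0,
              baseline > 0, mono_cv >= 0, noise_sd >= 0, block_sd >= 0,
              trait_cv >= 0, n_species_dropouts >= 0)
  })
  if (cfg$n_blocks != 8L) {
    stop("the constructive design supports n_blocks = 8", call. = FALSE)
  }
  structure(cfg, class = "befpart_config")
}

# Expected (noise-free) species biomass mean per environment.
species_env_mean <- function(cfg, pools, shade, fertilized) {
  base <- cfg$baseline *
    cfg$stature_mult[pools$stature] *
    cfg$fg_mult[pools$functional_group] *
    cfg$pool_mult[pools$pool]
  unname(base) *
    ifelse(shade, cfg$shade_mult, 1) *
    ifelse(fertilized, cfg$fert_mult, 1) *
    ifelse(shade & fertilized, cfg$shade_fert_mult, 1)
}

# lognormal draw with mean mu and coefficient of variation cv
rlnorm_mean_cv <- function(n, mu, cv) {
  if (cv == 0) return(rep(mu, length.out = n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mu) - sdl^2 / 2, sdlog = sdl)
}

# mean-1 lognormal multiplicative noise with log-scale sd
rlnorm_unit <- function(n, sdl) {
  if (sdl == 0) return(rep(1, n))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# True relative-yield shares for one mixture given monoculture skeleton
# values: 1/S + delta_c/S + (delta_d/S) u + (delta_t/S) (1+u)/2, where
# u = (M - mean(M)) / max|M - mean(M)| is the zero-sum dominance direction.
true_shares <- function(M, cfg) {
  s <- length(M)
  v <- M - mean(M)
  u <- if (max(abs(v)) > 0) v / max(abs(v)) else rep(0, s)
  share <- 1 / s + cfg$delta_c / s + (cfg$delta_d / s) * u +
    (cfg$delta_t / s) * (1 + u) / 2
  if (any(share < 0)) {
    stop("generator config drives an expected species biomass below zero ",
         "(couplings too strong)", call. = FALSE)
  }
  share
}

# Trait mean structure: base value per trait with functional-group,
# stature and environment multipliers (shade raises SLA and Hmax,
# fertilization raises tissue nitrogen, etc.).
trait_mean <- function(trait, fg, stature, shade, fertilized) {
  base <- switch(trait,
    SLA = if (fg == "forb") 25 else 20,
    SRL = if (fg == "grass") 180 else 90,
    LNC = if (fg == "forb") 25 else 18,
    RNC = if (fg == "forb") 12 else 8,
    Hmax = (if (stature == "tall") 90 else 35) +
      (if (fg == "grass") 10 else 0),
    WMD = (if (fg == "grass") 12 else 18) *
      (if (stature == "tall") 1.2 else 1))
  if (trait == "SLA" && stature == "small") base <- base + 2
  if (trait == "SRL" && stature == "small") base <- base * 1.1
  env <- switch(trait,
    SLA = (if (shade) 1.2 else 1) * (if (fertilized) 1.05 else 1),
    SRL = if (fertilized) 0.9 else 1,
    LNC = (if (fertilized) 1.25 else 1) * (if (shade) 1.1 else 1),
    RNC = if (fertilized) 1.2 else 1,
    Hmax = (if (shade) 1.15 else 1) * (if (fertilized) 1.1 else 1),
    WMD = if (fertilized) 0.9 else 1)
  base * env
}

#' Generate a complete synthetic experiment
#'
#' Draws monoculture biomasses lognormally around species x environment
#' means, constructs mixture species biomass as
#' `M_ie * share_i * block_mult * noise` where the true shares encode the
#' configured complementarity (`delta_c`), dominance (`delta_d`) and
#' trait-dependent (`delta_t`) couplings, applies the configured species
#' dropouts, and generates an environment-specific trait table.  The
#' noise-free skeleton and the exact per-mixture true partition components
#' are returned as ground truth.
#'
#' @param config a [generator_config()].
#' @param pools species metadata.
#' @return list of class `befpart_experiment`: `design` (annotated),
#'   `biomass` (long table), `traits`, `truth` (per-mixture true RYT and
#'   NE/TICE/TDCE/DE), `skeleton` (per plot x species noise-free `M` and
#'   `share`), `config`.
#' @export
generate_experiment <- function(config = generator_config(),
                                pools = default_species_pools()) {
  cfg <- config
  design <- annotate_composition(build_design(pools, seed = cfg$seed),
                                 pools)
  with_seed(cfg$seed + 1L, {
    envs <- environment_levels()
    M <- matrix(NA_real_, nrow(pools), length(envs),
                dimnames = list(pools$species_id, envs))
    # one latent lognormal deviation per species, shared across
    # environments: each M_ie is marginally lognormal around the species x
    # environment mean, but environments differ only through the
    # systematic treatment multipliers, so "no treatment effect" is a
    # sharp null (a plot's biomass does not depend on its assignment)
    sdl <- sqrt(log(1 + cfg$mono_cv^2))
    z <- rnorm(nrow(pools))
    for (e in envs) {
      ee <- as_environment(e)
      mu <- species_env_mean(cfg, pools, ee$shade, ee$fertilized)
      M[, e] <- mu * exp(z * sdl - sdl^2 / 2)
    }
    block_mult <- rlnorm_unit(cfg$n_blocks, cfg$block_sd)
    mix <- design[design$richness > 1L, ]
    two_sp <- mix$plot_id[mix$richness == 2L]
    dropout_plots <- if (cfg$n_species_dropouts > 0L) {
      sample(two_sp, min(cfg$n_species_dropouts, length(two_sp)))
    } else character(0)

    # monoculture plots observe the species x environment draw directly
    mono <- design[design$richness == 1L, ]
    sp_list <- strsplit(mix$composition, "+", fixed = TRUE)
    nsp <- lengths(sp_list)
    mp <- rep(seq_len(nrow(mix)), nsp)
    sk_plot <- rep(mix$plot_id, nsp)
    sk_species <- unlist(sp_list)
    sk_M <- M[cbind(sk_species, mix$environment[mp])]
    sk_share <- numeric(length(sk_M))
    for (i in seq_len(nrow(mix))) {
      idx <- which(mp == i)
      share <- true_shares(sk_M[idx], cfg)
      if (mix$plot_id[i] %in% dropout_plots) {
        share[sample(length(idx), 1L)] <- 0
      }
      sk_share[idx] <- share
    }
    eps <- rlnorm_unit(length(sk_M), cfg$noise_sd)
    y <- sk_M * sk_share * block_mult[mix$block[mp]] * eps
    biomass <- data.frame(
      plot_id = c(mono$plot_id, sk_plot),
      species_id = c(mono$composition, sk_species),
      biomass = c(M[cbind(mono$composition, mono$environment)], y),
      stringsAsFactors = FALSE)
    skeleton <- data.frame(plot_id = sk_plot, species_id = sk_species,
                           M = sk_M, share = sk_share,
                           stringsAsFactors = FALSE)

    traits <- expand.grid(species_id = pools$species_id,
                          environment = envs, trait = trait_names(),
                          stringsAsFactors = FALSE)
    attr(traits, "out.attrs") <- NULL
    mu_t <- numeric(nrow(traits))
    for (e in envs) {
      ee <- as_environment(e)
      for (tr in trait_names()) {
        i <- which(traits$environment == e & traits$trait == tr)
        sp_i <- match(traits$species_id[i], pools$species_id)
        mu_t[i] <- vapply(sp_i, function(j) {
          trait_mean(tr, pools$functional_group[j], pools$stature[j],
                     ee$shade, ee$fertilized)
        }, numeric(1))
      }
    }
    # persistent species-specific trait deviations (drawn once per species
    # x trait, shared across environments): species combine traits
    # idiosyncratically, which keeps single-trait diversity predictors
    # from being collinear across traits
    sp_dev <- matrix(exp(rnorm(nrow(pools) * length(trait_names()),
                               sd = 0.25)),
                     nrow(pools), length(trait_names()),
                     dimnames = list(pools$species_id, trait_names()))
    traits$value <- rlnorm_mean_cv(
      nrow(traits), mu_t * sp_dev[cbind(traits$species_id, traits$trait)],
      cfg$trait_cv)

    exp_ <- structure(list(design = design, biomass = biomass,
                           traits = traits, skeleton = skeleton,
                           config = cfg), class = "befpart_experiment")
    exp_$truth <- true_partition(exp_)
    exp_
  })
}

#' @export
print.befpart_experiment <- function(x, ...) {
  cat("Synthetic biodiversity experiment:", nrow(x$design), "plots,",
      sum(x$design$richness > 1), "mixtures, seed", x$config$seed, "\n")
  invisible(x)
}

#' True partition components from the noise-free skeleton
#'
#' Applies the exact tripartite partition to the generator's deterministic
#' skeleton (species biomass `M * share`, monoculture reference `M`),
#' giving the ground-truth NE/TICE/TDCE/DE of every mixture.
#'
#' @param experiment a [generate_experiment()] result.
#' @param plot_id optional subset of mixture plot ids.
#' @return data.frame: `plot_id`, `true_ryt`, `true_ne`, `true_tice`,
#'   `true_tdce`, `true_de`.
#' @export
true_partition <- function(experiment, plot_id = NULL) {
  sk <- experiment$skeleton
  idx <- split(seq_len(nrow(sk)),
               factor(sk$plot_id, levels = unique(sk$plot_id)))
  ids <- if (is.null(plot_id)) names(idx) else plot_id
  vals <- vapply(ids, function(pid) {
    i <- idx[[pid]]
    p <- tripartite_partition(y_obs = sk$M[i] * sk$share[i],
                              bm_mono = sk$M[i],
                              species = sk$species_id[i])
    c(p$ryt, p$ne, p$tice, p$tdce, p$de)
  }, numeric(5))
  res <- data.frame(plot_id = ids, true_ryt = vals[1, ],
                    true_ne = vals[2, ], true_tice = vals[3, ],
                    true_tdce = vals[4, ], true_de = vals[5, ],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Synthetic responses for multimodel-inference recovery tests
#'
#' Builds a response as a linear combination of chosen (z-scored)
#' predictors plus a block effect and Gaussian noise, returning the true
#' coefficient vector.
#'
#' @param predictors predictor data.frame/matrix (a `plot_id` column is
#'   ignored).
#' @param coefficients named numeric vector of true effects on the
#'   standardized scale (names must match predictor columns; others are 0).
#' @param block block ids, one per row.
#' @param block_sd sd of the Gaussian block effect.
#' @param noise_sd sd of the residual noise.
#' @param seed RNG seed.
#' @return list with `response` and `coefficients` (full-length, zeros for
#'   inactive predictors).
#' @export
generate_trait_response <- function(predictors, coefficients, block,
                                    block_sd = 0.5, noise_sd = 1,
                                    seed = 1L) {
  predictors <- as.data.frame(predictors)
  predictors$plot_id <- NULL
  X <- scale(as.matrix(predictors))
  beta <- setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(coefficients), names(beta))
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  beta[names(coefficients)] <- coefficients
  block <- factor(block)
  with_seed(seed, {
    be <- rnorm(nlevels(block), sd = block_sd)
    y <- drop(X %*% beta) + be[as.integer(block)] +
      rnorm(nrow(X), sd = noise_sd)
    list(response = y, coefficients = beta)
  })
}
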