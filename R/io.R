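# CSV I/O, pipeline configuration, and the end-to-end pipeline.

#' Read a community biomass table
#'
#' Plain CSV with header.  Required columns: `plot_id`, `species_id`, and
#' either `biomass` (annual) or both `spring_biomass` and `summer_biomass`
#' (summed to annual).
#'
#' @param path CSV file path.
#' @return data.frame (`plot_id`, `species_id`, `biomass`).
#' @export
read_biomass_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need_id <- c("plot_id", "species_id")
  miss <- setdiff(need_id, names(d))
  if (length(miss)) {
    stop("biomass table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("spring_biomass", "summer_biomass") %in% names(d))) {
    bm <- d$spring_biomass + d$summer_biomass
  } else if ("biomass" %in% names(d)) {
    bm <- d$biomass
  } else {
    stop("biomass table lacks column(s): biomass ",
         "(or spring_biomass + summer_biomass)", call. = FALSE)
  }
  if (!is.numeric(bm)) {
    bad <- which(is.na(suppressWarnings(as.numeric(bm))))
    stop("non-numeric biomass in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  data.frame(plot_id = as.character(d$plot_id),
             species_id = as.character(d$species_id),
             biomass = bm, stringsAsFactors = FALSE)
}

#' Read a trait table
#' @param path CSV with columns `species_id`, `environment`, `trait`,
#'   `value`.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species_id", "environment", "trait", "value"),
                  names(d))
  if (length(miss)) {
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(d$value)) stop("trait values must be numeric",
                                 call. = FALSE)
  d
}

#' Read a plot design table
#' @param path CSV as written by [write_table()] from [build_design()].
#' @return data.frame with logical `shade`/`fertilized` restored.
#' @export
read_design_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("plot_id", "block", "composition", "richness",
                    "shade", "fertilized"), names(d))
  if (length(miss)) {
    stop("design table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$shade <- as.logical(d$shade)
  d$fertilized <- as.logical(d$fertilized)
  d
}

#' Write a table as CSV at full precision
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()], either
#' from arguments or from a YAML file.  Unknown keys are rejected.
#'
#' @param ... configuration values: `seed`, `simulate` (logical; generate
#'   the data instead of reading), `biomass_path`, `trait_path`,
#'   `design_path`, `out_dir`, `df_method`
#'   (satterthwaite/kenward-roger/permutation), `delta_max`, `max_terms`,
#'   `use_aicc`, `percent_gain_method`, `distance`, `generator` (list of
#'   [generator_config()] overrides).
#' @param file optional YAML file; values in `...` override it.
#' @return list of class `befpart_pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(seed = 1L, simulate = TRUE, biomass_path = NULL,
                   trait_path = NULL, design_path = NULL,
                   out_dir = NULL, df_method = "satterthwaite",
                   delta_max = 4, max_terms = 3L, use_aicc = FALSE,
                   percent_gain_method = "ratio_of_means",
                   distance = "absolute", generator = list())
  vals <- list()
  if (!is.null(file)) vals <- yaml::read_yaml(file)
  vals <- modifyList(vals, list(...))
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, vals)
  structure(cfg, class = "befpart_pipeline_config")
}

#' Per-plot community biomass with model covariates
#'
#' Sums species biomass to community biomass per plot and joins the design
#' covariates used by the sequential ANOVA (including `log_sr`).
#'
#' @param biomass community biomass table.
#' @param design plot design (annotated; see [annotate_composition()]).
#' @return data.frame, one row per plot, with `community_biomass`.
#' @export
community_biomass_data <- function(biomass, design) {
  comm <- aggregate(biomass ~ plot_id, biomass, sum)
  names(comm)[2] <- "community_biomass"
  out <- merge(design, comm, by = "plot_id")
  out$log_sr <- log(out$richness)
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a community biomass table, validates it, computes
#' the per-mixture overyielding/partition table, per-environment percent
#' gains, trait composition and the transformed predictor matrix, the
#' sequential ANOVAs for community biomass and the diversity-effect
#' responses, one-sample tests (RYT != 1, D_max != 0, components != 0),
#' and the three trait-based multimodel-averaged tables (TICE, TDCE, DE).
#' If `out_dir` is set, all result tables plus the resolved configuration
#' are written there as CSV/YAML.
#'
#' @param config a [pipeline_config()].
#' @return list of class `befpart_result` with elements `design`,
#'   `biomass`, `validation`, `partition`, `percent_gain`, `overyield_tests`,
#'   `trait_composition`, `predictors`, `anova` (list), `averaged` (list of
#'   per-response model-averaged tables), `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  pools <- default_species_pools()
  if (isTRUE(cfg$simulate)) {
    gen <- do.call(generator_config,
                   modifyList(list(seed = cfg$seed), cfg$generator))
    exp_ <- generate_experiment(gen, pools)
    design <- exp_$design
    biomass <- exp_$biomass
    traits <- exp_$traits
  } else {
    if (is.null(cfg$biomass_path) || is.null(cfg$design_path)) {
      stop("non-simulated runs need biomass_path and design_path",
           call. = FALSE)
    }
    design <- annotate_composition(read_design_table(cfg$design_path),
                                   pools)
    biomass <- read_biomass_table(cfg$biomass_path)
    traits <- if (!is.null(cfg$trait_path)) read_trait_table(cfg$trait_path)
  }
  validation <- validate_table(biomass, design)
  if (any(validation$severity == "hard")) {
    stop("input biomass table fails validation (",
         sum(validation$severity == "hard"), " hard violation(s))",
         call. = FALSE)
  }
  ptab <- partition_table(biomass, design)
  gains <- percent_gain_summary(ptab, by = "environment",
                                method = cfg$percent_gain_method)
  ok <- ptab[is.na(ptab$exclude_reason), ]
  overyield_tests <- list(
    ryt = test_mean_against(ok$ryt, 1),
    d_max = test_mean_against(ok$d_max, 0),
    ne = test_mean_against(ok$ne, 0),
    tice = test_mean_against(ok$tice, 0),
    tdce = test_mean_against(ok$tdce, 0),
    de = test_mean_against(ok$de, 0))

  # community biomass ANOVA over all plots
  comm <- community_biomass_data(biomass, design)
  anova_biomass <- fit_sequential_anova(
    comm, "community_biomass", method = cfg$df_method)
  # diversity-effect ANOVAs over mixtures
  mixdat <- merge(design, ok[, c("plot_id", "ryt", "d_max", "ne", "tice",
                                 "tdce", "de")], by = "plot_id")
  mixdat$log_sr <- log(mixdat$richness)
  anovas <- list(community_biomass = anova_biomass)
  for (resp in c("ryt", "d_max", "ne", "tice", "tdce", "de")) {
    anovas[[resp]] <- fit_sequential_anova(mixdat, resp,
                                           method = cfg$df_method)
  }

  tc <- NULL
  predictors <- NULL
  averaged <- list()
  if (!is.null(traits)) {
    tc <- trait_composition(biomass, design, traits,
                            distance = cfg$distance)
    predictors <- build_predictor_matrix(tc, design, biomass)
    resp <- ok[match(predictors$plot_id, ok$plot_id),
               c("tice", "tdce", "de")]
    blk <- design$block[match(predictors$plot_id, design$plot_id)]
    for (v in c("tice", "tdce", "de")) {
      keep <- is.finite(resp[[v]])
      mmi <- all_subsets_mmi(resp[[v]][keep],
                             predictors[keep, , drop = FALSE],
                             block = blk[keep],
                             max_terms = cfg$max_terms,
                             use_aicc = cfg$use_aicc)
      averaged[[v]] <- model_average(mmi, delta_max = cfg$delta_max)
    }
  }

  res <- structure(list(
    design = design, biomass = biomass, validation = validation,
    partition = ptab, percent_gain = gains,
    overyield_tests = overyield_tests, trait_composition = tc,
    predictors = predictors, anova = anovas, averaged = averaged,
    summary = list(
      n_plots = nrow(design),
      n_mixtures = sum(design$richness > 1L),
      n_partitioned = nrow(ok),
      frac_ryt_gt_1 = mean(ok$ryt > 1),
      frac_dmax_gt_0 = mean(ok$d_max > 0),
      config = cfg)), class = "befpart_result")
  if (!is.null(cfg$out_dir)) write_result_bundle(res, cfg$out_dir)
  res
}

#' @export
print.befpart_result <- function(x, ...) {
  s <- x$summary
  cat("befpart pipeline result:", s$n_plots, "plots,", s$n_mixtures,
      "mixtures,", s$n_partitioned, "partitioned\n")
  cat(sprintf("  RYT > 1 in %.0f%% of mixtures; D_max > 0 in %.0f%%\n",
              100 * s$frac_ryt_gt_1, 100 * s$frac_dmax_gt_0))
  cat("Percent biomass gain by environment:\n")
  print(x$percent_gain, digits = 3, row.names = FALSE)
  invisible(x)
}

# Write all pipeline tables plus the resolved config.
write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(res$design, file.path(out_dir, "design.csv"))
  write_table(res$biomass, file.path(out_dir, "biomass.csv"))
  write_table(res$partition, file.path(out_dir, "partition.csv"))
  write_table(res$percent_gain, file.path(out_dir, "percent_gain.csv"))
  if (nrow(res$validation)) {
    write_table(res$validation, file.path(out_dir, "validation.csv"))
  }
  if (!is.null(res$trait_composition)) {
    write_table(res$trait_composition,
                file.path(out_dir, "trait_composition.csv"))
    write_table(res$predictors, file.path(out_dir, "predictors.csv"))
    excl <- attr(res$predictors, "exclusions")
    if (!is.null(excl) && nrow(excl)) {
      write_table(excl, file.path(out_dir, "predictor_exclusions.csv"))
    }
  }
  for (nm in names(res$anova)) {
    write_table(as.data.frame(res$anova[[nm]]),
                file.path(out_dir, paste0("anova_", nm, ".csv")))
  }
  for (nm in names(res$averaged)) {
    write_table(res$averaged[[nm]],
                file.path(out_dir, paste0("averaged_", nm, ".csv")))
  }
  cfg <- res$summary$config
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null,
                                        logical(1))],
                   file.path(out_dir, "config_resolved.yaml"))
  invisible(out_dir)
}
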