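# Overyielding metrics and the tripartite partition of net diversity effects.

#' Species relative yields
#'
#' The relative yield of species i is its observed mixture biomass divided
#' by its monoculture biomass in the same resource environment,
#' \eqn{RY_i = Y_{Oi} / BM_i}.
#'
#' @param y_obs numeric vector of observed per-species mixture biomass
#'   (g m^-2, >= 0).
#' @param bm_mono numeric vector of monoculture reference biomass (> 0).
#' @param species optional species ids used in error messages.
#' @return numeric vector of relative yields.
#' @export
relative_yields <- function(y_obs, bm_mono, species = NULL) {
  stopifnot(length(y_obs) == length(bm_mono))
  if (any(y_obs < 0)) stop("observed biomass must be >= 0", call. = FALSE)
  bad <- which(!(bm_mono > 0))
  if (length(bad)) {
    lab <- if (is.null(species)) paste("component", bad) else species[bad]
    stop("relative yield undefined: zero/negative monoculture biomass for ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  y_obs / bm_mono
}

#' Relative yield total
#'
#' Sum of component relative yields; RYT > 1 indicates non-transgressive
#' overyielding (the mixture outperforms the average of its monocultures).
#'
#' @param ry numeric vector of relative yields.
#' @return RYT (dimensionless).
#' @export
relative_yield_total <- function(ry) {
  if (length(ry) == 0L) stop("empty relative-yield vector", call. = FALSE)
  sum(ry)
}

#' Non-transgressive overyielding D_mean
#'
#' \eqn{D_{mean} = (Y_O - \bar{BM}) / \bar{BM}}.  Coincides with RYT - 1
#' when the component monocultures have equal biomass or when relative
#' yields are uniform across species; in general the two measure
#' overyielding on different weightings of the monocultures.
#'
#' @param y_total observed total mixture biomass (g m^-2).
#' @param bm_mean average monoculture biomass of the component species.
#' @return D_mean (dimensionless).
#' @export
overyield_mean <- function(y_total, bm_mean) {
  if (!(bm_mean > 0)) stop("mean monoculture biomass must be > 0",
                           call. = FALSE)
  (y_total - bm_mean) / bm_mean
}

#' Transgressive overyielding D_max
#'
#' \eqn{D_{max} = (Y_O - \max BM_i) / \max BM_i}; D_max > 0 means the
#' mixture outperforms its best monoculture.
#'
#' @param y_total observed total mixture biomass (g m^-2).
#' @param bm_mono vector of monoculture biomasses of the component species.
#' @return D_max (dimensionless).
#' @export
overyield_max <- function(y_total, bm_mono) {
  m <- max(bm_mono)
  if (!(m > 0)) stop("maximum monoculture biomass must be > 0", call. = FALSE)
  (y_total - m) / m
}

#' Relative yields corrected for sowing proportions
#'
#' Multiplying RY_i by the sown species number S rescales relative yields so
#' that values > 1 mean a species performs better in mixture than in its
#' monoculture, = 1 equal, < 1 worse.
#'
#' @param ry relative yield(s).
#' @param s sown species richness (>= 1).
#' @return corrected relative yield(s).
#' @export
corrected_relative_yield <- function(ry, s) {
  stopifnot(s >= 1)
  ry * s
}

#' Tripartite partition of the net diversity effect
#'
#' Splits the net diversity effect NE (observed minus expected mixture
#' biomass) into three additive components:
#' \itemize{
#'   \item TICE, trait-independent complementarity:
#'     \eqn{S \cdot \overline{\Delta RY} \cdot \overline{BM}} — a uniform
#'     average increase of relative yields (niche differentiation,
#'     facilitation); identical to the Loreau-Hector complementarity effect;
#'   \item DE, dominance: \eqn{S \cdot cov(BM_i, RY_i/RYT - p_i)} — species
#'     with high monoculture biomass gaining mixture share at the expense of
#'     others;
#'   \item TDCE, trait-dependent complementarity:
#'     \eqn{S \cdot cov(BM_i, RY_i - RY_i/RYT)} — high-monoculture-biomass
#'     species gaining relative yield without depressing others.
#' }
#' Covariances use the population convention (divide by S), which makes
#' \eqn{NE = TICE + TDCE + DE} an exact identity.  The expected relative
#' yield of species i is its sown proportion \eqn{p_i} (1/S for the
#' equal-proportion sowing of the reference design).
#'
#' @param y_obs observed per-species mixture biomass (g m^-2).
#' @param bm_mono monoculture reference biomass per species (> 0).
#' @param sown_prop sown proportions (default equal, 1/S); must sum to 1.
#' @param species optional species ids.
#' @return object of class `befpart_partition`: list with `S`, `species`,
#'   `ry`, `ryt`, `d_mean`, `d_max`, `y_e` (expected biomass), `ne`, `tice`,
#'   `tdce`, `de`, and the additive-partition cross-check `ce`, `se`.
#' @examples
#' p <- tripartite_partition(y_obs = c(50, 200), bm_mono = c(100, 200))
#' p$ne - (p$tice + p$tdce + p$de)  # 0
#' @export
tripartite_partition <- function(y_obs, bm_mono,
                                 sown_prop = rep(1 / length(y_obs),
                                                 length(y_obs)),
                                 species = NULL) {
  s <- length(y_obs)
  stopifnot(length(bm_mono) == s, length(sown_prop) == s)
  if (abs(sum(sown_prop) - 1) > 1e-8) {
    stop("sown proportions must sum to 1", call. = FALSE)
  }
  ry <- relative_yields(y_obs, bm_mono, species)
  ryt <- relative_yield_total(ry)
  if (ryt == 0) {
    stop("partition undefined: RYT = 0 (all species dead in mixture)",
         call. = FALSE)
  }
  d_ry <- ry - sown_prop
  y_e <- sum(sown_prop * bm_mono)
  ne <- sum(y_obs) - y_e
  tice <- s * mean(d_ry) * mean(bm_mono)
  de <- s * cov_pop(bm_mono, ry / ryt - sown_prop)
  tdce <- s * cov_pop(bm_mono, ry - ry / ryt)
  structure(list(
    S = s, species = species, ry = ry, ryt = ryt,
    d_mean = overyield_mean(sum(y_obs), mean(bm_mono)),
    d_max = overyield_max(sum(y_obs), bm_mono),
    y_e = y_e, ne = ne, tice = tice, tdce = tdce, de = de,
    ce = tice, se = s * cov_pop(bm_mono, d_ry)
  ), class = "befpart_partition")
}

#' @export
print.befpart_partition <- function(x, ...) {
  cat("Tripartite diversity-effect partition (S =", x$S, ")\n")
  cat(sprintf("  RYT = %.4f  D_mean = %.4f  D_max = %.4f\n",
              x$ryt, x$d_mean, x$d_max))
  cat(sprintf("  NE = %.3f = TICE %.3f + TDCE %.3f + DE %.3f  (g m^-2)\n",
              x$ne, x$tice, x$tdce, x$de))
  invisible(x)
}

#' Loreau-Hector additive partition
#'
#' The two-way partition of NE into complementarity (CE) and selection (SE)
#' effects.  Serves as an independent algebraic cross-check of the
#' tripartite partition: CE = TICE and SE = TDCE + DE.
#'
#' @inheritParams tripartite_partition
#' @return list with `ce` and `se` (g m^-2).
#' @export
additive_partition <- function(y_obs, bm_mono,
                               sown_prop = rep(1 / length(y_obs),
                                               length(y_obs)),
                               species = NULL) {
  s <- length(y_obs)
  ry <- relative_yields(y_obs, bm_mono, species)
  d_ry <- ry - sown_prop
  list(ce = s * mean(d_ry) * mean(bm_mono),
       se = s * cov_pop(bm_mono, d_ry))
}

#' Per-mixture partition table
#'
#' Applies the tripartite partition to every mixture plot (S > 1) of a
#' validated biomass table, using environment-matched monoculture
#' references.  Mixtures with a zero monoculture reference (relative yields
#' undefined) are reported with NA metrics and a reason.
#'
#' @param table community biomass table (`plot_id`, `species_id`, `biomass`).
#' @param design plot design as from [build_design()].
#' @return data.frame, one row per mixture plot: identifiers, `y_obs`,
#'   `y_e`, `ry` columns summarised as `ryt`, `d_mean`, `d_max`, `ne`,
#'   `tice`, `tdce`, `de`, `ce`, `se`, and `exclude_reason` (NA when
#'   computed).
#' @export
partition_table <- function(table, design) {
  rep_ <- validate_table(table, design)
  if (any(rep_$severity == "hard")) {
    stop("biomass table fails validation; see validate_table()",
         call. = FALSE)
  }
  # environment-specific monoculture reference lookup (mean over replicate
  # monocultures, matching monoculture_reference())
  mono <- design[design$richness == 1L, ]
  midx <- match(table$plot_id, mono$plot_id)
  sel <- !is.na(midx) & table$species_id == mono$composition[midx]
  mono_rows <- table[sel, ]
  mono_env <- mono$environment[midx[sel]]
  ref <- tapply(mono_rows$biomass,
                list(mono_rows$species_id, mono_env), mean)
  bio_key <- paste(table$plot_id, table$species_id)
  mix <- design[design$richness > 1L, ]
  mix <- mix[order(mix$plot_id), ]
  n <- nrow(mix)
  num <- matrix(NA_real_, n, 11,
                dimnames = list(NULL, c("y_obs", "y_e", "ryt", "d_mean",
                                        "d_max", "ne", "tice", "tdce",
                                        "de", "ce", "se")))
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sp <- composition_species(mix$composition[i])
    y <- table$biomass[match(paste(mix$plot_id[i], sp), bio_key)]
    y[is.na(y)] <- 0  # missing row for a sown species = died out
    bm <- ref[cbind(sp, mix$environment[i])]
    if (anyNA(bm)) {
      stop("no monoculture reference for ",
           paste(sp[is.na(bm)], collapse = ", "), " in environment ",
           mix$environment[i], call. = FALSE)
    }
    num[i, "y_obs"] <- sum(y)
    if (any(bm <= 0)) {
      reason[i] <- paste0("zero monoculture reference: ",
                          paste(sp[bm <= 0], collapse = ", "))
      next
    }
    p <- tripartite_partition(y, bm, species = sp)
    num[i, -1] <- c(p$y_e, p$ryt, p$d_mean, p$d_max, p$ne, p$tice,
                    p$tdce, p$de, p$ce, p$se)
  }
  res <- data.frame(plot_id = mix$plot_id, block = mix$block,
                    pool = mix$pool, richness = mix$richness,
                    composition = mix$composition,
                    environment = mix$environment, shade = mix$shade,
                    fertilized = mix$fertilized, num,
                    exclude_reason = reason, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Percent biomass gain attributable to diversity-effect components
#'
#' For each group (by default the resource environment) the biomass gain is
#' expressed as a percentage of the expected biomass:
#' \eqn{100 \cdot \overline{component} / \overline{Y_E}} (ratio of group
#' means, the default, robust to small Y_E) or the mean of per-mixture
#' ratios (`method = "mean_of_ratios"`).
#'
#' @param ptab partition table from [partition_table()].
#' @param by grouping column name (default `"environment"`); use `NULL` for
#'   a single overall group.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return data.frame with group, `n`, and percent gain columns `ne_pct`,
#'   `tice_pct`, `tdce_pct`, `de_pct`.
#' @export
percent_gain_summary <- function(ptab, by = "environment",
                                 method = c("ratio_of_means",
                                            "mean_of_ratios")) {
  method <- match.arg(method)
  ok <- ptab[is.na(ptab$exclude_reason), ]
  groups <- if (is.null(by)) list(overall = ok) else split(ok, ok[[by]])
  res <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) == 0L) {
      return(data.frame(group = g, n = 0L, ne_pct = NA_real_,
                        tice_pct = NA_real_, tdce_pct = NA_real_,
                        de_pct = NA_real_))
    }
    pct <- function(comp) {
      if (method == "ratio_of_means") 100 * mean(comp) / mean(d$y_e)
      else mean(100 * comp / d$y_e)
    }
    data.frame(group = g, n = nrow(d), ne_pct = pct(d$ne),
               tice_pct = pct(d$tice), tdce_pct = pct(d$tdce),
               de_pct = pct(d$de))
  })
  out <- do.call(rbind, res)
  names(out)[1] <- if (is.null(by)) "group" else by
  rownames(out) <- NULL
  out
}
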