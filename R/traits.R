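# Community-weighted mean traits and single-trait Rao quadratic entropy.

#' Canonical trait names
#'
#' The six functional traits used throughout: specific leaf area (SLA,
#' m2 kg-1), specific root length (SRL, m g-1), leaf and root nitrogen
#' concentration (LNC, RNC, mg g-1), maximum stretched shoot length (Hmax,
#' cm) and weighted mean depth of standing root biomass (WMD, cm).
#'
#' @return character vector of trait names.
#' @export
trait_names <- function() c("SLA", "SRL", "LNC", "RNC", "Hmax", "WMD")

# Traits whose community-weighted means are natural-log transformed before
# modelling (all FD columns are always logged).
log_cwm_traits <- function() c("SRL", "RNC", "LNC")

#' Relative abundance weights from biomass
#'
#' Species proportions in aboveground biomass, \eqn{p_i = Y_{Oi} / \sum Y_{Oi}}.
#'
#' @param biomass numeric vector of per-species biomass (>= 0).
#' @return weights summing to 1.
#' @export
abundance_weights <- function(biomass) {
  if (any(biomass < 0)) stop("biomass must be >= 0", call. = FALSE)
  tot <- sum(biomass)
  if (!(tot > 0)) stop("all-zero biomass: abundance weights undefined",
                       call. = FALSE)
  biomass / tot
}

#' Rao's quadratic entropy for a single trait
#'
#' \eqn{FD = \sum_i \sum_j p_i p_j d_{ij}} over all ordered species pairs,
#' where d is a pairwise trait distance.  The default distance is the
#' absolute trait difference on the raw scale; `distance = "gower"` divides
#' by the trait range within the community (range-scaled), which differs
#' from the default by a positive factor only.
#'
#' @param p relative abundance weights (summing to 1).
#' @param trait trait values, same length as `p`.
#' @param distance `"absolute"` (default) or `"gower"`, or a function
#'   `f(trait)` returning a symmetric distance matrix with zero diagonal.
#' @return FD >= 0; 0 for monocultures.
#' @export
rao_q <- function(p, trait, distance = c("absolute", "gower")) {
  if (length(p) != length(trait)) {
    stop("abundances and trait values differ in length", call. = FALSE)
  }
  d <- if (is.function(distance)) {
    distance(trait)
  } else {
    distance <- match.arg(distance)
    dm <- abs(outer(trait, trait, "-"))
    if (distance == "gower") {
      rng <- diff(range(trait))
      if (rng > 0) dm <- dm / rng
    }
    dm
  }
  sum(outer(p, p) * d)
}

#' Community-weighted mean trait value
#'
#' \eqn{CWM = \sum_i p_i t_i}, the abundance-weighted mean trait of the
#' community; bounded by the component species' trait range.
#'
#' @param p relative abundance weights; must sum to 1 (tolerance 1e-6).
#' @param trait trait values, same length as `p`.
#' @return CWM in the trait's units.
#' @export
cwm <- function(p, trait) {
  if (length(p) != length(trait)) {
    stop("abundances and trait values differ in length", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("abundance weights must sum to 1", call. = FALSE)
  }
  sum(p * trait)
}

# Look up trait values for a species set in one environment.
trait_values <- function(traits, species, environment, trait) {
  idx <- match(paste(species, environment, trait),
               paste(traits$species_id, traits$environment, traits$trait))
  if (anyNA(idx)) {
    stop("missing trait value(s) for ", trait, " in ", environment, ": ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  traits$value[idx]
}

#' Trait composition of every mixture
#'
#' Computes CWM and single-trait Rao's Q (FD) for each mixture plot and
#' each trait, with trait values matched to the plot's resource environment
#' and abundance weights taken from annual biomass proportions.
#'
#' @param table community biomass table.
#' @param design plot design.
#' @param traits trait table (`species_id`, `environment`, `trait`, `value`).
#' @param distance distance convention passed to [rao_q()].
#' @return data.frame, one row per mixture x trait: identifiers, `trait`,
#'   `cwm`, `fd`, `n_present` (species with biomass > 0).
#' @export
trait_composition <- function(table, design, traits,
                              distance = c("absolute", "gower")) {
  mix <- design[design$richness > 1L, ]
  tkey <- paste(traits$species_id, traits$environment, traits$trait)
  bio_key <- paste(table$plot_id, table$species_id)
  nt <- length(trait_names())
  keep <- cwm_v <- fd_v <- npres <- vector("list", nrow(mix))
  for (i in seq_len(nrow(mix))) {
    pl <- mix[i, ]
    sp <- composition_species(pl$composition)
    y <- table$biomass[match(paste(pl$plot_id, sp), bio_key)]
    y[is.na(y)] <- 0
    if (sum(y) <= 0) next
    p <- abundance_weights(y)
    cw <- fd <- numeric(nt)
    for (k in seq_len(nt)) {
      tr <- trait_names()[k]
      idx <- match(paste(sp, pl$environment, tr), tkey)
      if (anyNA(idx)) {
        stop("missing trait value(s) for ", tr, " in ", pl$environment,
             ": ", paste(sp[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      tv <- traits$value[idx]
      cw[k] <- cwm(p, tv)
      fd[k] <- rao_q(p, tv, distance)
    }
    keep[[i]] <- i
    cwm_v[[i]] <- cw
    fd_v[[i]] <- fd
    npres[[i]] <- sum(y > 0)
  }
  ki <- unlist(keep)
  res <- data.frame(
    plot_id = rep(mix$plot_id[ki], each = nt),
    composition = rep(mix$composition[ki], each = nt),
    environment = rep(mix$environment[ki], each = nt),
    richness = rep(mix$richness[ki], each = nt),
    block = rep(mix$block[ki], each = nt),
    trait = rep(trait_names(), length(ki)),
    cwm = unlist(cwm_v), fd = unlist(fd_v),
    n_present = rep(unlist(npres), each = nt),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assemble the transformed predictor matrix for trait-based inference
#'
#' Builds the mixture x 12 matrix of trait-composition predictors: CWM and
#' FD for each of the six traits.  All six FD columns and the CWM columns
#' for SRL, RNC and LNC are natural-log transformed.  Mixtures are excluded
#' (with a logged reason) when a sown species is missing from the biomass
#' (FD not computable as specified) or when a log transform would hit a
#' non-positive value.
#'
#' @param composition_result output of [trait_composition()].
#' @param design plot design (used to find dead-species plots).
#' @param table community biomass table (used to find dead-species plots).
#' @return data.frame keyed by `plot_id` with columns `CWM_<trait>` and
#'   `FD_<trait>` (post-transformation); excluded plots are recorded in
#'   `attr(, "exclusions")` as a data.frame (`plot_id`, `reason`).
#' @export
build_predictor_matrix <- function(composition_result, design, table) {
  mix <- design[design$richness > 1L, ]
  exclusions <- list()
  drop_plot <- function(pid, why) {
    exclusions[[length(exclusions) + 1L]] <<- data.frame(
      plot_id = pid, reason = why, stringsAsFactors = FALSE)
  }
  # dead-species plots: FD cannot be computed as specified
  for (i in seq_len(nrow(mix))) {
    pl <- mix[i, ]
    sp <- composition_species(pl$composition)
    rows <- table[table$plot_id == pl$plot_id, ]
    y <- rows$biomass[match(sp, rows$species_id)]
    y[is.na(y)] <- 0
    if (any(y == 0)) {
      drop_plot(pl$plot_id, "species missing from mixture (biomass 0)")
    }
  }
  dead <- vapply(exclusions, function(e) e$plot_id, "")
  cr <- composition_result[!composition_result$plot_id %in% dead, ]
  wide <- NULL
  for (tr in trait_names()) {
    sub <- cr[cr$trait == tr, c("plot_id", "cwm", "fd")]
    names(sub) <- c("plot_id", paste0("CWM_", tr), paste0("FD_", tr))
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "plot_id")
  }
  # log transforms; plots hitting log of a non-positive value are excluded
  log_cols <- c(paste0("FD_", trait_names()),
                paste0("CWM_", log_cwm_traits()))
  bad <- rep(FALSE, nrow(wide))
  for (cl in log_cols) bad <- bad | !(wide[[cl]] > 0)
  for (pid in wide$plot_id[bad]) {
    drop_plot(pid, "non-positive value in log-transformed predictor")
  }
  wide <- wide[!bad, ]
  for (cl in log_cols) wide[[cl]] <- log(wide[[cl]])
  rownames(wide) <- NULL
  structure(wide,
            exclusions = if (length(exclusions)) do.call(rbind, exclusions)
                         else data.frame(plot_id = character(),
                                         reason = character()))
}

#' Pairwise collinearity screen of predictors
#'
#' Pearson correlations between all predictor pairs, flagging |r| above a
#' threshold (the conventional cutoff below which collinearity is not
#' considered a modelling problem is 0.7).
#'
#' @param x predictor data.frame or matrix (numeric columns; a `plot_id`
#'   column is ignored).
#' @param threshold flag |r| above this value (default 0.7).
#' @return data.frame of pairs: `var1`, `var2`, `r`, `flagged`; constant
#'   columns produce NA correlations and are flagged.
#' @export
collinearity_screen <- function(x, threshold = 0.7) {
  x <- as.data.frame(x)
  x$plot_id <- NULL
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  cm <- suppressWarnings(cor(as.matrix(x)))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(
    var1 = colnames(cm)[pairs[, 1]],
    var2 = colnames(cm)[pairs[, 2]],
    r = cm[pairs],
    flagged = is.na(cm[pairs]) | abs(cm[pairs]) > threshold,
    stringsAsFactors = FALSE)
}
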