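# Experimental universe: species pools, plot design, and table validation.

#' Default species metadata for the two experimental pools
#'
#' Two independent pools of four perennial grassland species; each pool
#' crosses two functional groups (grass, forb) with two growth statures
#' (small, tall).  Species ids are synthetic labels of the form
#' `<fg><stature>.<pool>`, e.g. `gt.A` = tall grass of pool A.
#'
#' @return data.frame with columns `species_id`, `pool`, `functional_group`,
#'   `stature`.
#' @examples
#' default_species_pools()
#' @export
default_species_pools <- function() {
  grid <- expand.grid(functional_group = c("grass", "forb"),
                      stature = c("small", "tall"),
                      pool = c("A", "B"),
                      stringsAsFactors = FALSE)
  grid$species_id <- paste0(substr(grid$functional_group, 1, 1),
                            substr(grid$stature, 1, 1), ".", grid$pool)
  grid[, c("species_id", "pool", "functional_group", "stature")]
}

# Check pool metadata: each pool has exactly 4 species covering all
# functional-group x stature combinations.
validate_pools <- function(pools) {
  req <- c("species_id", "pool", "functional_group", "stature")
  missing <- setdiff(req, names(pools))
  if (length(missing)) {
    stop("species metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pools$species_id)) {
    stop("duplicated species_id in species metadata", call. = FALSE)
  }
  for (p in unique(pools$pool)) {
    sub <- pools[pools$pool == p, ]
    combos <- paste(sub$functional_group, sub$stature)
    need <- c("grass small", "grass tall", "forb small", "forb tall")
    if (nrow(sub) != 4L || !setequal(combos, need)) {
      stop("pool ", p, " must contain exactly 4 species covering all ",
           "functional-group x stature combinations", call. = FALSE)
    }
  }
  if (length(unique(pools$pool)) != 2L) {
    stop("expected exactly two species pools", call. = FALSE)
  }
  invisible(pools)
}

# Half-block templates.  Within one pool, a block of template group "X"
# holds monocultures of role-species 1 and 2 and the pairs {1,4},{2,3},{3,4};
# group "Y" holds monocultures 3,4 and the complementary pairs.  Together the
# two groups give every composition 4 replicates (four-species: 8) while each
# role-species occurs exactly 3 times per block half.
design_templates <- function() {
  list(
    X = list(mono = list(1L, 2L),
             pair = list(c(1L, 4L), c(2L, 3L), c(3L, 4L))),
    Y = list(mono = list(3L, 4L),
             pair = list(c(1L, 2L), c(1L, 3L), c(2L, 4L)))
  )
}

# Fertilization role patterns over the 4 blocks of one template group,
# ordered (shaded1, shaded2, unshaded1, unshaded2).  Entry TRUE = fertilized.
# Columns are block slots; rows are composition roles.  The two pools use
# complementary pattern sets so each block fertilizes exactly half of its
# plots within every richness level.
fert_patterns <- function(first_pool) {
  m1 <- c(TRUE, FALSE, TRUE, FALSE)   # F in slots 1 and 3
  m2 <- c(FALSE, TRUE, FALSE, TRUE)   # F in slots 2 and 4
  pa <- m1
  pb <- m2
  pc <- c(TRUE, FALSE, FALSE, TRUE)   # F in slots 1 and 4
  pd <- c(FALSE, TRUE, TRUE, FALSE)   # complement of pc
  if (first_pool) {
    list(mono = list(m1, m2), pair = list(pa, pb, pc), four = m1)
  } else {
    list(mono = list(m2, m1), pair = list(pb, pa, pd), four = m2)
  }
}

#' Build the 96-plot experimental design
#'
#' Constructs the full plot layout: 8 blocks of 12 plots (per block and pool:
#' 2 monocultures, 3 two-species mixtures, 1 four-species mixture), every
#' species composition replicated once per resource environment
#' (four-species mixtures twice), shading applied to 4 whole blocks and
#' fertilization to half the plots of every richness level within each
#' block.  Randomization (block layout, shade assignment, species roles,
#' fertilization roles) is driven entirely by `seed`.
#'
#' @param pools species metadata as returned by [default_species_pools()].
#' @param seed integer seed controlling all randomization.
#' @return data.frame of plot records: `plot_id`, `block`, `template_group`,
#'   `pool`, `richness`, `composition` ('+'-joined sorted species ids),
#'   `shade`, `fertilized`, `environment`.
#' @examples
#' d <- build_design(default_species_pools(), seed = 1)
#' table(d$richness)
#' @export
build_design <- function(pools = default_species_pools(), seed = 1L) {
  validate_pools(pools)
  with_seed(seed, {
    tg <- sample(rep(c("X", "Y"), each = 4L))          # template group / block
    blocks_x <- which(tg == "X")
    blocks_y <- which(tg == "Y")
    shaded <- c(sample(blocks_x, 2L), sample(blocks_y, 2L))
    # block slot order within each group: (shaded1, shaded2, unsh1, unsh2)
    slot_x <- c(sample(intersect(blocks_x, shaded)),
                sample(setdiff(blocks_x, shaded)))
    slot_y <- c(sample(intersect(blocks_y, shaded)),
                sample(setdiff(blocks_y, shaded)))
    tmpl <- design_templates()
    pool_ids <- sort(unique(pools$pool))
    first <- sample(pool_ids)                           # which pool gets set 1
    n_plots <- 96L
    acc <- list(block = integer(n_plots),
                template_group = character(n_plots),
                pool = character(n_plots), richness = integer(n_plots),
                composition = character(n_plots),
                shade = logical(n_plots), fertilized = logical(n_plots))
    pos <- 0L
    add <- function(block, tg, pool, richness, comp, sh, fert) {
      pos <<- pos + 1L
      acc$block[pos] <<- block
      acc$template_group[pos] <<- tg
      acc$pool[pos] <<- pool
      acc$richness[pos] <<- richness
      acc$composition[pos] <<- comp
      acc$shade[pos] <<- sh
      acc$fertilized[pos] <<- fert
    }
    for (p in pool_ids) {
      sp <- pools$species_id[pools$pool == p]
      roles <- sample(sp)                               # role 1..4 -> species
      fp <- fert_patterns(first_pool = identical(p, first[1L]))
      for (g in c("X", "Y")) {
        slots <- if (g == "X") slot_x else slot_y
        t <- tmpl[[g]]
        # randomize which composition takes which fertilization role
        mono_order <- sample(1:2)
        pair_order <- sample(1:3)
        for (s in seq_along(slots)) {
          b <- slots[s]
          sh <- s <= 2L
          for (k in 1:2) {
            add(b, g, p, 1L,
                composition_label(roles[t$mono[[mono_order[k]]]]),
                sh, fp$mono[[k]][s])
          }
          for (k in 1:3) {
            add(b, g, p, 2L,
                composition_label(roles[t$pair[[pair_order[k]]]]),
                sh, fp$pair[[k]][s])
          }
          add(b, g, p, 4L, composition_label(roles), sh, fp$four[s])
        }
      }
    }
    design <- as.data.frame(acc, stringsAsFactors = FALSE)
    design <- design[order(design$block, design$pool, design$richness,
                           design$composition), ]
    design$environment <- environment_code(design$shade, design$fertilized)
    design$plot_id <- sprintf("p%02d", seq_len(nrow(design)))
    rownames(design) <- NULL
    design[, c("plot_id", "block", "template_group", "pool", "richness",
               "composition", "shade", "fertilized", "environment")]
  })
}

#' Monoculture reference biomass for a species in an environment
#'
#' The expected biomass of a species in a mixture is derived from the
#' observed biomass of its monoculture grown in the same resource
#' environment.  With replicated monocultures (a generalization; the
#' reference design has exactly one per species x environment) the
#' arithmetic mean is returned.
#'
#' @param table community biomass table (`plot_id`, `species_id`, `biomass`).
#' @param design plot design as from [build_design()].
#' @param species_id species to look up.
#' @param environment environment code (e.g. `"F+S-"`) or
#'   `list(shade=, fertilized=)`.
#' @return monoculture biomass in g m^-2; zero-valued references trigger a
#'   warning because downstream relative yields are undefined.
#' @export
monoculture_reference <- function(table, design, species_id, environment) {
  env <- as_environment(environment)
  mono <- design[design$richness == 1L &
                   design$composition == species_id &
                   design$shade == env$shade &
                   design$fertilized == env$fertilized, ]
  if (nrow(mono) == 0L) {
    stop("no monoculture of '", species_id, "' in environment ",
         environment_code(env$shade, env$fertilized), call. = FALSE)
  }
  rows <- table[table$plot_id %in% mono$plot_id &
                  table$species_id == species_id, ]
  if (nrow(rows) == 0L) {
    stop("no biomass record for monoculture of '", species_id,
         "' in environment ", environment_code(env$shade, env$fertilized),
         call. = FALSE)
  }
  bm <- mean(rows$biomass)
  if (bm == 0) {
    warning("monoculture reference for '", species_id, "' in ",
            environment_code(env$shade, env$fertilized),
            " is zero; relative yields are undefined", call. = FALSE)
  }
  bm
}

#' Validate a community biomass table against a design
#'
#' Checks referential integrity and value sanity.  Hard violations (unknown
#' plots or species, negative biomass, duplicated plot x species rows, rows
#' for species not sown in the plot) stop the pipeline; missing rows for
#' sown species are warnings (a species that died out should be recorded
#' with biomass 0).
#'
#' @param table community biomass table (`plot_id`, `species_id`, `biomass`).
#' @param design plot design as from [build_design()].
#' @return data.frame report with columns `severity` ("hard"/"warning"),
#'   `plot_id`, `species_id`, `problem`; zero rows if fully consistent.
#' @export
validate_table <- function(table, design) {
  req <- c("plot_id", "species_id", "biomass")
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop("biomass table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sp_per_plot <- strsplit(design$composition, "+", fixed = TRUE)
  sown_keys <- paste(rep(design$plot_id, lengths(sp_per_plot)),
                     unlist(sp_per_plot))
  key <- paste(table$plot_id, table$species_id)
  unknown_plot <- !table$plot_id %in% design$plot_id
  not_sown <- !unknown_plot & !key %in% sown_keys
  bad_bm <- !is.finite(table$biomass) | table$biomass < 0
  dup <- duplicated(key)
  missing_key <- setdiff(sown_keys, key)
  mk <- if (length(missing_key)) {
    parts <- strsplit(missing_key, " ", fixed = TRUE)
    data.frame(severity = "warning",
               plot_id = vapply(parts, `[`, "", 1L),
               species_id = vapply(parts, `[`, "", 2L),
               problem = "missing row for sown species",
               stringsAsFactors = FALSE)
  }
  issue <- function(idx, problem) {
    if (!any(idx)) return(NULL)
    data.frame(severity = "hard", plot_id = table$plot_id[idx],
               species_id = table$species_id[idx], problem = problem,
               stringsAsFactors = FALSE)
  }
  out <- rbind(issue(unknown_plot, "unknown plot"),
               issue(not_sown, "species not sown in plot"),
               issue(bad_bm, "negative or non-finite biomass"),
               issue(dup, "duplicated row"),
               mk)
  if (is.null(out)) {
    out <- data.frame(severity = character(), plot_id = character(),
                      species_id = character(), problem = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Functional-group / growth-stature composition of a plot's species set:
# "pure grass" / "pure forb" / "grass-forb", and "pure small" / "pure tall" /
# "small-tall".
composition_classes <- function(composition, pools) {
  sp <- composition_species(composition)
  idx <- match(sp, pools$species_id)
  fg <- unique(pools$functional_group[idx])
  gs <- unique(pools$stature[idx])
  c(fg = if (length(fg) > 1L) "grass-forb" else paste("pure", fg),
    gs = if (length(gs) > 1L) "small-tall" else paste("pure", gs))
}

#' Annotate a design with functional composition classes
#'
#' Adds the community-level classification used as fixed effects in the
#' sequential ANOVA: `fg_composition` (pure grass / pure forb / grass-forb)
#' and `gs_composition` (pure small / pure tall / small-tall).
#'
#' @param design plot design.
#' @param pools species metadata.
#' @return design with two added columns.
#' @export
annotate_composition <- function(design, pools = default_species_pools()) {
  comps <- unique(design$composition)
  cls <- vapply(comps, composition_classes, c(fg = "", gs = ""),
                pools = pools)
  i <- match(design$composition, comps)
  design$fg_composition <- unname(cls["fg", i])
  design$gs_composition <- unname(cls["gs", i])
  design
}
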