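# Sequential mixed-model ANOVA, one-sample tests, post-hoc LS-mean
# differences.

#' Default sequential fixed-effect order
#'
#' The entry order used for sequential (type I) decomposition at the
#' community level: shade, fertilization, log species richness, functional
#' group composition, growth stature composition, then all two- and
#' three-way interactions of the treatments with the composition terms.
#' At the species level the composition terms are replaced by functional
#' group identity and growth stature identity.
#'
#' @param level `"community"` or `"species"`.
#' @param composition_terms include richness/composition terms (set FALSE
#'   for responses defined on mixtures of one richness level).
#' @return ordered character vector of term labels.
#' @export
default_fixed_terms <- function(level = c("community", "species"),
                                composition_terms = TRUE) {
  level <- match.arg(level)
  comp <- if (level == "community") c("fg_composition", "gs_composition")
          else c("fg_id", "gs_id")
  main <- c("shade", "fertilized", if (composition_terms) "log_sr", comp)
  two <- c("shade:fertilized",
           if (composition_terms) c("shade:log_sr", "fertilized:log_sr"),
           paste0("shade:", comp), paste0("fertilized:", comp))
  three <- c(if (composition_terms) "shade:fertilized:log_sr",
             paste0("shade:fertilized:", comp))
  c(main, two, three)
}

# Random-intercept grouping terms used in the reference analyses.
default_random_terms <- function(level = c("community", "species")) {
  level <- match.arg(level)
  if (level == "community") c("block", "composition")
  else c("block", "plot_id", "composition", "species_id")
}

#' Sequential (type I) mixed-model ANOVA
#'
#' Fits a linear mixed model with the fixed effects entered in the given
#' order and independent random intercepts for the grouping terms, and
#' tests each fixed term given all earlier terms (type I sums of squares).
#' Denominator degrees of freedom come from the Satterthwaite (default) or
#' Kenward-Roger approximation; `method = "permutation"` instead computes
#' design-based p-values by re-randomizing the treatment assignment under
#' the experiment's randomization scheme (see
#' [rerandomization_anova()]), which is exact under the global null of no
#' treatment effect but only yields p-values for terms involving the
#' randomized factors (shade, fertilization).
#'
#' @param data data.frame with the response, fixed-effect columns, and
#'   grouping columns (for the permutation method also `template_group`,
#'   `pool`, `richness`).
#' @param response response column name.
#' @param fixed ordered character vector of fixed-effect term labels.
#' @param random character vector of random-intercept grouping columns.
#' @param method `"satterthwaite"`, `"kenward-roger"` or `"permutation"`.
#' @param nperm number of re-randomizations for the permutation method.
#' @return object of class `befpart_anova`: data.frame with one row per
#'   fixed term (`term`, `df`, `den_df`, `ss`, `ms`, `F`, `p`,
#'   `direction`), with the method recorded in `attr(, "method")` and the
#'   fitted model (lmer methods) in `attr(, "model")`.
#' @export
fit_sequential_anova <- function(data, response,
                                 fixed = default_fixed_terms("community"),
                                 random = default_random_terms("community"),
                                 method = c("satterthwaite", "kenward-roger",
                                            "permutation"),
                                 nperm = 199L) {
  method <- match.arg(method)
  data <- droplevels(as.data.frame(data))
  data <- data[complete.cases(data[, unique(c(response,
           unlist(strsplit(fixed, ":", fixed = TRUE)), random)),
           drop = FALSE]), ]
  for (r in random) data[[r]] <- factor(data[[r]])
  if (method == "permutation") {
    return(rerandomization_anova(data, response, fixed, nperm = nperm))
  }
  ddf <- if (method == "kenward-roger") "Kenward-Roger" else "Satterthwaite"
  if (method == "kenward-roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    stop("Kenward-Roger requires the pbkrtest package", call. = FALSE)
  }
  f <- as.formula(paste(response, "~", paste(fixed, collapse = " + "), "+",
                        paste(sprintf("(1|%s)", random), collapse = " + ")))
  m <- lmerTest::lmer(f, data = data, REML = TRUE)
  at <- as.data.frame(anova(m, type = 1, ddf = ddf))
  out <- data.frame(term = fixed, df = NA_real_, den_df = NA_real_,
                    ss = NA_real_, ms = NA_real_, F = NA_real_, p = NA_real_,
                    direction = NA_real_, stringsAsFactors = FALSE)
  idx <- match(normalize_terms(out$term), normalize_terms(rownames(at)))
  hit <- !is.na(idx)
  out$df[hit] <- at$NumDF[idx[hit]]
  out$den_df[hit] <- at$DenDF[idx[hit]]
  out$ss[hit] <- at$`Sum Sq`[idx[hit]]
  out$ms[hit] <- at$`Mean Sq`[idx[hit]]
  out$F[hit] <- at$`F value`[idx[hit]]
  out$p[hit] <- at$`Pr(>F)`[idx[hit]]
  out$direction <- term_directions(m, fixed, data)
  structure(out, method = method, model = m, class = c("befpart_anova",
                                                       "data.frame"))
}

# Term labels modulo interaction-order differences.
normalize_terms <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), "")
}

# Sign of the effect for single-df main terms (2-level factors, logicals,
# numeric covariates); NA otherwise.
term_directions <- function(model, fixed, data) {
  fe <- lme4::fixef(model)
  vapply(fixed, function(tm) {
    if (grepl(":", tm)) return(NA_real_)
    v <- data[[tm]]
    if (is.numeric(v)) {
      cf <- fe[names(fe) == tm]
      if (length(cf) == 1L) return(sign(unname(cf)))
    } else {
      lv <- levels(factor(v))
      if (length(lv) == 2L) {
        cf <- fe[names(fe) == paste0(tm, lv[2L])]
        if (length(cf) == 1L) return(sign(unname(cf)))
      }
    }
    NA_real_
  }, numeric(1))
}

#' @export
print.befpart_anova <- function(x, ...) {
  cat("Sequential (type I) ANOVA, method:", attr(x, "method"), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

# ---- design-based re-randomization inference --------------------------

# Sequential sums of squares for an ordered list of term model matrices.
# Returns per-term SS, df (independent columns only) and residual SS/df.
# base qr() pivots only near-singular columns; those land at the end and
# are excluded via rank, so independent columns keep their entry order and
# the attribution of Q'y coordinates to terms remains sequential.
sequential_ss <- function(y, mats) {
  n <- length(y)
  X <- do.call(cbind, mats)
  q <- qr(X)
  keep <- q$pivot[seq_len(q$rank)]
  qty <- qr.qty(q, y)[seq_len(q$rank)]
  sizes <- vapply(mats, ncol, 0L)
  term_of <- rep(seq_along(mats), sizes)
  ss <- numeric(length(mats))
  df <- integer(length(mats))
  for (k in seq_len(q$rank)) {
    tm <- term_of[keep[k]]
    ss[tm] <- ss[tm] + qty[k]^2
    df[tm] <- df[tm] + 1L
  }
  rss <- sum(y^2) - sum(qty^2)
  list(ss = ss, df = df, rss = rss, rdf = n - q$rank)
}

# Dummy/covariate columns for one variable (no intercept column).
variable_columns <- function(v) {
  if (is.numeric(v)) {
    matrix(v, ncol = 1)
  } else if (is.logical(v)) {
    matrix(as.numeric(v), ncol = 1)
  } else {
    f <- factor(v)
    stats::model.matrix(~ f)[, -1, drop = FALSE]
  }
}

# Column-wise interaction (all products of columns).
columns_product <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a) * ncol(b))
  k <- 0L
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      k <- k + 1L
      out[, k] <- a[, i] * b[, j]
    }
  }
  out
}

# Re-draw the treatment assignment (shade per block, fertilization per
# plot) under the design's randomization scheme, conditional on the
# composition layout: re-sample the shaded pair and slot order within each
# template group, which pool takes which fertilization pattern set, and
# the random assignment of patterns to compositions within pool x group.
# Returns per-unit shade/fertilized for the `units` plot table.
redraw_treatments <- function(units) {
  plan <- make_redraw_plan(units)
  redraw_from_plan(plan)
}

# Precompute the index structure for fast repeated re-randomization.
make_redraw_plan <- function(units) {
  units$composition <- as.character(units$composition)
  units$block <- as.character(units$block)
  units$pool <- as.character(units$pool)
  gl <- sort(unique(units$template_group))
  row_group <- match(units$template_group, gl)
  blocks_by_group <- lapply(gl, function(g) {
    bg <- unique(units$block[units$template_group == g])
    if (length(bg) != 4L) {
      stop("re-randomization requires 4 blocks per template group",
           call. = FALSE)
    }
    sort(bg)
  })
  row_block_pos <- integer(nrow(units))
  for (gi in seq_along(gl)) {
    i <- row_group == gi
    row_block_pos[i] <- match(units$block[i], blocks_by_group[[gi]])
  }
  pool_ids <- sort(unique(units$pool))
  # per richness level: 4-slot x n-roles fertilization pattern matrices
  # for the pool holding the first and the second pattern set
  patmats <- lapply(c(TRUE, FALSE), function(first) {
    fp <- fert_patterns(first)
    list(`1` = do.call(cbind, fp$mono),
         `2` = do.call(cbind, fp$pair),
         `4` = matrix(fp$four, ncol = 1))
  })
  cells <- list()
  for (pi in seq_along(pool_ids)) {
    for (gi in seq_along(gl)) {
      for (r in intersect(c(1L, 2L, 4L), units$richness)) {
        rows <- which(units$pool == pool_ids[pi] & row_group == gi &
                        units$richness == r)
        if (!length(rows)) next
        cc <- unique(units$composition[rows])
        npat <- c(`1` = 2L, `2` = 3L, `4` = 1L)[[as.character(r)]]
        if (length(cc) > npat) {
          stop("composition layout incompatible with the template design",
               call. = FALSE)
        }
        cells[[length(cells) + 1L]] <- list(
          rows = rows, pool_idx = pi, rich = as.character(r),
          code = match(units$composition[rows], cc), npat = npat)
      }
    }
  }
  list(n = nrow(units), n_groups = length(gl), row_group = row_group,
       row_block_pos = row_block_pos, blocks_by_group = blocks_by_group,
       pool_ids = pool_ids, patmats = patmats, cells = cells)
}

redraw_from_plan <- function(plan) {
  slot_pos <- vector("list", plan$n_groups)
  for (gi in seq_len(plan$n_groups)) {
    shpair <- sample.int(4L, 2L)
    ord <- c(shpair[sample.int(2L)],
             setdiff(1:4, shpair)[sample.int(2L)])
    sp <- integer(4L)
    sp[ord] <- 1:4
    slot_pos[[gi]] <- sp
  }
  rowslot <- integer(plan$n)
  for (gi in seq_len(plan$n_groups)) {
    i <- plan$row_group == gi
    rowslot[i] <- slot_pos[[gi]][plan$row_block_pos[i]]
  }
  first_idx <- sample.int(length(plan$pool_ids), 1L)
  fert <- logical(plan$n)
  for (cell in plan$cells) {
    pats <- plan$patmats[[if (cell$pool_idx == first_idx) 1L else 2L]][[
      cell$rich]]
    k <- if (cell$npat > 1L) sample.int(cell$npat) else 1L
    fert[cell$rows] <- pats[cbind(rowslot[cell$rows], k[cell$code])]
  }
  shaded <- unlist(lapply(seq_len(plan$n_groups), function(gi) {
    plan$blocks_by_group[[gi]][slot_pos[[gi]] <= 2L]
  }))
  list(shade = rowslot <= 2L, fertilized = fert, shaded_blocks = shaded)
}

#' Re-randomization ANOVA for treatment terms
#'
#' Design-based p-values for the sequential F statistics of terms that
#' involve the randomized treatment factors.  The treatment assignment
#' (shading of whole blocks, fertilization of plots) is re-drawn `nperm`
#' times under the experiment's own randomization scheme, conditional on
#' the composition layout (see the constructive template design of
#' [build_design()]).  Because the re-draws follow the same conditional
#' distribution that generated the actual assignment, the test is exact
#' under the global null of no treatment effect.  Terms not involving a
#' randomized factor (richness, composition) receive NA p-values under
#' this method.
#'
#' Between-block terms (shading) are tested on block means adjusted for
#' template group; within-block terms via sequential OLS sums of squares
#' after absorbing block.
#'
#' @param data data.frame with response, fixed-term columns, and
#'   `plot_id`, `block`, `template_group`, `pool`, `richness`,
#'   `composition`, `shade`, `fertilized`.
#' @param response response column name.
#' @param fixed ordered term labels (products of column names joined by
#'   `:`).
#' @param nperm number of re-randomizations.
#' @return `befpart_anova` data.frame (see [fit_sequential_anova()]).
#' @export
rerandomization_anova <- function(data, response,
                                  fixed = default_fixed_terms("community"),
                                  nperm = 199L) {
  need <- c("plot_id", "block", "template_group", "pool", "richness",
            "composition", "shade", "fertilized")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("re-randomization needs design columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  block <- factor(data$block)
  block_mat <- stats::model.matrix(~ block)
  comps <- strsplit(fixed, ":", fixed = TRUE)
  vars <- unique(unlist(comps))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("fixed terms reference missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  treat_terms <- vapply(comps, function(cc) {
    any(cc %in% c("shade", "fertilized"))
  }, logical(1))
  base_cols <- lapply(setNames(vars, vars),
                      function(v) variable_columns(data[[v]]))
  # a term is between-block iff all its components are block-constant
  var_between <- vapply(vars, function(v) {
    m <- base_cols[[v]]
    all(vapply(split(seq_len(nrow(m)), block), function(i) {
      all(abs(sweep(m[i, , drop = FALSE], 2, m[i[1L], ], "-")) < 1e-10)
    }, logical(1)))
  }, logical(1))
  term_between <- vapply(comps, function(cc) all(var_between[cc]),
                         logical(1))

  units <- unique(data[, c("plot_id", "block", "template_group", "pool",
                           "richness", "composition")])
  row_of_unit <- match(data$plot_id, units$plot_id)
  binfo <- unique(data.frame(block = data$block, tg = data$template_group))
  binfo <- binfo[order(binfo$block), ]
  bm <- as.numeric(tapply(y, block, mean))
  # block means centered within template group, for the between-block test
  tg_of_block <- binfo$tg
  bm_c <- bm - ave(bm, tg_of_block)
  n_groups <- length(unique(tg_of_block))

  tg_idx <- match(tg_of_block, unique(tg_of_block))
  tg_size <- tabulate(tg_idx)
  between_F <- function(shaded_blocks) {
    sh <- as.numeric(as.character(binfo$block) %in%
                       as.character(shaded_blocks))
    sh_c <- sh - (tapply(sh, tg_idx, sum) / tg_size)[tg_idx]
    ssx <- sum(sh_c^2)
    if (ssx < 1e-12) return(NA_real_)
    ss <- sum(sh_c * bm_c)^2 / ssx
    rss <- sum(bm_c^2) - ss
    rdf <- length(bm) - n_groups - 1L
    (ss / 1) / (rss / rdf)
  }

  stats_for <- function(cols, shaded_blocks) {
    mats <- c(list(block_mat), lapply(comps, function(cc) {
      Reduce(columns_product, cols[cc])
    }))
    sq <- sequential_ss(y, mats)
    f <- (sq$ss[-1] / pmax(sq$df[-1], 1)) / (sq$rss / sq$rdf)
    if (any(term_between)) f[term_between] <- between_F(shaded_blocks)
    list(f = f, df = sq$df[-1], ss = sq$ss[-1], rss = sq$rss, rdf = sq$rdf)
  }

  obs_shaded <- binfo$block[as.logical(tapply(data$shade, block, any))]
  obs <- stats_for(base_cols, obs_shaded)
  greater <- ties <- numeric(length(fixed))
  tol <- 1e-9 * pmax(1, abs(obs$f))
  plan <- make_redraw_plan(units)
  for (r in seq_len(nperm)) {
    cols <- base_cols
    rl <- redraw_from_plan(plan)
    if ("shade" %in% vars) {
      cols[["shade"]] <- matrix(as.numeric(rl$shade[row_of_unit]),
                                ncol = 1)
    }
    if ("fertilized" %in% vars) {
      cols[["fertilized"]] <-
        matrix(as.numeric(rl$fertilized[row_of_unit]), ncol = 1)
    }
    st <- stats_for(cols, rl$shaded_blocks)
    greater <- greater + (st$f > obs$f + tol)
    ties <- ties + (abs(st$f - obs$f) <= tol)
  }
  # randomized tie-break: the block-level randomization distribution is
  # discrete (few distinct shade assignments), so ties are resolved
  # uniformly at random, making the p-value exactly uniform under the
  # null (a fuzzy/randomized permutation p-value)
  p <- (greater + runif(length(fixed)) * (ties + 1)) / (nperm + 1)
  p[!treat_terms] <- NA_real_
  # between-block terms are absorbed by block in the within stage; report
  # their nominal df from the term's column count
  obs$df[term_between] <- vapply(comps[term_between], function(cc) {
    prod(vapply(cc, function(v) ncol(base_cols[[v]]), 0L))
  }, 0)
  out <- data.frame(term = fixed, df = obs$df,
                    den_df = ifelse(term_between, NA_real_, obs$rdf),
                    ss = ifelse(term_between, NA_real_, obs$ss),
                    ms = ifelse(term_between, NA_real_,
                                obs$ss / pmax(obs$df, 1)),
                    F = obs$f, p = p, direction = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, method = "permutation", nperm = nperm,
            class = c("befpart_anova", "data.frame"))
}

# ---- species-level data, one-sample tests, post-hoc -------------------

#' Species-level response table
#'
#' Expands a biomass table to one row per plot x sown species with the
#' responses used in species-level analyses: relative yield and biomass
#' both multiplied by the sown species number S (correcting for decreasing
#' sown proportions at increasing richness), plus functional-group and
#' growth-stature identity covariates.
#'
#' @param table community biomass table.
#' @param design plot design.
#' @param pools species metadata.
#' @return data.frame with identifiers, `fg_id`, `gs_id`, `log_sr`,
#'   `biomass`, `ry`, `ry_s` (RY x S), `biomass_s` (biomass x S); `ry` is NA
#'   where the monoculture reference is zero.
#' @export
species_level_prepare <- function(table, design,
                                  pools = default_species_pools()) {
  out <- list()
  for (i in seq_len(nrow(design))) {
    pl <- design[i, ]
    sp <- composition_species(pl$composition)
    rows <- table[table$plot_id == pl$plot_id, ]
    y <- rows$biomass[match(sp, rows$species_id)]
    y[is.na(y)] <- 0
    bm <- vapply(sp, function(s) {
      suppressWarnings(monoculture_reference(table, design, s,
                                             pl$environment))
    }, numeric(1))
    idx <- match(sp, pools$species_id)
    ry <- ifelse(bm > 0, y / bm, NA_real_)
    out[[i]] <- data.frame(
      plot_id = pl$plot_id, block = pl$block, pool = pl$pool,
      composition = pl$composition, richness = pl$richness,
      environment = pl$environment, shade = pl$shade,
      fertilized = pl$fertilized,
      template_group = pl$template_group,
      species_id = sp, fg_id = pools$functional_group[idx],
      gs_id = pools$stature[idx], log_sr = log(pl$richness),
      biomass = y, ry = ry, ry_s = ry * pl$richness,
      biomass_s = y * pl$richness, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sample test of a mean against a reference value
#'
#' Two-sided one-sample t-test of `mean(values) != reference`, as used for
#' RYT != 1, D_max != 0 and diversity effects != 0.  Optionally aggregates
#' to block means first (a block-aware variant).
#'
#' @param values numeric vector.
#' @param reference reference value (e.g. 1 for RYT, 0 for D_max).
#' @param block optional block ids; if given, values are averaged per block
#'   before testing.
#' @return list with `estimate` (mean), `sd`, `n`, `t`, `df`, `p`, and
#'   `note` (non-NA when the variance is zero and p is undefined).
#' @export
test_mean_against <- function(values, reference, block = NULL) {
  values <- values[is.finite(values)]
  if (!is.null(block)) {
    values <- as.numeric(tapply(values, block[seq_along(values)], mean))
  }
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    if (m == reference) {
      return(list(estimate = m, sd = 0, n = n, t = 0, df = n - 1, p = 1,
                  note = "zero variance"))
    }
    return(list(estimate = m, sd = 0, n = n, t = sign(m - reference) * Inf,
                df = n - 1, p = NA_real_, note = "zero variance"))
  }
  tt <- t.test(values, mu = reference)
  list(estimate = m, sd = s, n = n, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, note = NA_character_)
}

#' Pairwise least-squares-mean differences for a factor
#'
#' All pairwise differences between the least-squares (marginal) means of a
#' factor in a fitted (mixed) model, with unadjusted p-values, matching the
#' `difflsmeans`-style post-hoc procedure.
#'
#' @param model a fitted model (e.g. from [fit_sequential_anova()],
#'   `attr(x, "model")`, or any model supported by emmeans).
#' @param factor_name name of the factor.
#' @param adjust p-value adjustment (default `"none"`).
#' @return data.frame of contrasts: `contrast`, `estimate`, `se`, `df`,
#'   `t`, `p`.
#' @export
posthoc_lsmeans_diff <- function(model, factor_name, adjust = "none") {
  em <- if (inherits(model, "merMod")) {
    emmeans::emmeans(model, specs = factor_name, lmer.df = "satterthwaite")
  } else {
    emmeans::emmeans(model, specs = factor_name)
  }
  pr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                              adjust = adjust, infer = c(FALSE, TRUE)))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, se = pr$SE,
             df = pr$df, t = pr$t.ratio, p = pr$p.value,
             stringsAsFactors = FALSE)
}
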