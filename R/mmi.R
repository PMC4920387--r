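# All-subsets AIC multimodel inference with a block random intercept,
# and full (zero-substitution) model averaging.

# Maximum-likelihood fit of y = X beta + (1|block) + e by profiling the
# variance ratio lambda = var(block) / var(resid).  The marginal covariance
# is block-diagonal compound symmetry, so whitening is closed-form:
# (I + lambda J_m)^(-1/2) = I - c J_m with c = (1 - 1/sqrt(1 + m lambda))/m.
# Equivalent to lmer(..., REML = FALSE); used because all-subsets screening
# fits hundreds of candidates.
fit_block_ml <- function(y, X, g, m_sizes, Sy, SX) {
  n <- length(y)
  p <- ncol(X)
  # whitening is closed-form per block: v - c_b * blocksum(v), with
  # c_b = (1 - 1/sqrt(1 + m_b * lambda)) / m_b; block sums precomputed
  dev_at <- function(lam) {
    cc <- (1 - 1 / sqrt(1 + m_sizes * lam)) / m_sizes
    yt <- y - cc[g] * Sy[g]
    Xt <- X - cc[g] * SX[g, , drop = FALSE]
    rss <- sum(.lm.fit(Xt, yt)$residuals^2)
    n * log(2 * pi * rss / n) + n + sum(log(1 + m_sizes * lam))
  }
  opt <- optimize(function(ll) dev_at(exp(ll)), interval = c(-15, 10))
  lam <- exp(opt$minimum)
  dev <- opt$objective
  dev0 <- dev_at(0)
  if (dev0 <= dev) {
    lam <- 0
    dev <- dev0
  }
  cc <- (1 - 1 / sqrt(1 + m_sizes * lam)) / m_sizes
  yt <- y - cc[g] * Sy[g]
  Xt <- X - cc[g] * SX[g, , drop = FALSE]
  q <- qr(Xt)
  beta <- qr.coef(q, yt)
  rss <- sum(qr.resid(q, yt)^2)
  sigma2 <- rss / n
  xtxi <- chol2inv(qr.R(q)[seq_len(q$rank), seq_len(q$rank), drop = FALSE])
  se <- sqrt(sigma2 * diag(xtxi))
  k <- p + 2  # fixed effects + block variance + residual variance
  list(beta = beta, se = se, logLik = -dev / 2, aic = dev + 2 * k,
       aicc = dev + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1),
       lambda = lam, sigma2 = sigma2, k = k)
}

# lme4 route for the same model; used for validation and as an alternative
# engine.
fit_block_lmer <- function(y, X, block) {
  d <- as.data.frame(X[, -1, drop = FALSE])
  d$..y <- y
  d$..block <- block
  rhs <- if (ncol(X) > 1L) paste(colnames(X)[-1], collapse = " + ") else "1"
  f <- as.formula(paste("..y ~", rhs, "+ (1|..block)"))
  m <- lme4::lmer(f, data = d, REML = FALSE,
                  control = lme4::lmerControl(check.conv.singular = "ignore",
                                              calc.derivs = FALSE))
  fe <- lme4::fixef(m)
  list(beta = fe, se = sqrt(diag(as.matrix(vcov(m)))),
       logLik = as.numeric(logLik(m)), aic = AIC(m),
       aicc = AIC(m) + 2 * (length(fe) + 2) * (length(fe) + 3) /
         max(length(y) - length(fe) - 3, 1),
       lambda = NA_real_, sigma2 = stats::sigma(m)^2, k = length(fe) + 2)
}

#' All-subsets AIC model screening with a block random intercept
#'
#' Fits every candidate model with up to `max_terms` predictors (all
#' subsets of sizes 0..`max_terms`) plus a random intercept for block, by
#' maximum likelihood (so AIC is comparable across fixed structures), and
#' ranks them by AIC with Akaike weights
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum \exp(-\Delta/2)}.  Predictors are
#' z-scored before fitting so estimates are comparable across predictors
#' (standardized estimates).
#'
#' @param response numeric response vector.
#' @param predictors data.frame/matrix of candidate predictors (numeric; a
#'   `plot_id` column is ignored).
#' @param block block ids (random intercept grouping).
#' @param max_terms maximum number of predictors per model (default 3).
#' @param use_aicc rank by AICc instead of AIC.
#' @param engine `"fast"` (internal profiled-ML fitter) or `"lmer"`.
#' @param standardize z-score predictors first (default TRUE).
#' @return object of class `befpart_mmi`: list with `models` (data.frame:
#'   `model_id`, `terms`, `k`, `logLik`, `aic`, `delta`, `weight`, ranked
#'   by AIC), `coefs` (per-model named coefficient vectors), `ses`,
#'   `predictors` (names), `n`.
#' @export
all_subsets_mmi <- function(response, predictors, block, max_terms = 3L,
                            use_aicc = FALSE,
                            engine = c("fast", "lmer"),
                            standardize = TRUE) {
  engine <- match.arg(engine)
  predictors <- as.data.frame(predictors)
  predictors$plot_id <- NULL
  X <- as.matrix(predictors)
  storage.mode(X) <- "double"
  if (standardize) X <- scale(X)
  y <- as.numeric(response)
  n <- length(y)
  stopifnot(nrow(X) == n, length(block) == n)
  block <- factor(block)
  g <- as.integer(block)
  m_sizes <- as.numeric(tabulate(g))
  Xfull <- cbind(`(Intercept)` = 1, X)
  SXfull <- rowsum(Xfull, g)
  Sy <- as.numeric(rowsum(y, g))
  pn <- colnames(X)
  subsets <- list(integer(0))
  for (s in seq_len(min(max_terms, ncol(X)))) {
    subsets <- c(subsets, combn(ncol(X), s, simplify = FALSE))
  }
  fits <- vector("list", length(subsets))
  ok <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    cols <- c(1L, subsets[[i]] + 1L)
    Xi <- Xfull[, cols, drop = FALSE]
    fit <- tryCatch({
      if (engine == "fast") {
        fit_block_ml(y, Xi, g, m_sizes, Sy,
                     SXfull[, cols, drop = FALSE])
      } else {
        fit_block_lmer(y, Xi, block)
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !all(is.finite(c(fit$aic, fit$beta)))) {
      ok[i] <- FALSE
    } else {
      ok[i] <- TRUE
      names(fit$beta) <- names(fit$se) <-
        c("(Intercept)", pn[subsets[[i]]])
      fits[[i]] <- fit
    }
  }
  if (!all(ok)) {
    warning(sum(!ok), " non-convergent candidate model(s) dropped; ",
            "weights renormalized over the remainder", call. = FALSE)
  }
  subsets <- subsets[ok]
  fits <- fits[ok]
  ic <- vapply(fits, function(f) if (use_aicc) f$aicc else f$aic, 0)
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  models <- data.frame(
    model_id = seq_along(fits),
    terms = vapply(subsets, function(s) {
      if (length(s)) paste(pn[s], collapse = "+") else "(null)"
    }, ""),
    k = vapply(fits, function(f) f$k, 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    aic = ic, delta = delta, weight = w, stringsAsFactors = FALSE)
  ord <- order(models$aic)
  structure(list(models = models[ord, ],
                 coefs = lapply(fits, function(f) f$beta)[ord],
                 ses = lapply(fits, function(f) f$se)[ord],
                 predictors = pn, n = n,
                 criterion = if (use_aicc) "AICc" else "AIC"),
            class = "befpart_mmi")
}

#' @export
print.befpart_mmi <- function(x, ...) {
  cat("All-subsets multimodel screening (", x$criterion, ", ",
      nrow(x$models), " candidate models, n = ", x$n, ")\n", sep = "")
  print(head(x$models, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Akaike weights from information-criterion differences
#'
#' \eqn{w_m = \exp(-\Delta_m / 2) / \sum_j \exp(-\Delta_j / 2)}.
#'
#' @param delta vector of IC differences from the best model.
#' @return normalized weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Full model averaging over a Delta-window
#'
#' Averages coefficients over all models with `delta < delta_max`
#' (weights renormalized within that set) using full (zero-substitution)
#' averaging: a predictor absent from a model contributes an estimate of 0.
#' The unconditional standard error follows the model-averaging variance
#' formula \eqn{SE = \sum_m w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2}},
#' and the relative importance of a predictor is the sum of the
#' renormalized weights of the models containing it.
#'
#' @param mmi result of [all_subsets_mmi()].
#' @param delta_max retain models with delta below this value (default 4).
#' @param conf confidence level for the interval (default 0.95).
#' @return data.frame per predictor: `predictor`, `estimate`, `se`,
#'   `lower`, `upper`, `importance`.
#' @export
model_average <- function(mmi, delta_max = 4, conf = 0.95) {
  keep <- which(mmi$models$delta < delta_max)
  if (!length(keep)) stop("no model with delta < delta_max", call. = FALSE)
  w <- mmi$models$weight[keep]
  w <- w / sum(w)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(mmi$predictors, function(pv) {
    beta <- vapply(mmi$coefs[keep], function(cf) {
      if (pv %in% names(cf)) unname(cf[pv]) else 0
    }, 0)
    se_m <- vapply(seq_along(keep), function(j) {
      cf <- mmi$ses[[keep[j]]]
      if (pv %in% names(cf)) unname(cf[pv]) else 0
    }, 0)
    contains <- vapply(mmi$coefs[keep], function(cf) pv %in% names(cf),
                       logical(1))
    est <- sum(w * beta)
    se <- sum(w * sqrt(se_m^2 + (beta - est)^2))
    data.frame(predictor = pv, estimate = est, se = se,
               lower = est - z * se, upper = est + z * se,
               importance = sum(w[contains]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
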