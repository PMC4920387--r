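# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Population (divide-by-n) covariance: the convention under which
# S * cov reproduces summed deviations exactly.
cov_pop <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 1L)
  mean(x * y) - mean(x) * mean(y)
}

#' Encode a resource environment
#'
#' Environments are the four combinations of fertilization and shading,
#' written `F-S-`, `F-S+`, `F+S-`, `F+S+` (fertilizer first, shade second).
#'
#' @param shade logical, plot is shaded.
#' @param fertilized logical, plot is fertilized.
#' @return character environment code.
#' @examples
#' environment_code(shade = FALSE, fertilized = TRUE)  # "F+S-"
#' @export
environment_code <- function(shade, fertilized) {
  stopifnot(is.logical(shade), is.logical(fertilized))
  paste0("F", ifelse(fertilized, "+", "-"), "S", ifelse(shade, "+", "-"))
}

#' All four environment codes
#' @return character vector of the four environment codes.
#' @export
environment_levels <- function() {
  c("F-S-", "F-S+", "F+S-", "F+S+")
}

# Parse an environment given either as a code string or a list/logical pair.
as_environment <- function(env) {
  if (is.character(env) && length(env) == 1L) {
    if (!env %in% environment_levels()) {
      stop("unknown environment code: ", env, call. = FALSE)
    }
    list(shade = grepl("S\\+", env), fertilized = grepl("F\\+", env))
  } else if (is.list(env) && all(c("shade", "fertilized") %in% names(env))) {
    list(shade = isTRUE(env$shade), fertilized = isTRUE(env$fertilized))
  } else {
    stop("environment must be a code string or list(shade=, fertilized=)",
         call. = FALSE)
  }
}

# '+'-joined sorted species ids; the canonical composition label.
composition_label <- function(species_ids) {
  paste(sort(species_ids), collapse = "+")
}

#' Species of a composition label
#' @param composition a '+'-joined composition label.
#' @return character vector of species ids.
#' @export
composition_species <- function(composition) {
  strsplit(composition, "+", fixed = TRUE)[[1]]
}
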