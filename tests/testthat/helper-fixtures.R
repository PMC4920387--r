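# Shared fixtures, built in code.

# One default synthetic experiment, computed once per test run.
default_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_experiment(generator_config(seed = 101))
    cache
  }
})

# A tiny hand-made design: 1 block slice with one monoculture per species
# of one pool in one environment plus one 2-species mixture, enough to
# exercise lookups without the full factorial.
tiny_design <- function() {
  data.frame(
    plot_id = c("m1", "m2", "x1"),
    block = 1L, template_group = "X", pool = "A",
    richness = c(1L, 1L, 2L),
    composition = c("spA", "spB", "spA+spB"),
    shade = FALSE, fertilized = FALSE,
    environment = "F-S-", stringsAsFactors = FALSE)
}

tiny_table <- function(mA = 100, mB = 200, yA = 60, yB = 120) {
  data.frame(
    plot_id = c("m1", "m2", "x1", "x1"),
    species_id = c("spA", "spB", "spA", "spB"),
    biomass = c(mA, mB, yA, yB), stringsAsFactors = FALSE)
}

# Independent brute-force tripartite partition: explicit summed-deviation
# evaluation of the three components (population covariance written as a
# raw loop), kept free of package internals.
brute_partition <- function(y, bm, prop = rep(1 / length(y), length(y))) {
  s <- length(y)
  ry <- y / bm
  ryt <- sum(ry)
  d_ry <- ry - prop
  covl <- function(a, b) {
    tot <- 0
    for (i in seq_len(s)) tot <- tot + (a[i] - mean(a)) * (b[i] - mean(b))
    tot / s
  }
  list(ne = sum(y) - sum(prop * bm),
       tice = s * mean(d_ry) * mean(bm),
       de = s * covl(bm, ry / ryt - prop),
       de_printed = s * covl(bm, d_ry / ryt),  # paper-printed argument
       tdce = s * covl(bm, ry - ry / ryt))
}

random_mixture <- function(s = sample(2:6, 1)) {
  list(y = runif(s, 0, 400), bm = runif(s, 50, 600))
}
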