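# deterministic random inputs shared across test files

random_image <- function(seed, max_side = 8L, values = 0:255) {
  withr::with_seed(seed, {
    h <- sample.int(max_side, 1L)
    w <- sample.int(max_side, 1L)
    matrix(sample(values, h * w, replace = TRUE), h, w)
  })
}

# finite-pair H1-style diagram with exponential lifespans
random_pd <- function(n, seed, rate = 0.1) {
  withr::with_seed(seed, {
    birth <- runif(n, 0, 100)
    life <- stats::rexp(n, rate) + 1e-6
    tibble::tibble(dim = 1L, birth = birth, death = birth + life,
                   lifespan = life)
  })
}

# Betti curve implied by a persistence diagram: points alive at t
implied_betti <- function(pd, thresholds) {
  vapply(thresholds, function(t) sum(pd$birth <= t & pd$death > t),
         numeric(1))
}
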