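# Shared fixtures, built once per test run.

# simple rasterized shapes
disc_mask <- function(n = 201, r = n %/% 3, cx = (n + 1) / 2, cy = cx) {
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  (i - cy)^2 + (j - cx)^2 <= r^2
}

square_mask <- function(n = 201, side = 120) {
  m <- matrix(FALSE, n, n)
  s0 <- (n - side) %/% 2
  m[s0 + seq_len(side), s0 + seq_len(side)] <- TRUE
  m
}

ellipse_mask <- function(n = 301, a = 120, b = 60) {
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  ((j - c0) / a)^2 + ((i - c0) / b)^2 <= 1
}

flat_image <- function(rgb, n = 32) {
  array(rep(rgb, each = n * n), dim = c(n, n, 3))
}

# one default rendered fruit, memoised across tests
default_fruit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(101)
      cache <<- render_fruit(fruit_spec(), seed = 101)
    }
    cache
  }
})

# small feature-level population with traits, memoised
feature_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(202)
      pop <- sample_population(20, n_years = 2, fruits_per_genotype_year = 5,
                               render = FALSE)
      ph <- rbind(generate_traits(pop$truth, pop$meta, trait_model("Peeling")),
                  generate_traits(pop$truth, pop$meta, trait_model("FruH")))
      cache <<- list(pop = pop, phenotypes = ph)
    }
    cache
  }
})

# feature table with exactly three disjoint near-duplicate pairs (the
# multicollinearity construction: 21 features, |r| >= 0.95 within the three
# pairs, all other pairwise |r| < 0.95)
collinear_feature_table <- function(n = 100, seed = 1) {
  set.seed(seed)
  nm <- feature_names()
  pairs <- list(c("Whole area", "Radius"),
                c("Flavedo Lab (L)", "Flavedo Lab (b)"),
                c("Albedo area", "Albedo thickness"))
  base <- setdiff(nm, unlist(lapply(pairs, `[`, 2)))
  X <- matrix(rnorm(n * length(base)), n, length(base),
              dimnames = list(NULL, base))
  for (p in pairs) {
    X <- cbind(X, matrix(X[, p[1]] + rnorm(n, 0, 0.05),
                         dimnames = list(NULL, p[2])))
  }
  X <- X[, nm]
  R <- abs(cor(X)); diag(R) <- 0
  over <- which(R >= 0.95, arr.ind = TRUE)
  stopifnot(nrow(over) == 6)  # the three pairs, twice each by symmetry
  X
}
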