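chain_data <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n); z <- x + rnorm(n, 0, 0.7); y <- z + rnorm(n, 0, 0.7)
  cbind(X = x, Z = z, Y = y)
}

skeleton <- function(st) {
  a <- structure_arcs(st)
  if (!nrow(a)) return(character(0))
  sort(apply(cbind(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2])), 1,
             paste, collapse = "-"))
}

test_that("empty-graph BIC equals the univariate closed form", {
  set.seed(20)
  for (k in c(3, 6)) {
    M <- matrix(rnorm(200 * k), 200, k,
                dimnames = list(NULL, paste0("v", seq_len(k))))
    M <- scale(M)
    st <- network_structure(colnames(M))
    n <- nrow(M)
    ll <- sum(vapply(seq_len(k), function(j) {
      s2 <- mean((M[, j] - mean(M[, j]))^2)
      -n / 2 * (log(2 * pi * s2) + 1)
    }, numeric(1)))
    expect_equal(bic_score(st, M), ll - k * (2 / 2) * log(n),
                 tolerance = 1e-8)
  }
})

test_that("BIC increases when adding a true strong arc, and is decomposable", {
  M <- chain_data(500, seed = 21)
  empty <- network_structure(colnames(M))
  with_arc <- network_structure(colnames(M), list(Z = "X"))
  expect_gt(bic_score(with_arc, M), bic_score(empty, M))
  # decomposability: changing Z's parents leaves X and Y terms unchanged
  n1 <- citrusect:::.node_score(M, "X", character(0))
  n2 <- citrusect:::.node_score(M, "Y", character(0))
  expect_equal(bic_score(with_arc, M) - citrusect:::.node_score(M, "Z", "X"),
               n1 + n2, tolerance = 1e-10)
  # singular parent design scores -Inf
  M2 <- cbind(M, X2 = M[, "X"])
  sing <- network_structure(colnames(M2), list(Y = c("X", "X2")))
  expect_equal(bic_score(sing, M2), -Inf)
})

test_that("hill climbing returns the empty graph for independent data", {
  set.seed(22)
  M <- matrix(rnorm(5000 * 4), 5000, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  st <- hill_climb(M)
  expect_equal(nrow(structure_arcs(st)), 0L)
})

test_that("hill climbing recovers the chain skeleton", {
  set.seed(23)
  ok <- vapply(1:20, function(i) {
    M <- chain_data(2000)
    identical(skeleton(hill_climb(M)), c("X-Z", "Y-Z"))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the blacklist is respected in every learned structure", {
  set.seed(24)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  trait <- f1 - f2 + rnorm(n, 0, 0.4)
  M <- cbind(f1 = f1, f2 = f2, Trait = trait)
  bl <- trait_blacklist(colnames(M), "Trait")
  for (alg in list(hill_climb, tabu_search)) {
    st <- alg(M, blacklist = bl)
    arcs <- structure_arcs(st)
    expect_false(any(arcs[, "from"] == "Trait"))
    expect_true(any(arcs[, "to"] == "Trait"))  # trait still connected
  }
})

test_that("tabu search never scores below hill climbing and degenerates to it", {
  set.seed(25)
  for (i in 1:5) {
    M <- matrix(rnorm(120 * 4), 120, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
    M[, 2] <- M[, 1] + rnorm(120, 0, 0.5)
    M[, 4] <- M[, 3] - M[, 2] + rnorm(120, 0, 0.5)
    set.seed(1000 + i); hc <- hill_climb(M)
    set.seed(2000 + i); tb <- tabu_search(M)
    expect_gte(bic_score(tb, M), bic_score(hc, M) - 1e-9)
    set.seed(1000 + i)
    tb0 <- tabu_search(M, tabu_length = 0L, max_stagnation = 0L)
    expect_identical(structure_arcs(tb0), structure_arcs(hc))
  }
})

test_that("incremental move scoring equals full rescoring", {
  M <- chain_data(300, seed = 26)
  cache <- new.env(parent = emptyenv())
  st <- network_structure(colnames(M))
  for (mv in list(list(type = "add", from = "X", to = "Z"),
                  list(type = "add", from = "Z", to = "Y"))) {
    delta <- citrusect:::.move_delta(M, st, mv, cache)
    after <- citrusect:::.apply_move(st, mv)
    expect_equal(delta, bic_score(after, M) - bic_score(st, M),
                 tolerance = 1e-8)
    st <- after
  }
  # reverse move touches both endpoints
  mv <- list(type = "reverse", from = "X", to = "Z")
  delta <- citrusect:::.move_delta(M, st, mv, cache)
  expect_equal(delta, bic_score(citrusect:::.apply_move(st, mv), M) -
                 bic_score(st, M), tolerance = 1e-8)
})

test_that("bootstrap averaging quantifies arc support coherently", {
  set.seed(27)
  M <- chain_data(400)
  bc <- bootstrap_average(M, algorithm = "hc", replicates = 60)
  a <- bc$arcs
  expect_true(all(a$strength >= 0 & a$strength <= 1))
  expect_true(all(a$direction_confidence >= 0 & a$direction_confidence <= 1))
  # undirected strength symmetric; direction confidences sum to 1
  for (i in seq_len(nrow(a))) {
    j <- which(a$from == a$to[i] & a$to == a$from[i])
    if (length(j)) {
      expect_equal(a$strength[i], a$strength[j])
      expect_equal(a$direction_confidence[i] + a$direction_confidence[j], 1)
    }
  }
  # a dependency present in every replicate has strength 1
  xz <- a$strength[a$from == "X" & a$to == "Z"]
  expect_equal(max(xz, 0), 1)
})

test_that("symmetric two-variable dependency has ~0.5 direction confidence", {
  set.seed(28)
  n <- 400
  x <- rnorm(n); y <- x + rnorm(n)
  M <- cbind(A = x, B = y)
  bc <- bootstrap_average(M, algorithm = "hc", replicates = 500)
  dc <- bc$arcs$direction_confidence[bc$arcs$from == "A"]
  expect_equal(dc, 0.5, tolerance = 0.05)
})

test_that("averaged network honours thresholds and stays acyclic", {
  set.seed(29)
  M <- chain_data(400)
  bc <- bootstrap_average(M, algorithm = "hc", replicates = 50)
  expect_equal(nrow(structure_arcs(averaged_network(bc, threshold = 1.01))),
               0L)
  full <- averaged_network(bc, threshold = 0)
  expect_false(citrusect:::.is_cyclic(full))
  half <- averaged_network(bc, threshold = 0.5)
  expect_true(all(skeleton(half) %in% c("X-Z", "Y-Z", "X-Y")))
})
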