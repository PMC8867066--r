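#' Year-adjusted genotype values by REML/BLUP
#'
#' Fits the mixed linear model y = mu + year (fixed) + genotype (random) + e
#' to the records of one variable and returns the shrunken genotype effects
#' (BLUPs). Restricted maximum likelihood is profiled down to the single
#' variance ratio lambda = sigma2_genotype / sigma2_residual and optimized
#' in one dimension, which is exact for this model class. With a single
#' year level the year effect is dropped with a warning; a boundary fit
#' pins the genotype variance at 0 with a warning.
#'
#' @param records data.frame with columns `genotype`, `year`, `value`.
#' @param lambda optional fixed variance ratio; when supplied, REML
#'   estimation is skipped (used e.g. by the balanced-design closed form).
#' @return list of class `genotype_values`: `values` (data.frame with
#'   genotype, blup, expected = overall fixed-effect mean + blup),
#'   `sigma2_g`, `sigma2_e`, `lambda`, `year_effects` (named, first year as
#'   reference), `mu` (fixed-effect mean averaged over years), `logLik_reml`.
#' @export
fit_blup <- function(records, lambda = NULL) {
  stopifnot(all(c("genotype", "year", "value") %in% names(records)))
  if (anyNA(records[c("genotype", "year", "value")]) ||
      any(!is.finite(records$value)))
    stop("records contain missing or non-finite entries")
  g <- factor(records$genotype)
  yr <- factor(records$year)
  y <- records$value
  n <- length(y)
  if (nlevels(g) < 2) stop("need at least 2 genotypes")

  if (nlevels(yr) > 1) {
    X <- stats::model.matrix(~yr)
  } else {
    X <- matrix(1, n, 1)
    warning("single year level: year effect dropped")
  }
  Z <- stats::model.matrix(~g - 1)
  p <- ncol(X); q <- ncol(Z)
  ni <- colSums(Z)

  XtX <- crossprod(X); Xty <- crossprod(X, y)
  ZtX <- crossprod(Z, X); Zty <- crossprod(Z, y)

  # profiled -2 restricted log-likelihood in log(lambda)
  neg2reml <- function(loglam) {
    lam <- exp(loglam)
    D <- ni + 1 / lam                      # diag(Z'Z + I/lambda)
    # V^{-1} = I - Z diag(1/D) Z'
    XtViX <- XtX - crossprod(ZtX, ZtX / D)
    XtViy <- Xty - crossprod(ZtX, Zty / D)
    beta <- solve(XtViX, XtViy)
    r <- y - X %*% beta
    Ztr <- crossprod(Z, r)
    rVir <- sum(r^2) - sum(Ztr^2 / D)
    s2e <- rVir / (n - p)
    logdetV <- sum(log1p(lam * ni))
    as.numeric((n - p) * log(s2e) + logdetV +
                 determinant(XtViX, logarithm = TRUE)$modulus)
  }

  if (is.null(lambda)) {
    opt <- stats::optimize(neg2reml, interval = c(-14, 14))
    lam <- exp(opt$minimum)
    if (opt$minimum < -13) {
      warning("genotype variance pinned at 0 (boundary fit)")
      lam <- 0
    }
  } else {
    lam <- lambda
  }

  if (lam == 0) {
    D <- rep(Inf, q)
    beta <- solve(XtX, Xty)
    r <- y - X %*% beta
    s2e <- sum(r^2) / (n - p)
    u <- rep(0, q)
  } else {
    D <- ni + 1 / lam
    XtViX <- XtX - crossprod(ZtX, ZtX / D)
    XtViy <- Xty - crossprod(ZtX, Zty / D)
    beta <- solve(XtViX, XtViy)
    r <- y - X %*% beta
    Ztr <- crossprod(Z, r)
    s2e <- (sum(r^2) - sum(Ztr^2 / D)) / (n - p)
    u <- as.numeric(Ztr / D)               # BLUP of genotype effects
  }
  s2g <- lam * s2e

  year_eff <- if (p > 1) stats::setNames(c(0, beta[-1]), levels(yr)) else
    stats::setNames(0, levels(yr)[1])
  mu <- as.numeric(beta[1] + mean(year_eff))
  values <- data.frame(genotype = levels(g), blup = u, expected = mu + u,
                       stringsAsFactors = FALSE)
  structure(list(values = values, sigma2_g = s2g, sigma2_e = s2e,
                 lambda = lam, year_effects = year_eff, mu = mu,
                 logLik_reml = if (is.null(lambda)) -opt$objective / 2 else NA),
            class = "genotype_values")
}

#' Year-adjusted genotype value matrix over many variables
#'
#' Applies [fit_blup()] to every variable of a long table and assembles the
#' genotype x variable matrix of expected values used by the association
#' and network stages.
#'
#' @param records long data.frame with columns `genotype`, `year`,
#'   `variable`, `value`.
#' @return numeric matrix, rownames = genotypes, colnames = variables.
#' @export
adjust_genotype_values <- function(records) {
  stopifnot(all(c("genotype", "year", "variable", "value") %in% names(records)))
  vars <- unique(records$variable)
  gens <- sort(unique(as.character(records$genotype)))
  out <- matrix(NA_real_, length(gens), length(vars),
                dimnames = list(gens, vars))
  for (v in vars) {
    sub <- records[records$variable == v, ]
    fit <- suppressWarnings(fit_blup(sub))
    out[fit$values$genotype, v] <- fit$values$expected
  }
  out
}
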