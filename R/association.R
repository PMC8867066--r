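#' Pairwise collinearity filter
#'
#' Greedily removes one member of every feature pair whose absolute Pearson
#' correlation meets the threshold, until no such pair remains (the r >= 0.95
#' pruning that reduced the 21 features to 18 in the motivating analysis).
#' The default policy is deterministic: within an offending pair, the member
#' with the larger mean absolute correlation to all other features is
#' dropped. `policy = "random"` picks one member at random (reproducible
#' under `set.seed()`), reproducing the random selection variant.
#'
#' @param X numeric matrix with column names.
#' @param threshold absolute correlation at or above which a pair offends.
#' @param policy "deterministic" or "random".
#' @return list: `retained` (column names), `dropped` (data.frame with the
#'   offending pair, its correlation and which member was dropped).
#' @export
collinearity_filter <- function(X, threshold = 0.95,
                                policy = c("deterministic", "random")) {
  policy <- match.arg(policy)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, !is.null(colnames(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s) ", paste(colnames(X)[sds == 0], collapse = ", "),
            ": correlations treated as 0")
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  keep <- colnames(X)
  dropped <- data.frame(feature_a = character(0), feature_b = character(0),
                        r = numeric(0), dropped = character(0))
  repeat {
    A <- abs(R[keep, keep, drop = FALSE])
    if (length(keep) < 2 || max(A) < threshold) break
    ij <- which(A == max(A), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop <- if (policy == "random") {
      sample(c(a, b), 1)
    } else {
      ma <- mean(A[a, setdiff(keep, c(a, b))])
      mb <- mean(A[b, setdiff(keep, c(a, b))])
      if (length(keep) == 2 || ma >= mb) a else b
    }
    dropped <- rbind(dropped,
                     data.frame(feature_a = a, feature_b = b,
                                r = R[a, b], dropped = drop))
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, dropped = dropped)
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of the trait on z-scored features, so coefficient
#' magnitudes are comparable across features; raw-scale coefficients are
#' returned alongside. Significance is the two-sided coefficient t-test.
#'
#' @param X numeric feature matrix (already collinearity-filtered).
#' @param y trait values.
#' @return list of class `mlr_fit`: `coefficients` data.frame (feature,
#'   estimate, se, t, p_value, estimate_raw), `fitted`, `r_squared`, `model`
#'   (the underlying `lm`).
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) > ncol(X), nrow(X) == length(y))
  Z <- scale(X)
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(X) + 1) {
    bad <- colnames(X)[qrz$pivot[seq(qrz$rank + 1, ncol(X) + 1)] - 1]
    stop("rank-deficient design; linearly dependent columns: ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(y = y, Z, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients[-1, , drop = FALSE]
  coefs <- data.frame(feature = colnames(X),
                      estimate = sm[, 1], se = sm[, 2], t = sm[, 3],
                      p_value = sm[, 4],
                      estimate_raw = sm[, 1] / attr(Z, "scaled:scale"),
                      row.names = NULL)
  structure(list(coefficients = coefs, fitted = stats::fitted(fit),
                 r_squared = summary(fit)$r.squared, model = fit),
            class = "mlr_fit")
}

#' Shadow-feature random-forest importance (Boruta-style)
#'
#' Iteratively appends a permuted copy (shadow) of every still-undecided
#' feature, fits a random forest with OOB permutation importance, and scores
#' a hit for each real feature whose importance exceeds the maximum shadow
#' importance. After each iteration a two-sided binomial test on the
#' accumulated hit counts confirms (significantly more hits than chance) or
#' rejects (significantly fewer) features at level `alpha`; features still
#' undecided after `max_iterations` are tentative. By default the binomial
#' p-values are Bonferroni-adjusted for the number of features under test
#' (the reference shadow-feature implementation's default): without it, a
#' feature whose spurious in-sample correlation persists across iterations
#' is too easily confirmed on pure noise.
#'
#' @param X numeric feature matrix with column names.
#' @param y response.
#' @param max_iterations maximum Boruta iterations.
#' @param alpha test level for the binomial decision.
#' @param adjust "bonferroni" (default) or "none".
#' @param ntree trees per forest.
#' @return list of class `shadow_importance`: `decision` (named factor
#'   confirmed/rejected/tentative), `hits`, `iterations`, `history` (matrix
#'   of importances per iteration).
#' @export
shadow_importance <- function(X, y, max_iterations = 10L, alpha = 0.05,
                              adjust = c("bonferroni", "none"),
                              ntree = 100L) {
  adjust <- match.arg(adjust)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 20, !is.null(colnames(X)))
  p <- ncol(X)
  feats <- colnames(X)
  if (stats::sd(y) == 0) {
    warning("constant response: all features rejected")
    dec <- factor(rep("rejected", p), levels = c("confirmed", "rejected", "tentative"))
    names(dec) <- feats
    return(structure(list(decision = dec, hits = stats::setNames(rep(0L, p), feats),
                          iterations = 0L, history = NULL),
                     class = "shadow_importance"))
  }
  dec <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(rep(0L, p), feats)
  tested <- stats::setNames(rep(0L, p), feats)
  history <- list()
  for (it in seq_len(max_iterations)) {
    active <- feats[dec != "rejected"]
    if (!length(active) || all(dec[active] == "confirmed")) break
    Xa <- X[, active, drop = FALSE]
    Xs <- apply(Xa, 2, sample)
    colnames(Xs) <- paste0(".shadow.", active)
    fit <- rf_fit(cbind(Xa, Xs), y, ntree = ntree, importance = TRUE)
    imp <- fit$importance
    shadow_max <- max(imp[colnames(Xs)])
    undecided <- active[dec[active] == "tentative"]
    hit <- imp[undecided] > shadow_max
    hits[undecided] <- hits[undecided] + as.integer(hit)
    tested[undecided] <- tested[undecided] + 1L
    history[[it]] <- imp
    m_adj <- if (adjust == "bonferroni") length(undecided) else 1L
    for (f in undecided) {
      pv <- min(stats::binom.test(hits[[f]], tested[[f]], 0.5)$p.value *
                  m_adj, 1)
      if (pv < alpha) {
        dec[f] <- if (hits[[f]] > tested[[f]] / 2) "confirmed" else "rejected"
      }
    }
  }
  structure(list(decision = factor(dec, levels = c("confirmed", "rejected",
                                                   "tentative")),
                 hits = hits, iterations = length(history),
                 history = history),
            class = "shadow_importance")
}

#' Repeated k-fold cross-validation of MLR and RF
#'
#' Within each repeat the same fold assignment is shared by both models;
#' accuracy is Pearson's r and RMSE between out-of-fold predictions and
#' observations. Models are compared with a paired t-test across the
#' repeat-level means.
#'
#' @param X feature matrix.
#' @param y trait values.
#' @param folds number of CV folds (default 10).
#' @param repeats number of repeats (default 5).
#' @param ntree trees for the RF model.
#' @return list of class `cv_result`: `per_repeat` (data.frame), `summary`
#'   (mean and sd of r and RMSE per model), `comparison` (paired p-values
#'   for r and RMSE).
#' @export
cross_validate <- function(X, y, folds = 10L, repeats = 5L, ntree = 500L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= folds, n == length(y))
  per <- expand.grid(repeat_ = seq_len(repeats), model = c("MLR", "RF"),
                     stringsAsFactors = FALSE)
  per$r <- NA_real_; per$rmse <- NA_real_
  for (rep_i in seq_len(repeats)) {
    fold <- sample(rep(seq_len(folds), length.out = n))
    if (min(table(fold)) < 2) stop("a fold has fewer than 2 samples")
    pred_mlr <- pred_rf <- rep(NA_real_, n)
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- !tr
      dtr <- data.frame(y = y[tr], X[tr, , drop = FALSE], check.names = FALSE)
      lmfit <- stats::lm(y ~ ., data = dtr)
      pred_mlr[te] <- stats::predict(
        lmfit, newdata = data.frame(X[te, , drop = FALSE], check.names = FALSE))
      rffit <- rf_fit(X[tr, , drop = FALSE], y[tr], ntree = ntree,
                      importance = FALSE)
      pred_rf[te] <- predict.citrus_rf(rffit, X[te, , drop = FALSE])
    }
    for (m in c("MLR", "RF")) {
      pr <- if (m == "MLR") pred_mlr else pred_rf
      i <- per$repeat_ == rep_i & per$model == m
      per$r[i] <- stats::cor(pr, y)
      per$rmse[i] <- sqrt(mean((pr - y)^2))
    }
  }
  summ <- do.call(rbind, lapply(c("MLR", "RF"), function(m) {
    s <- per[per$model == m, ]
    data.frame(model = m, mean_r = mean(s$r), sd_r = stats::sd(s$r),
               mean_rmse = mean(s$rmse), sd_rmse = stats::sd(s$rmse))
  }))
  rm_ <- per[per$model == "MLR", ]; rf_ <- per[per$model == "RF", ]
  comparison <- data.frame(
    metric = c("r", "rmse"),
    p_value = c(stats::t.test(rf_$r, rm_$r, paired = TRUE)$p.value,
                stats::t.test(rf_$rmse, rm_$rmse, paired = TRUE)$p.value))
  structure(list(per_repeat = per, summary = summ, comparison = comparison),
            class = "cv_result")
}

#' Apparent and partial correlations
#'
#' Partial correlations come from the inverse correlation matrix
#' (precision matrix): rho_ij.rest = -Omega_ij / sqrt(Omega_ii Omega_jj),
#' i.e. the correlation between variables i and j after removing the linear
#' effects of all other columns. Significance uses the t statistic with
#' n - 2 - k degrees of freedom, k the number of controls. Apparent
#' (marginal) Pearson correlations and their tests are returned alongside.
#'
#' @param M numeric matrix of features plus traits (columns = variables).
#' @return list of class `correlation_result`: `apparent`, `apparent_p`,
#'   `partial`, `partial_p`, `n`.
#' @export
partial_correlations <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M) - 2
  if (n <= ncol(M) + 2) stop("need n > number of variables + 2")
  R <- stats::cor(M)
  Omega <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; apply collinearity_filter() first"))
  d <- sqrt(diag(Omega))
  P <- -Omega / tcrossprod(d)
  diag(P) <- 1
  tstat <- function(r, df) r * sqrt(df / pmax(1 - r^2, 1e-15))
  df_p <- n - 2 - k
  if (df_p < 1) stop("not enough samples for the partial-correlation test")
  Pp <- 2 * stats::pt(abs(tstat(P, df_p)), df_p, lower.tail = FALSE)
  Ap <- 2 * stats::pt(abs(tstat(R, n - 2)), n - 2, lower.tail = FALSE)
  diag(Pp) <- diag(Ap) <- NA
  structure(list(apparent = R, apparent_p = Ap, partial = P, partial_p = Pp,
                 n = n), class = "correlation_result")
}
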