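## Redundancy analysis with permutation tests and forward selection of
## environmental predictors (entry by permutation p-value; performed only
## when the global test with all predictors is significant).

## least-squares multivariate fit; returns R2, adjusted R2 (Ezekiel) and
## the F statistic for the model
rdaFit <- function(Y, X) {
  n <- nrow(Y)
  Xc <- scale(as.matrix(X), center = TRUE, scale = TRUE)
  qrX <- qr(Xc)
  m <- qrX$rank
  if (n - m - 1 <= 0)
    stop("too few samples for ", m, " predictor(s): residual df <= 0")
  fit <- qr.fitted(qrX, Y)
  ss_fit <- sum(fit^2)
  ss_tot <- sum(Y^2)
  r2 <- ss_fit / ss_tot
  list(fitted = fit, m = m, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1),
       F = (ss_fit / m) / ((ss_tot - ss_fit) / (n - m - 1)))
}

rdaPermP <- function(Y, X, n_perm, seed) {
  obs <- rdaFit(Y, X)
  Fs <- withSeed(seed, vapply(seq_len(n_perm), function(i)
    rdaFit(Y[sample(nrow(Y)), , drop = FALSE], X)$F, numeric(1)))
  list(F = obs$F, r2 = obs$r2, adj_r2 = obs$adj_r2,
       p = (1 + sum(Fs >= obs$F - 1e-12)) / (1 + n_perm))
}

#' RDA with global test and forward selection of predictors
#'
#' The response (typically Hellinger-transformed abundances) is regressed
#' on the predictor table.  A global permutation test with all predictors
#' runs first; only if it is significant at \code{alpha} does greedy
#' forward selection proceed, at each step adding the predictor with the
#' lowest permutation p-value (< alpha) until none qualifies.  Collinear
#' predictors (rank-deficient fit) are dropped with a warning.  RDA axes
#' are the principal components of the fitted values.
#'
#' @param response samples x features numeric matrix.
#' @param predictors samples x variables data.frame or matrix (numeric).
#' @param alpha entry/global significance level (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed integer seed.
#' @return list with global (F, r2, adj_r2, p), selected (character),
#'   steps (data.frame), adj_r2 (of the selected model), site_scores,
#'   species_scores, biplot_scores; selection fields are NULL when the
#'   global test is not significant.
#' @export
rdaForwardSelect <- function(response, predictors, alpha = 0.05,
                             n_perm = 999L, seed = 1L) {
  Y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  X <- as.matrix(predictors)
  stopifnot(nrow(Y) == nrow(X))
  storage.mode(X) <- "double"
  ## drop collinear columns
  qrX <- qr(scale(X))
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear predictor(s): ", paste(drop, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  global <- rdaPermP(Y, X, n_perm, seed)
  if (global$p >= alpha)
    return(list(global = global, selected = NULL, steps = NULL,
                adj_r2 = NULL, site_scores = NULL, species_scores = NULL,
                biplot_scores = NULL))
  selected <- character(0)
  steps <- NULL
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining)) break
    cand <- lapply(remaining, function(v) {
      Xs <- X[, c(selected, v), drop = FALSE]
      res <- rdaPermP(Y, Xs, n_perm, seed + length(selected))
      ## partial contribution of v given current model
      res
    })
    ps <- vapply(cand, `[[`, 0, "p")
    fs <- vapply(cand, `[[`, 0, "F")
    if (length(selected)) {
      ## partial F of the added term
      base_fit <- rdaFit(Y, X[, selected, drop = FALSE])
      partial <- vapply(remaining, function(v) {
        fit2 <- rdaFit(Y, X[, c(selected, v), drop = FALSE])
        dfres <- nrow(Y) - fit2$m - 1
        (sum(fit2$fitted^2) - sum(base_fit$fitted^2)) /
          ((sum(Y^2) - sum(fit2$fitted^2)) / dfres)
      }, numeric(1))
      ps <- vapply(seq_along(remaining), function(i) {
        v <- remaining[i]
        obsF <- partial[i]
        Fs <- withSeed(seed + 1000L + length(selected) * 100L + i, {
          vapply(seq_len(n_perm), function(b) {
            Yp <- Y[sample(nrow(Y)), , drop = FALSE]
            fit2 <- rdaFit(Yp, X[, c(selected, v), drop = FALSE])
            base2 <- rdaFit(Yp, X[, selected, drop = FALSE])
            dfres <- nrow(Y) - fit2$m - 1
            (sum(fit2$fitted^2) - sum(base2$fitted^2)) /
              ((sum(Yp^2) - sum(fit2$fitted^2)) / dfres)
          }, numeric(1))
        })
        (1 + sum(Fs >= obsF - 1e-12)) / (1 + n_perm)
      }, numeric(1))
      fs <- partial
    }
    ok <- ps < alpha
    if (!any(ok)) break
    pick <- which(ok)[order(ps[ok], -fs[ok])][1]
    selected <- c(selected, remaining[pick])
    steps <- rbind(steps, data.frame(variable = remaining[pick],
                                     p = ps[pick], stringsAsFactors = FALSE))
  }
  if (!length(selected))
    return(list(global = global, selected = character(0), steps = NULL,
                adj_r2 = NULL, site_scores = NULL, species_scores = NULL,
                biplot_scores = NULL))
  fit <- rdaFit(Y, X[, selected, drop = FALSE])
  pc <- prcomp(fit$fitted, center = FALSE)
  n_axes <- min(2L, ncol(pc$x))
  site <- pc$x[, seq_len(n_axes), drop = FALSE]
  list(global = global, selected = selected, steps = steps,
       adj_r2 = fit$adj_r2,
       site_scores = site,
       species_scores = pc$rotation[, seq_len(n_axes), drop = FALSE],
       biplot_scores = cor(scale(X[, selected, drop = FALSE]), site))
}
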