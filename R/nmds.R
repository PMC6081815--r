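## Nonmetric multidimensional scaling by alternating isotonic regression
## (primary ties averaged) and Guttman-transform majorization, minimizing
## Kruskal stress-1, best of several random starts.

## one SMACOF run from a starting configuration; returns config, stress,
## stress history and convergence flag
nmdsRun <- function(dvec, n, k, X, max_iter, tol) {
  ord <- order(dvec)
  tie_groups <- match(dvec[ord], unique(dvec[ord]))
  stress_hist <- numeric(0)
  stress_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- as.matrix(dist(X))
    Dv <- D[lower.tri(D)]
    ## monotone fit of config distances on dissimilarity ranks; average
    ## within tied dissimilarity groups first (primary tie treatment)
    y <- Dv[ord]
    y_tied <- ave(y, tie_groups)
    fit <- isoreg(seq_along(y_tied), y_tied)$yf
    dhat_v <- numeric(length(Dv))
    dhat_v[ord] <- fit
    dhat <- matrix(0, n, n)
    dhat[lower.tri(dhat)] <- dhat_v
    dhat <- dhat + t(dhat)
    stress <- sqrt(sum((Dv - dhat_v)^2) / sum(Dv^2))
    stress_hist <- c(stress_hist, stress)
    if (is.finite(stress_old) && abs(stress_old - stress) < tol) {
      converged <- TRUE
      break
    }
    stress_old <- stress
    ## Guttman transform
    ratio <- ifelse(D > 0, dhat / D, 0)
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
  }
  list(X = X, stress = stress_hist[length(stress_hist)],
       stress_history = stress_hist, converged = converged)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Alternates isotonic regression of configuration distances on
#' dissimilarity ranks with Guttman-transform updates; keeps the best of
#' \code{n_starts} starts (classical scaling plus random configurations).
#' Deterministic under a fixed seed.
#'
#' @param d a \code{dist} or symmetric dissimilarity matrix.
#' @param k number of ordination axes (default 2).
#' @param n_starts number of starts (default 20).
#' @param max_iter iterations per start (default 200).
#' @param tol stress-change convergence tolerance (default 1e-6).
#' @param seed integer seed.
#' @return list with coordinates (n x k), stress, converged,
#'   stress_history (of the best start) and seed.
#' @export
nmdsOrdination <- function(d, k = 2L, n_starts = 20L, max_iter = 200L,
                           tol = 1e-6, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < k + 2) stop("need at least k + 2 samples")
  dvec <- dm[lower.tri(dm)]
  best <- NULL
  withSeed(seed, {
    for (s in seq_len(n_starts)) {
      X0 <- if (s == 1L) {
        cm <- suppressWarnings(cmdscale(dm, k = k))
        if (ncol(cm) < k) cbind(cm, matrix(rnorm(n * (k - ncol(cm)), sd = 1e-4),
                                           n, k - ncol(cm))) else cm
      } else matrix(rnorm(n * k), n, k)
      run <- nmdsRun(dvec, n, k, X0, max_iter, tol)
      if (is.null(best) || run$stress < best$stress) best <- run
    }
  })
  coords <- best$X
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  list(coordinates = coords, stress = best$stress,
       converged = best$converged, stress_history = best$stress_history,
       seed = seed)
}
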