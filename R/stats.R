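## Ordination and permutation statistics for community matrices.
## Conventions shared by all permutation tests: deterministic under a
## fixed seed; p = (1 + #{perm stat >= observed}) / (1 + n_perm), so the
## p-value resolution is exactly 1/(n_perm + 1) and the observed statistic
## is always counted in the null.

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(x, y) = sum|x - y| / sum(x + y)} over rows (samples).
#'
#' @param matrix non-negative samples x features matrix.
#' @return a \code{dist} object.
#' @export
brayCurtis <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(m < 0)) stop("abundances must be non-negative")
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(m[i, ] + m[j, ])
    if (denom == 0)
      stop("two all-zero samples: Bray-Curtis undefined for rows ",
           i, " and ", j)
    out[i, j] <- out[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
  }
  as.dist(out)
}

#' Hellinger transform
#'
#' \code{y_ij = sqrt(x_ij / rowSum_i)}; rows then have unit sum of squares
#' and the transform is invariant to row scaling.
#'
#' @param matrix non-negative samples x features matrix with positive row
#'   sums.
#' @return transformed matrix.
#' @export
hellinger <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(m < 0)) stop("abundances must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) stop("all-zero row: Hellinger transform undefined")
  sqrt(sweep(m, 1, rs, "/"))
}

## all permutations of 1..n (n! rows); used for exhaustive PERMANOVA
permEnumerate <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permEnumerate(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

## Anderson's pseudo-F from squared dissimilarities and group labels
pseudoF <- function(d2, labels) {
  n <- length(labels)
  groups <- unique(labels)
  a <- length(groups)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(labels == g)
    ss_within <- ss_within + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) /
      length(idx)
  }
  ss_among <- ss_total - ss_within
  list(F = (ss_among / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_among / ss_total)
}

#' PERMANOVA (one factor, free permutation of labels)
#'
#' Permutational multivariate ANOVA on a dissimilarity matrix: pseudo-F
#' from the among/within partition of squared dissimilarities, p-value by
#' label permutation with the +1 convention.  With
#' \code{exhaustive = TRUE} (n <= 8) all n! label permutations are
#' enumerated and p is the exact fraction with F >= observed.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @param labels group labels (>= 2 groups, each >= 2 members).
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list with statistic (pseudo-F), R2, p_value, n_permutations,
#'   seed.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  stopifnot(nrow(dm) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two members")
  d2 <- dm^2
  obs <- pseudoF(d2, labels)
  if (exhaustive) {
    n <- length(labels)
    if (n > 8) stop("exhaustive enumeration supported for n <= 8")
    perms <- permEnumerate(n)
    Fs <- apply(perms, 1, function(p) pseudoF(d2, labels[p])$F)
    p_val <- mean(Fs >= obs$F - 1e-12)
    n_eff <- nrow(perms)
  } else {
    Fs <- withSeed(seed, vapply(seq_len(n_perm), function(i)
      pseudoF(d2, sample(labels))$F, numeric(1)))
    p_val <- (1 + sum(Fs >= obs$F - 1e-12)) / (1 + n_perm)
    n_eff <- n_perm
  }
  list(statistic = obs$F, R2 = obs$R2, p_value = p_val,
       n_permutations = n_eff, seed = seed)
}

## center and scale a configuration to unit sum of squares
standardizeConfig <- function(X) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  ss <- sum(X^2)
  if (ss == 0) stop("degenerate configuration")
  X / sqrt(ss)
}

#' Procrustes superimposition with protest permutation test
#'
#' Both configurations are centered and scaled to unit sum of squares;
#' \code{Y} is rotated onto \code{X} by the optimal orthogonal rotation.
#' \code{m2} is the minimized residual sum of squares and the Procrustes
#' correlation is \code{sqrt(1 - m2)}.  Significance by permutation of the
#' rows of \code{Y}.
#'
#' @param X,Y coordinate matrices with equal row counts (>= 3).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with correlation, m2, rotation, p_value, n_permutations,
#'   seed.
#' @export
procrustesProtest <- function(X, Y, n_perm = 999L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 3) stop("need at least 3 rows")
  if (ncol(Y) < ncol(X)) Y <- cbind(Y, matrix(0, nrow(Y), ncol(X) - ncol(Y)))
  if (ncol(X) < ncol(Y)) X <- cbind(X, matrix(0, nrow(X), ncol(Y) - ncol(X)))
  Xs <- standardizeConfig(X)
  corrOf <- function(Ym) {
    sum(svd(crossprod(Xs, standardizeConfig(Ym)))$d)
  }
  obs <- corrOf(Y)
  sv <- svd(crossprod(Xs, standardizeConfig(Y)))
  perm_stats <- withSeed(seed, vapply(seq_len(n_perm), function(i)
    corrOf(Y[sample(nrow(Y)), , drop = FALSE]), numeric(1)))
  p_val <- (1 + sum(perm_stats >= obs - 1e-12)) / (1 + n_perm)
  list(correlation = obs, m2 = 1 - obs^2,
       rotation = sv$v %*% t(sv$u),
       p_value = p_val, n_permutations = n_perm, seed = seed)
}

#' Principal component analysis of a samples x variables table
#'
#' Variables are z-score standardized (optional) and the covariance
#' eigendecomposition taken; zero-variance variables are dropped with a
#' warning.
#'
#' @param table numeric samples x variables matrix or data.frame.
#' @param standardize scale variables to unit variance (default TRUE).
#' @return list with coordinates (scores), variance_explained, loadings.
#' @export
pcaOrdination <- function(table, standardize = TRUE) {
  m <- as.matrix(table)
  stopifnot(nrow(m) >= 3, ncol(m) >= 2)
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = standardize)
  list(coordinates = pc$x,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation)
}
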