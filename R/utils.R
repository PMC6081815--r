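#' @import methods
#' @importFrom stats rnorm rpois rbinom runif rgamma sd dist hclust cutree
#'   prcomp cmdscale isoreg pt pnorm qnorm var cov cor t.test as.dist
#'   setNames ave
#' @importFrom utils head read.delim write.table
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.  All generators and permutation tests funnel through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Accept a character scalar, DNAString or length-1 DNAStringSet; return
## an uppercase character scalar.
asSequenceChar <- function(x) {
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    x <- x[[1L]]
  }
  if (is(x, "DNAString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

## Named DNAStringSet of one sequence, carrying role/taxonomy metadata.
asRecord <- function(seq, id, role = c("viral", "host"), taxonomy = NA_character_) {
  role <- match.arg(role)
  out <- Biostrings::DNAStringSet(setNames(seq, id))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(role = role, taxonomy = taxonomy)
  out
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopifnotScalarFraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("'%s' must be a fraction %s", name,
                        if (open) "in (0, 1)" else "in [0, 1]"), call. = FALSE)
  invisible(TRUE)
}
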