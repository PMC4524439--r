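#' @importFrom stats rnorm runif rbinom rpois rbeta rlnorm quantile median
#'   lm model.matrix p.adjust pt kruskal.test sd var coef resid fitted
#'   complete.cases phyper setNames qnorm aggregate rexp mad cor
#' @importFrom utils head write.table read.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed for a named pipeline stage; stays well below 2^31.
childSeed <- function(seed, stage) {
  offs <- c(cohort = 11L, annotation = 23L, methylation = 37L,
            expression = 53L, terms = 71L, pyro = 89L, surrogates = 101L,
            network = 127L, enrichment = 151L, report = 173L)
  k <- offs[[stage]]
  (as.integer(seed) %% 2000003L) * 1009L + k
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment of a vector of p-values.
#' Thin wrapper over [stats::p.adjust()] so the correction used across the
#' package is a single, named choice.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, monotone in `p`, each `>= p`.
#' @export
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.03))
fdrCorrect <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) && (any(p <= 0, na.rm = TRUE) || any(p > 1, na.rm = TRUE))) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

# shared input check helpers
assertPositiveCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a positive integer", name))
  }
  invisible(as.integer(x))
}
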