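#' @importFrom stats median sd mad rbinom runif rnorm rpois cor quantile
#'   setNames approx prcomp coef residuals predict
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# All stochastic package operations route through this so that a seed argument
# fully determines the result without clobbering the session RNG.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying in 32-bit
# integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12289L) %% 2147483629)
}

checkInterval <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] >= x[2])
    stop(sprintf("'%s' must be a numeric interval c(start, end) with start < end", name))
  as.numeric(x)
}

# Centred boxcar moving average; partial windows at the edges are averaged
# over the available samples so the output length equals the input length.
boxcarSmooth <- function(x, widthBins) {
  widthBins <- max(1L, as.integer(round(widthBins)))
  if (widthBins == 1L) return(x)
  n <- length(x)
  half <- widthBins %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (widthBins - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Per-condition column means of a trial x electrode rate matrix.
conditionMeans <- function(rates, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(rates) == length(labels))
  conds <- sort(unique(labels))
  m <- vapply(conds, function(cc) colMeans(rates[labels == cc, , drop = FALSE]),
              numeric(ncol(rates)))
  out <- t(matrix(m, nrow = ncol(rates)))
  rownames(out) <- conds
  out
}
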