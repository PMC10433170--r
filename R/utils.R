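# Seed hierarchy: master -> subject -> trial. A small LCG step keeps every
# derived seed a deterministic pure function of (parent, key) and inside the
# 32-bit range R accepts in set.seed().
deriveSeed <- function(parent, key) {
  m <- 2147483647
  as.integer(((as.numeric(parent) %% m) * 48271 + as.numeric(key) * 9973) %% m)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around the standard t-based correlation test, returning the
#' estimate and two-sided p-value; used to relate modulation depth to
#' z-scores and harmonic index to stimulation frequency.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return named numeric `c(rho, p)`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearsonCor needs two vectors of equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearsonCor: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Storey q-values
#'
#' False discovery rate q-values with the proportion of true nulls estimated
#' as `pi0 = mean(p > lambda) / (1 - lambda)` (clamped to (0, 1]); `lambda =
#' 0.5` by default. With `pi0 = 1` this reduces to Benjamini-Hochberg.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param lambda tuning parameter in (0, 1).
#' @param pi0 optional override for the null proportion (e.g. 1 for BH).
#' @return numeric q-values, same order as `p`.
#' @export
storeyQ <- function(p, lambda = 0.5, pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1), lambda > 0, lambda < 1)
  m <- length(p)
  if (is.null(pi0)) pi0 <- mean(p > lambda) / (1 - lambda)
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(stats::setNames(q[order(o)], names(p)), 1)
}
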