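#' Truncated-normal input parameter distribution
#'
#' @param name Parameter name (e.g. `"f_cl"`, `"T"`, `"m_waste"`,
#'   `"eta_ESP"`, `"eta_WS"`, `"f_metal"`).
#' @param mean,sd Moments of the parent normal; `sd > 0`.
#' @param lo,hi Truncation bounds; default mean +/- 2 sd. `mean` must lie
#'   strictly inside `(lo, hi)`.
#' @return Object of class `parameter_distribution`.
#' @export
parameter_distribution <- function(name, mean, sd, lo = mean - 2 * sd,
                                   hi = mean + 2 * sd) {
  stopifnot(is.character(name), length(name) == 1L, sd > 0, lo < hi,
            mean > lo, mean < hi)
  structure(list(name = name, mean = mean, sd = sd, lo = lo, hi = hi),
            class = "parameter_distribution")
}

# quantile function of the truncated normal
qtnorm <- function(p, d) {
  plo <- stats::pnorm(d$lo, d$mean, d$sd)
  phi <- stats::pnorm(d$hi, d$mean, d$sd)
  stats::qnorm(plo + p * (phi - plo), d$mean, d$sd)
}

# closed-form mean and sd of the truncated normal (used by tests as oracle
# reference is standard; exported for reuse in moment checks)
#' Analytic moments of a truncated normal distribution
#'
#' @param d A [parameter_distribution()].
#' @return List with `mean` and `sd` of the truncated distribution.
#' @export
tnorm_moments <- function(d) {
  a <- (d$lo - d$mean) / d$sd
  b <- (d$hi - d$mean) / d$sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  mu <- d$mean + d$sd * (da - db) / Z
  v <- d$sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = mu, sd = sqrt(v))
}

#' Latin hypercube sample from truncated-normal inputs
#'
#' Each parameter's range of cumulative probability is split into `n`
#' equal-probability strata; exactly one draw falls in each stratum
#' (per parameter), and strata are paired across parameters by independent
#' random permutations. `method = "median"` (default) places each draw at
#' its stratum's probability midpoint, giving fully reproducible designs;
#' `method = "random"` samples uniformly within strata (via
#' [lhs::randomLHS()]).
#'
#' @param dists List of [parameter_distribution()] objects.
#' @param n Sample count, at least 2.
#' @param seed Integer seed; same seed, same matrix.
#' @param method `"median"` or `"random"`.
#' @return `n x p` numeric matrix, columns named by parameter.
#' @export
lhs_sample <- function(dists, n, seed = 1L, method = c("median", "random")) {
  method <- match.arg(method)
  if (inherits(dists, "parameter_distribution")) dists <- list(dists)
  stopifnot(length(dists) >= 1L, n >= 2)
  for (d in dists) stopifnot(inherits(d, "parameter_distribution"))
  p <- length(dists)
  set.seed(as.integer(seed))
  U <- if (method == "random") {
    lhs::randomLHS(n, p)
  } else {
    vapply(seq_len(p),
           function(j) (sample.int(n) - 0.5) / n,
           numeric(n))
  }
  X <- vapply(seq_len(p), function(j) qtnorm(U[, j], dists[[j]]), numeric(n))
  colnames(X) <- vapply(dists, `[[`, character(1), "name")
  X
}

#' Variance attribution by normalized squared Spearman correlations
#'
#' For each input column, the Spearman rank correlation `rho_i` with the
#' output is computed; the contribution factor is
#' `k_i = rho_i^2 / sum(rho^2)`. Being rank-based, the attribution is
#' invariant under strictly monotone transformations of the output and
#' affine rescaling of the inputs.
#'
#' @param X `n x p` sample matrix (columns named by parameter).
#' @param y Numeric output vector, `length(y) == nrow(X)`, not constant.
#' @return Object of class `sensitivity_result`: data frame with columns
#'   `parameter`, `rho`, `k`, sorted by decreasing `k`.
#' @export
contribution_factors <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3L)
  if (stats::sd(y) == 0)
    stop("output is constant; variance attribution undefined")
  rho <- drop(stats::cor(X, y, method = "spearman"))
  k <- if (all(rho == 0)) rep(0, length(rho)) else rho^2 / sum(rho^2)
  out <- data.frame(
    parameter = colnames(X) %||% paste0("x", seq_along(rho)),
    rho = unname(rho), k = unname(k)
  )
  out <- out[order(-out$k), ]
  rownames(out) <- NULL
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sensitivity analysis: contribution factors\n")
  df <- as.data.frame(x)
  df$rho <- round(df$rho, 3)
  df$k <- round(df$k, 3)
  print(df)
  invisible(x)
}

#' Run a full Latin-hypercube sensitivity analysis
#'
#' Wires [lhs_sample()] through a user model to [contribution_factors()].
#'
#' @param model Function mapping a named parameter vector (one sample row)
#'   to a scalar model output (e.g. an annual emission quantity). Must be
#'   deterministic.
#' @param dists List of [parameter_distribution()].
#' @param n Sample count.
#' @param seed Integer seed.
#' @param method LHS placement, see [lhs_sample()].
#' @return A `sensitivity_result`; the full sample table (inputs plus
#'   output column `y`) is attached as attribute `samples` for audit.
#' @export
run_sensitivity <- function(model, dists, n, seed = 1L,
                            method = c("median", "random")) {
  X <- lhs_sample(dists, n, seed = seed, method = match.arg(method))
  y <- vapply(seq_len(nrow(X)), function(i) {
    out <- tryCatch(model(X[i, ]),
                    error = function(e) stop("model failed on sample row ", i,
                                             ": ", conditionMessage(e)))
    as.numeric(out)
  }, numeric(1))
  res <- contribution_factors(X, y)
  attr(res, "samples") <- cbind(as.data.frame(X), y = y)
  res
}
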