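#' Fit a one-dimensional Gaussian mixture by expectation-maximization
#'
#' Maximum-likelihood fit of a `k`-component univariate Gaussian mixture.
#' Each of `n_restarts` EM runs is initialized from a seeded k-means
#' partition; the run with the highest log-likelihood wins, so the result
#' is deterministic for a fixed seed.  `k = 1` is the closed-form ML fit
#' (mean and variance with denominator `n`).  BIC is
#' \eqn{p \ln n - 2 \ln \hat L} with \eqn{p = 3k - 1} free parameters
#' (k weights summing to 1, k means, k variances); lower is better.
#'
#' @param values Numeric vector; at least `10 * k` observations.
#' @param k Number of components, 1 to 3.
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of EM restarts.
#' @param weight_floor Validity rule: the fit is flagged `valid` only if
#'   every component weight is at least this value.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per restart.
#' @return A list of class `omi_gmm`: `k`, `weights`, `means`,
#'   `variances` (components sorted by mean), `loglik`, `bic`, `valid`,
#'   `n`, `seed`.
#' @export
fit_gmm <- function(values, k, seed = 1, n_restarts = 10,
                    weight_floor = 0.1, tol = 1e-6, max_iter = 500) {
  values <- as.numeric(values)
  n <- length(values)
  if (!k %in% 1:3) stop("'k' must be 1, 2 or 3")
  if (n < 10 * k)
    stop(sprintf("need at least %d values to fit %d components", 10 * k, k))
  var_floor <- 1e-9 * stats::var(values)
  if (!is.finite(var_floor) || var_floor <= 0) var_floor <- 1e-12

  if (k == 1) {
    mu <- mean(values)
    v <- max(mean((values - mu)^2), var_floor)
    ll <- sum(stats::dnorm(values, mu, sqrt(v), log = TRUE))
    return(gmm_result(1, 1, mu, v, ll, n, weight_floor, seed))
  }

  best <- NULL
  floored <- FALSE
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    km <- tryCatch(stats::kmeans(values, centers = k, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) next
    w <- as.numeric(table(factor(km$cluster, levels = 1:k))) / n
    mu <- as.numeric(km$centers)
    v <- vapply(1:k, function(j) {
      xj <- values[km$cluster == j]
      max(if (length(xj) > 1) mean((xj - mean(xj))^2) else 0, var_floor)
    }, numeric(1))
    w[w == 0] <- 1e-6; w <- w / sum(w)

    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(1:k, function(j)
        w[j] * stats::dnorm(values, mu[j], sqrt(v[j])), numeric(n))
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
      ll <- sum(log(rowsum_d))
      resp <- dens / rowsum_d
      nk <- colSums(resp)
      nk[nk == 0] <- .Machine$double.xmin
      w <- nk / n
      mu <- colSums(resp * values) / nk
      v <- vapply(1:k, function(j)
        sum(resp[, j] * (values - mu[j])^2) / nk[j], numeric(1))
      if (any(v < var_floor)) { v <- pmax(v, var_floor); floored <- TRUE }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(w = w, mu = mu, v = v, ll = ll)
  }
  if (is.null(best)) stop("all EM restarts failed")
  if (floored)
    message("variance floor applied during EM (degenerate component)")
  ord <- order(best$mu)
  gmm_result(k, best$w[ord], best$mu[ord], best$v[ord], best$ll, n,
             weight_floor, seed)
}

gmm_result <- function(k, w, mu, v, ll, n, weight_floor, seed) {
  p <- 3 * k - 1
  structure(list(k = k, weights = w, means = mu, variances = v,
                 loglik = ll, bic = p * log(n) - 2 * ll,
                 valid = min(w) >= weight_floor, n = n, seed = seed),
            class = "omi_gmm")
}

#' @export
print.omi_gmm <- function(x, ...) {
  cat(sprintf("<omi_gmm> k=%d  BIC=%.2f  valid=%s\n", x$k, x$bic, x$valid))
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  invisible(x)
}

#' Select a Gaussian mixture by the weight-floor rule and lowest BIC
#'
#' Fits mixtures with 1 to `k_max` components, discards fits in which any
#' component weight falls below `weight_floor` (such minor components are
#' treated as over-fitting), and returns the valid fit with the lowest
#' BIC.  A single-component fit has weight 1 and is always valid, so
#' selection never fails; BIC ties break towards fewer components.
#'
#' @param values Numeric vector of single-cell measurements.
#' @param k_max Maximum number of components (default 3).
#' @param weight_floor Minimum admissible component weight (default 0.1).
#' @param seed,n_restarts Passed to [fit_gmm()].
#' @return The selected `omi_gmm`; attribute `"bic_table"` holds the BIC
#'   and validity of every candidate `k`.
#' @export
select_gmm <- function(values, k_max = 3, weight_floor = 0.1, seed = 1,
                       n_restarts = 10) {
  ks <- 1:k_max
  ks <- ks[10 * ks <= length(values)]
  fits <- lapply(ks, function(k)
    fit_gmm(values, k, seed = seed, n_restarts = n_restarts,
            weight_floor = weight_floor))
  tab <- data.frame(k = ks,
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    valid = vapply(fits, `[[`, logical(1), "valid"))
  cand <- which(tab$valid)
  best <- cand[order(tab$bic[cand], tab$k[cand])][1]
  out <- fits[[best]]
  attr(out, "bic_table") <- tab
  out
}

#' Weighted entropy-distance heterogeneity index
#'
#' Quantifies sub-population structure of a single-cell variable from a
#' fitted Gaussian mixture.  Each component contributes its weight
#' entropy \eqn{-w_i \ln w_i} scaled by the distance of its mean from the
#' overall mixture mean \eqn{\bar\mu = \sum_i w_i \mu_i}:
#' \deqn{H = \sum_{i=1}^{k} -w_i \ln w_i \, |\mu_i - \bar\mu|.}
#' `H` is zero for a single component (or coincident means) and carries
#' the units of the input variable, so the unit convention (ps vs ns for
#' lifetimes) must be stated alongside any reported value.
#'
#' @param fit An `omi_gmm` (typically from [select_gmm()]).
#' @param units Unit label recorded in the result.
#' @return A list of class `omi_heterogeneity`: `H`, `mu_bar`, `fit`,
#'   `n`, `units`.
#' @examples
#' g <- list(k = 2, weights = c(.5, .5), means = c(0, 2),
#'           variances = c(1, 1), n = 100)
#' class(g) <- "omi_gmm"
#' heterogeneity_index(g)$H  # ln 2
#' @export
heterogeneity_index <- function(fit, units = "ps") {
  w <- fit$weights; mu <- fit$means
  mu_bar <- sum(w * mu)
  ent <- ifelse(w > 0, -w * log(w), 0)
  H <- sum(ent * abs(mu - mu_bar))
  structure(list(H = H, mu_bar = mu_bar, fit = fit, n = fit$n,
                 units = units),
            class = "omi_heterogeneity")
}

#' @export
print.omi_heterogeneity <- function(x, ...) {
  cat(sprintf("<omi_heterogeneity> H = %.4g %s (k = %d, n = %d)\n",
              x$H, x$units, x$fit$k, x$n))
  invisible(x)
}

#' One-call heterogeneity analysis of a single-cell variable
#'
#' Convenience wrapper: [select_gmm()] followed by
#' [heterogeneity_index()].
#'
#' @inheritParams select_gmm
#' @inheritParams heterogeneity_index
#' @return An `omi_heterogeneity`.
#' @export
heterogeneity <- function(values, k_max = 3, weight_floor = 0.1, seed = 1,
                          n_restarts = 10, units = "ps") {
  heterogeneity_index(select_gmm(values, k_max, weight_floor, seed,
                                 n_restarts), units = units)
}
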