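#' Covariance matrix adaptation evolution strategy
#'
#' A compact (mu/mu_w, lambda)-CMA-ES minimiser with rank-one and rank-mu
#' covariance updates and cumulative step-size adaptation, following the
#' standard tutorial parameterisation. Box constraints are handled by
#' penalised projection: out-of-bounds candidates are evaluated at their
#' projection with a quadratic distance penalty.
#'
#' @param fn objective function of a numeric vector; must return a finite
#'   scalar (non-finite values are treated as very poor candidates).
#' @param x0 initial mean.
#' @param sigma0 initial step size.
#' @param lower,upper box bounds (recycled to \code{length(x0)}).
#' @param lambda population size; default \code{4 + floor(3 log n)}.
#' @param max_gen maximum generations.
#' @param tol_fun stop when the best objective over the last
#'   \code{stall_gen} generations improves by less than this.
#' @param stall_gen window for the stagnation test.
#' @param stop_fitness stop as soon as the best objective falls to or below
#'   this value (default \code{-Inf}: never).
#' @param seed RNG seed.
#' @return List with \code{par} (best point found), \code{value},
#'   \code{n_eval}, \code{generations}, \code{converged}.
#' @export
cma_es <- function(fn, x0, sigma0 = 1, lower = -Inf, upper = Inf,
                   lambda = NULL, max_gen = 200, tol_fun = 1e-10,
                   stall_gen = 25, stop_fitness = -Inf, seed = 0) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mueff <- 1 / sum(wts^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  old <- .save_seed(seed)
  on.exit(.restore_seed(old))

  xmean <- pmin(upper, pmax(lower, as.numeric(x0)))
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); invsqrtC <- diag(n)
  best_x <- xmean; best_f <- Inf
  n_eval <- 0L
  hist_best <- numeric(0)
  eval_pen <- function(x) {
    xp <- pmin(upper, pmax(lower, x))
    f <- fn(xp)
    if (!is.finite(f)) f <- 1e300
    n_eval <<- n_eval + 1L
    list(f = f + 1e4 * sum((x - xp)^2), fraw = f, xp = xp)
  }
  converged <- FALSE
  g <- 0L
  while (g < max_gen) {
    g <- g + 1L
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    invsqrtC <- B %*% diag(1 / D, n) %*% t(B)
    Y <- B %*% (D * Z)                      # C^{1/2} z
    X <- xmean + sigma * Y
    evals <- apply(X, 2, eval_pen)
    f <- vapply(evals, `[[`, numeric(1), "f")
    ord <- order(f)
    for (k in ord[seq_len(min(3, lambda))]) {
      if (evals[[k]]$fraw < best_f) {
        best_f <- evals[[k]]$fraw; best_x <- evals[[k]]$xp
      }
    }
    sel <- ord[seq_len(mu)]
    yw <- drop(Y[, sel, drop = FALSE] %*% wts)
    xmean <- xmean + sigma * yw
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    artmp <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (wts * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    hist_best <- c(hist_best, min(f))
    if (best_f <= stop_fitness) { converged <- TRUE; break }
    if (g >= stall_gen) {
      recent <- hist_best[(g - stall_gen + 1):g]
      if (max(recent) - min(recent) < tol_fun) { converged <- TRUE; break }
    }
    if (!is.finite(sigma) || sigma < 1e-12) { converged <- TRUE; break }
  }
  list(par = best_x, value = best_f, n_eval = n_eval, generations = g,
       converged = converged)
}
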