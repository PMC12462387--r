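# Gradient-free minimization over a box via Gaussian-process Bayesian
# optimization: Matern-5/2 kernel on inputs normalized to the unit box,
# standardized observations, expected-improvement acquisition over a
# seeded candidate set. Small-n (tens of evaluations) by design -- the
# objective here is a full pipeline run, not the GP algebra.

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r * r / 3) * exp(-r)
}

pairwise_dist <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# fit a zero-mean unit-variance GP on standardized y; lengthscale chosen
# from a small grid by marginal likelihood
gp_fit <- function(X, y) {
  n <- nrow(X)
  my <- mean(y)
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy < 1e-12) sy <- 1
  ys <- (y - my) / sy
  D <- pairwise_dist(X, X)
  best <- NULL
  for (ell in c(0.1, 0.2, 0.3, 0.5, 1.0)) {
    K <- matern52(D, ell)
    diag(K) <- diag(K) + 1e-6
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) next
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ell = ell, L = L, alpha = alpha)
    }
  }
  if (is.null(best)) return(NULL)
  list(X = X, my = my, sy = sy, ell = best$ell, L = best$L, alpha = best$alpha)
}

gp_predict <- function(fit, Xnew) {
  Ks <- matern52(pairwise_dist(Xnew, fit$X), fit$ell)
  mu <- as.vector(Ks %*% fit$alpha)
  V <- forwardsolve(t(fit$L), t(Ks))
  s2 <- pmax(1 + 1e-6 - colSums(V * V), 1e-12)
  list(mu = mu * fit$sy + fit$my, sd = sqrt(s2) * fit$sy)
}

expected_improvement <- function(mu, sd, fmin) {
  u <- (fmin - mu) / sd
  (fmin - mu) * stats::pnorm(u) + sd * stats::dnorm(u)
}

#' Bayesian minimization of a black-box objective over a box
#'
#' Starts from a seeded Latin-hypercube design of \code{max(5, d + 1)}
#' points, then alternates GP fitting and expected-improvement candidate
#' selection. Objective evaluations that throw are recorded as +Inf and
#' the search continues; the GP sees them imputed at the worst finite
#' value. Deterministic given \code{seed}. Dimensions with
#' \code{lower == upper} are held fixed.
#'
#' @param objective function taking a named numeric vector, returning a
#'   scalar.
#' @param lower,upper named numeric bounds of the box.
#' @param n_evals total objective evaluations (>= 2 * dimension advised).
#' @param seed integer seed.
#' @param init_points optional matrix (rows = points in original
#'   coordinates) evaluated first, counted against \code{n_evals}; used by
#'   the ADMM loop to warm-start from the previous incumbent.
#' @return list(best_x, best_y, records) where records is a data.frame of
#'   iteration index, objective value and coordinates.
#' @export
bo_minimize <- function(objective, lower, upper, n_evals, seed,
                        init_points = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, n_evals >= 1)
  nms <- names(lower) %||% paste0("x", seq_len(d))
  free <- which(upper - lower > 1e-12)
  width <- upper - lower

  denorm <- function(U) {
    # U: m x length(free) in [0,1] -> full coordinates
    m <- nrow(U)
    X <- matrix(rep(lower, each = m), nrow = m, dimnames = list(NULL, nms))
    if (length(free)) {
      X[, free] <- U * matrix(rep(width[free], each = m), nrow = m) +
        matrix(rep(lower[free], each = m), nrow = m)
    }
    X
  }
  norm01 <- function(X) {
    m <- nrow(X)
    if (!length(free)) return(matrix(0, nrow = m, ncol = 0))
    (X[, free, drop = FALSE] - matrix(rep(lower[free], each = m), nrow = m)) /
      matrix(rep(width[free], each = m), nrow = m)
  }
  eval1 <- function(x) {
    x <- stats::setNames(as.numeric(x), nms)
    v <- tryCatch(as.numeric(objective(x)), error = function(e) Inf)
    if (length(v) != 1L || is.na(v)) Inf else v
  }

  with_seed(seed, {
    df <- length(free)
    if (df == 0L) {
      x0 <- stats::setNames(as.numeric(lower), nms)
      y0 <- eval1(x0)
      if (!is.finite(y0)) stop("objective failed at the only feasible point")
      rec <- data.frame(iter = 1L, value = y0)
      return(list(best_x = x0, best_y = y0,
                  records = cbind(rec, as.data.frame(t(x0)))))
    }
    n_init <- min(max(5L, df + 1L), n_evals)
    U <- lhs::randomLHS(n_init, df)
    X <- denorm(U)
    if (!is.null(init_points)) {
      ip <- matrix(init_points, ncol = d)
      colnames(ip) <- nms
      ip <- pmin(pmax(ip, matrix(rep(lower, each = nrow(ip)), nrow = nrow(ip))),
                 matrix(rep(upper, each = nrow(ip)), nrow = nrow(ip)))
      X <- rbind(ip, X)
      X <- X[seq_len(min(nrow(X), n_evals)), , drop = FALSE]
    }
    y <- apply(X, 1, eval1)

    while (length(y) < n_evals) {
      yf <- y
      if (any(!is.finite(yf))) {
        worst <- if (any(is.finite(yf))) max(yf[is.finite(yf)]) else NA
        if (is.na(worst)) {
          if (length(y) == n_evals) break
          # all failed so far: keep sampling space-filling points
          Xc <- denorm(matrix(stats::runif(df), ncol = df))
          y <- c(y, eval1(Xc[1, ])); X <- rbind(X, Xc)
          next
        }
        pen <- worst + max(stats::sd(yf[is.finite(yf)]), 1e-3)
        yf[!is.finite(yf)] <- pen
      }
      fit <- gp_fit(norm01(X), yf)
      # candidates: global uniform + local Gaussian around the incumbent
      Ug <- matrix(stats::runif(128 * df), ncol = df)
      inc <- norm01(X[which.min(yf), , drop = FALSE])
      Ul <- matrix(stats::rnorm(32 * df, mean = rep(as.numeric(inc), each = 32),
                                sd = 0.08), ncol = df)
      Uc <- rbind(Ug, pmin(pmax(Ul, 0), 1))
      if (is.null(fit)) {
        pick <- Uc[1, , drop = FALSE]
      } else {
        pr <- gp_predict(fit, Uc)
        ei <- expected_improvement(pr$mu, pr$sd, min(yf))
        pick <- Uc[which.max(ei), , drop = FALSE]
      }
      xn <- denorm(pick)
      y <- c(y, eval1(xn[1, ]))
      X <- rbind(X, xn)
    }
    if (all(!is.finite(y))) stop("objective failed at every evaluated point")
    best <- which.min(replace(y, !is.finite(y), Inf))
    records <- cbind(data.frame(iter = seq_along(y), value = y),
                     as.data.frame(X))
    list(best_x = stats::setNames(as.numeric(X[best, ]), nms),
         best_y = y[best], records = records)
  })
}

#' Exact minimization over a finite point set (test oracle)
#'
#' @param objective function of a named numeric vector.
#' @param points matrix or data.frame, one point per row.
#' @return list(best_x, best_y) with first-occurrence tie-breaking.
#' @export
exhaustive_minimize <- function(objective, points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  vals <- apply(points, 1, function(x) as.numeric(objective(x)))
  i <- which.min(vals)  # which.min returns the first minimum
  list(best_x = points[i, ], best_y = vals[i])
}
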