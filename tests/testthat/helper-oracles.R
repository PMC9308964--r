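# Independent numerical oracles used by the tests. These deliberately avoid
# the package's own code paths.

# Discretized quadratic-program oracle for the equal-area spline: minimize
# (1/m) sum_k (mean of f over layer k - y_k)^2 + lambda * sum (df/dd)^2 * h
# over a free discrete function f on a fine grid, by solving the normal
# equations. Returns a function of depth (nearest-node lookup).
qpSplineOracle <- function(profile, lambda, h = 0.05) {
  p <- profile[order(profile$top), ]
  lo <- min(p$top); hi <- max(p$bottom)
  centers <- seq(lo + h / 2, hi - h / 2, by = h)
  n <- length(centers)
  m <- nrow(p)
  M <- matrix(0, m, n)
  for (k in seq_len(m)) {
    inLayer <- centers > p$top[k] & centers < p$bottom[k]
    M[k, inLayer] <- 1 / sum(inLayer)
  }
  # first-difference penalty: integral of f'^2 ~ sum (diff(f)/h)^2 * h
  D <- diff(diag(n))
  H <- 2 * crossprod(M) / m + 2 * lambda * crossprod(D) / h + diag(1e-10, n)
  b <- 2 * crossprod(M, p$value) / m
  f <- solve(H, b)
  function(d) approx(centers, f, xout = d, rule = 2)$y
}

# Exact interventional Shapley values by enumeration over all 2^p coalitions.
# f takes a data.frame and returns a numeric vector (one value per row).
exactShapley <- function(f, instance, background, features) {
  p <- length(features)
  vcache <- new.env()
  value <- function(S) {
    key <- paste0("S", paste(S, collapse = ","))
    if (!is.null(vcache[[key]])) return(vcache[[key]])
    df <- background
    for (j in S) df[[features[j]]] <- instance[[features[j]]]
    v <- mean(f(df))
    vcache[[key]] <- v
    v
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(mask) which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      s <- length(S)
      wt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[i] <- phi[i] + wt * (value(sort(c(S, i))) - value(S))
    }
  }
  names(phi) <- features
  phi
}

# brute-force minimizer of the mean pinball loss over constant predictions:
# evaluates the loss at every observed value and returns the argmin
bruteForceQuantile <- function(y, tau) {
  losses <- vapply(y, function(c) mean(pmax(tau * (y - c), (tau - 1) * (y - c))),
                   numeric(1))
  y[which.min(losses)]
}
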