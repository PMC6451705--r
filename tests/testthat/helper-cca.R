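# Derivative-free oracle for the first canonical correlation: random
# restarts of Nelder-Mead maximising |cor(X a, Y b)|.
optimizer_cca_r <- function(X, Y, restarts = 25) {
  X <- scale(X)
  Y <- scale(Y)
  f <- function(par) {
    a <- par[seq_len(ncol(X))]
    b <- par[-seq_len(ncol(X))]
    cx <- drop(X %*% a)
    cy <- drop(Y %*% b)
    if (sd(cx) < 1e-12 || sd(cy) < 1e-12) return(0)
    -abs(cor(cx, cy))
  }
  best <- 0
  for (i in seq_len(restarts)) {
    o <- optim(rnorm(ncol(X) + ncol(Y)), f, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    best <- max(best, -o$value)
  }
  best
}

# standardized blocks with an exact one-factor canonical structure at
# population canonical correlation rho
factor_blocks <- function(n, p, q, rho) {
  u <- rnorm(n)
  e <- rho * u + sqrt(1 - rho^2) * rnorm(n)
  X <- cbind(u, matrix(rnorm(n * (p - 1)), n))
  Y <- cbind(e, matrix(rnorm(n * (q - 1)), n))
  list(X = X, Y = Y)
}
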