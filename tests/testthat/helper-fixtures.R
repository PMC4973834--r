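# Shared fixtures: tiny datasets built in code, plus the packaged examples.

apgar <- apgar_cutpoints()
mvd <- microvessel_density()

# three heterogeneous studies at one level, for 1-D REML oracle checks
toy_uni <- tibble::tibble(
  y = c(0.2, 1.1, 0.7),
  se = c(0.25, 0.40, 0.30)
)

# two complete 2-level studies with known within-study correlation
toy_bivariate <- function(rho = 0.4) {
  eff <- tibble::tibble(
    study_id = c("a", "a", "b", "b"),
    cutpoint = c(1, 2, 1, 2),
    y = c(0.5, 0.3, 0.9, 0.8),
    se = c(0.2, 0.25, 0.3, 0.35)
  )
  cors <- tibble::tibble(
    study_id = c("a", "b"), level_a = "1", level_b = "2", rho = rho
  )
  meta_dataset(eff, cors)
}

# dense, library-free evaluation of the restricted log-likelihood used as
# an independent oracle for mv_restricted_loglik: stacks all studies into
# one block-diagonal system and uses solve()/determinant() directly
dense_reml_loglik <- function(blocks, beta, omega) {
  d <- length(beta)
  Vs <- lapply(blocks, function(b) omega[b$idx, b$idx, drop = FALSE] + b$S)
  n <- sum(vapply(blocks, function(b) length(b$y), integer(1)))
  V <- matrix(0, n, n)
  X <- matrix(0, n, d)
  yv <- numeric(n)
  at <- 0L
  for (i in seq_along(blocks)) {
    di <- length(blocks[[i]]$y)
    rows <- at + seq_len(di)
    V[rows, rows] <- Vs[[i]]
    X[rows, ] <- diag(d)[blocks[[i]]$idx, , drop = FALSE]
    yv[rows] <- blocks[[i]]$y
    at <- at + di
  }
  Vi <- solve(V)
  r <- yv - X %*% beta
  XtViX <- t(X) %*% Vi %*% X
  -0.5 * ((n - d) * log(2 * pi) +
    as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
    drop(t(r) %*% Vi %*% r)) +
    0.5 * as.numeric(determinant(t(X) %*% X, logarithm = TRUE)$modulus)
}
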