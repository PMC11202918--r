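# Small exact t-SNE (quadratic cost), sufficient for the dozens of per-image
# mean spectra this package embeds. Perplexity calibration by bisection on
# the per-point Gaussian bandwidth; standard early exaggeration and momentum
# schedule.

tsne_exact <- function(X, perplexity = 10, seed = 1, n_iter = 400,
                       eta = 100) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D[i, -i]
    for (it in 1:50) {
      p <- exp(-Di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)

  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1
    mom <- if (iter <= 250) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain <- pmax(gain, 0.01)
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
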