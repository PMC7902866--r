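# Independent NIPALS-PLS1 reference (plain R), used as an oracle for the
# SIMPLS implementation: for a single response the two algorithms define the
# same sequence of latent models.
nipalsPls1 <- function(X, y, L) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- P <- matrix(0, ncol(X), L)
  qv <- numeric(L)
  for (a in seq_len(L)) {
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w); tt <- sum(t^2)
    p <- drop(crossprod(Xc, t)) / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - t * q
    W[, a] <- w; P[, a] <- p; qv[a] <- q
  }
  B <- W %*% solve(crossprod(P, W), qv)
  list(beta = drop(B), xMean = xm, yMean = ym,
       predict = function(Xn) drop(sweep(Xn, 2, xm) %*% B) + ym)
}
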