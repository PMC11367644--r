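# Independent oracles used to cross-check the package's implementations.
# They deliberately use different algorithms from the code under test.

# Horn's quaternion method for optimal rigid superposition RMSD: the
# largest eigenvalue of the 4x4 key matrix built from the covariance of
# the centred coordinate sets gives the optimal rotation directly.
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- t(A) %*% B
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lam)) / nrow(A))
}

# Brute-force stationary distribution of the explicit 3-state rate matrix
# (free domain <-> reporter complex, free domain <-> competitor complex),
# solved as the null space of the transposed generator with the
# normalisation constraint appended.
stationary_3state <- function(u1, w1, u2, w2) {
  Q <- matrix(0, 3, 3)        # states: 1 free, 2 reporter, 3 competitor
  Q[1, 2] <- u1; Q[2, 1] <- w1
  Q[1, 3] <- u2; Q[3, 1] <- w2
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 3))
  pi <- qr.solve(A, c(0, 0, 0, 1))
  c(P0 = pi[1], P1 = pi[2], P2 = pi[3])
}

# Uniform random rotation for invariance tests (independent of the
# package's random_rotation).
test_rotation <- function() {
  repeat {
    m <- matrix(rnorm(9), 3)
    q <- qr.Q(qr(m))
    if (det(q) > 0) return(q)
  }
}
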