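# Independent oracles used across the suite. These deliberately use
# different algorithms / code paths than the package implementation.

# Two-tailed binomial P value via the exact cumulative distribution
# (stats::pbinom), independent of the package's log-space term summation.
oracle_binom_two_tailed <- function(x, n, ep, cap = TRUE) {
  r <- x / n
  if (r == ep) return(1)
  p <- if (r < ep) 2 * pbinom(x, n, ep) else 2 * pbinom(x - 1, n, ep, lower.tail = FALSE)
  if (cap) min(p, 1) else p
}

# Horn's quaternion method for optimal rigid-body superposition: the best
# rotation is the eigenvector of a 4x4 matrix built from the cross-dispersion.
oracle_quaternion_superpose <- function(moving, reference) {
  mc <- sweep(moving, 2, colMeans(moving))
  rc <- sweep(reference, 2, colMeans(reference))
  m <- crossprod(mc, rc)  # sum over points of p q^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sweep(mc %*% t(rot), 2, colMeans(reference), "+")
}

# Cyclic Jacobi eigenvalue sweeps for a symmetric matrix.
oracle_jacobi_eigenvalues <- function(a, tol = 1e-12, max_sweeps = 100) {
  a <- as.matrix(a)
  n <- nrow(a)
  for (sweep_i in seq_len(max_sweeps)) {
    off <- sqrt(sum(a[upper.tri(a)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        if (abs(a[p, q]) < tol / n) next
        theta <- (a[q, q] - a[p, p]) / (2 * a[p, q])
        t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
        if (theta == 0) t <- 1
        cs <- 1 / sqrt(t^2 + 1)
        sn <- t * cs
        g <- a[, p]; h <- a[, q]
        a[, p] <- cs * g - sn * h
        a[, q] <- sn * g + cs * h
        g <- a[p, ]; h <- a[q, ]
        a[p, ] <- cs * g - sn * h
        a[q, ] <- sn * g + cs * h
      }
    }
  }
  sort(diag(a), decreasing = TRUE)
}

# Small synthetic kinase family shared by annotation/enrichment tests.
make_test_family <- function(n_kinases = 8, n_snps = 200, seed = 77, ...) {
  spec <- snp_sim_spec(n_kinases = n_kinases, n_snps = n_snps, seed = seed, ...)
  fam <- simulate_kinase_family(spec)
  list(spec = spec, fam = fam)
}
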