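# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: double/triple loops, svd-based pseudo-inverse,
# power iteration.

# Brute-force Kirchhoff matrix by explicit double loop.
oracle_kirchhoff <- function(xyz, cutoff) {
  n <- nrow(xyz)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        k[i, j] <- -1
      }
    }
  }
  diag(k) <- -rowSums(k)
  k
}

# Moore-Penrose pseudo-inverse via SVD (independent of eigen()).
oracle_pinv <- function(m, tol = 1e-8) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Dominant eigenvector by power iteration (independent of eigen()).
oracle_power_vector <- function(m, iters = 5000) {
  v <- rep(1, nrow(m)) + seq_len(nrow(m)) / nrow(m)
  for (i in seq_len(iters)) {
    v <- m %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(v)
}

# All residue triads by explicit O(n^3) loop.
oracle_triads <- function(xyz, resno, cutoff, min_sep) {
  n <- nrow(xyz)
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k &&
        d(i, j) <= cutoff && d(i, k) <= cutoff && d(j, k) <= cutoff &&
        abs(resno[i] - resno[j]) >= min_sep &&
        abs(resno[i] - resno[k]) >= min_sep &&
        abs(resno[j] - resno[k]) >= min_sep) {
      out <- rbind(out, sort(c(resno[i], resno[j], resno[k])))
    }
  }
  if (is.null(out)) out <- matrix(integer(), ncol = 3L)
  out[order(out[, 1L], out[, 2L], out[, 3L]), , drop = FALSE]
}

# Random rigid transformation of coordinates.
rigid_transform <- function(xyz, seed = 1) {
  set.seed(seed)
  qrres <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qrres)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- rnorm(3, sd = 20)
  sweep(xyz %*% rot, 2, -shift)
}

transform_chain <- function(chain, seed = 1) {
  chain$xyz <- rigid_transform(chain$xyz, seed)
  chain
}
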