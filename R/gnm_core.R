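#' @title Gaussian Network Model core
#' @name gnm_core
#' @description Build the Kirchhoff (connectivity) matrix of a C-alpha trace
#'   and work with its eigendecomposition: residue-fluctuation correlations
#'   and mean-square distance fluctuations, in full or per mode.
NULL

chain_xyz <- function(chain) {
  if (inherits(chain, "calpha_chain")) return(chain$xyz)
  if (is.matrix(chain) && ncol(chain) == 3L) return(chain)
  stop("expected a calpha_chain or an n x 3 coordinate matrix")
}

#' Build the GNM Kirchhoff matrix
#'
#' Off-diagonal entry (i, j) is -1 when the C-alpha distance r_ij is at most
#' \code{r_cutoff} (closed ball), 0 otherwise; the diagonal holds each
#' residue's contact count, so every row sums to zero. The matrix depends on
#' pairwise distances only and is therefore invariant under rigid motion.
#'
#' @param chain A \code{calpha_chain} or an n x 3 coordinate matrix.
#' @param r_cutoff Contact cutoff in Angstrom (> 0).
#' @return An n x n symmetric integer-valued matrix with residue numbers as
#'   dimnames when available.
#' @export
build_kirchhoff <- function(chain, r_cutoff) {
  stopifnot(is.numeric(r_cutoff), length(r_cutoff) == 1L, r_cutoff > 0)
  xyz <- chain_xyz(chain)
  n <- nrow(xyz)
  stopifnot(n >= 2L)
  d <- as.matrix(stats::dist(xyz))
  a <- (d <= r_cutoff) * 1
  diag(a) <- 0
  k <- diag(rowSums(a)) - a
  if (inherits(chain, "calpha_chain")) {
    dimnames(k) <- list(chain$resno, chain$resno)
  }
  k
}

#' Eigendecompose a Kirchhoff matrix into a GNM model
#'
#' Full spectrum sorted ascending with orthonormal eigenvectors; each
#' eigenvector's first component of magnitude above 1e-12 is made positive
#' so the decomposition is deterministic. Zero modes (eigenvalues below
#' 1e-8 of the largest in magnitude) are counted; a connected contact graph
#' has exactly one, with a uniform eigenvector. A degenerate largest
#' eigenvalue (within 1e-8 relative) triggers a warning because the fastest
#' mode is then basis-dependent.
#'
#' @param kirchhoff Symmetric n x n matrix (see \code{\link{build_kirchhoff}}).
#' @param gamma Positive spring-constant scale; eigenvalues are those of
#'   \code{gamma * kirchhoff}. Default 1.
#' @param chain Optional \code{calpha_chain} the matrix came from, carried
#'   along for reporting.
#' @param r_cutoff Optional cutoff used, carried along for reporting.
#' @return An object of class \code{gnm_model} with elements
#'   \code{kirchhoff}, \code{gamma}, \code{values} (ascending),
#'   \code{vectors} (columns, orthonormal), \code{n_zero_modes},
#'   \code{connected}, \code{resno}, \code{r_cutoff}.
#' @export
gnm_model <- function(kirchhoff, gamma = 1, chain = NULL, r_cutoff = NA_real_) {
  stopifnot(is.matrix(kirchhoff), nrow(kirchhoff) == ncol(kirchhoff),
            is.numeric(gamma), gamma > 0)
  if (!isSymmetric(unname(kirchhoff), tol = 1e-10)) {
    stop("kirchhoff matrix must be symmetric")
  }
  e <- eigen(gamma * kirchhoff, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  values <- e$values[idx]
  vectors <- e$vectors[, idx, drop = FALSE]
  # deterministic sign: first component with |v| > 1e-12 is positive
  for (k in seq_len(ncol(vectors))) {
    v <- vectors[, k]
    lead <- which(abs(v) > 1e-12)[1L]
    if (!is.na(lead) && v[lead] < 0) vectors[, k] <- -v
  }
  lam_max <- max(abs(values))
  tol <- 1e-8 * max(lam_max, 1)
  n_zero <- sum(abs(values) < tol)
  n <- length(values)
  if (n >= 2L && abs(values[n] - values[n - 1L]) <= 1e-8 * lam_max) {
    warning("largest eigenvalue is degenerate within 1e-8 relative; ",
            "the fastest mode is basis-dependent")
  }
  structure(list(
    kirchhoff = kirchhoff,
    gamma = gamma,
    values = values,
    vectors = vectors,
    n_zero_modes = n_zero,
    connected = n_zero == 1L,
    resno = if (!is.null(chain)) chain$resno else
      suppressWarnings(as.integer(rownames(kirchhoff))),
    r_cutoff = r_cutoff
  ), class = "gnm_model")
}

#' Build and decompose a GNM in one step
#'
#' @inheritParams build_kirchhoff
#' @param gamma Spring-constant scale (default 1).
#' @return A \code{gnm_model}.
#' @examples
#' ch <- toy_chain("helix", 25)
#' m <- gnm(ch, 7.0)
#' m$values[1:3]
#' @export
gnm <- function(chain, r_cutoff, gamma = 1) {
  gnm_model(build_kirchhoff(chain, r_cutoff), gamma = gamma,
            chain = if (inherits(chain, "calpha_chain")) chain else NULL,
            r_cutoff = r_cutoff)
}

#' @export
print.gnm_model <- function(x, ...) {
  n <- length(x$values)
  cat("GNM model: n = ", n, ", cutoff = ", x$r_cutoff, " A, gamma = ",
      x$gamma, "\n  eigenvalues in [", format(x$values[1L], digits = 3), ", ",
      format(x$values[n], digits = 3), "], zero modes: ", x$n_zero_modes,
      if (!x$connected) " (contact graph disconnected)" else "", "\n", sep = "")
  invisible(x)
}

nonzero_modes <- function(model) {
  n <- length(model$values)
  if (model$n_zero_modes >= n) return(integer(0))
  seq.int(model$n_zero_modes + 1L, n)
}

check_mode_subset <- function(model, mode_subset) {
  if (is.null(mode_subset)) return(nonzero_modes(model))
  stopifnot(all(mode_subset >= 1L), all(mode_subset <= length(model$values)))
  if (any(mode_subset <= model$n_zero_modes)) {
    stop("zero mode has no inverse")
  }
  as.integer(mode_subset)
}

#' Residue-fluctuation correlation matrix
#'
#' Sum over the selected nonzero modes of \code{scale / lambda_k * u_k u_k'}.
#' The thermal prefactor (3kT/gamma in physical units) is folded into the
#' single \code{scale} constant because every quantity derived downstream is
#' used through relative magnitudes only. With all nonzero modes this is the
#' Moore-Penrose pseudo-inverse of the Kirchhoff matrix (times \code{scale}).
#'
#' @param model A \code{gnm_model}.
#' @param mode_subset Optional integer vector of mode indices (ascending
#'   eigenvalue order, so \code{n} is the fastest). Must exclude zero modes.
#' @param scale Multiplicative constant standing in for 3kT/gamma, default 1.
#' @return n x n symmetric matrix.
#' @export
gnm_correlation <- function(model, mode_subset = NULL, scale = 1) {
  stopifnot(inherits(model, "gnm_model"))
  ks <- check_mode_subset(model, mode_subset)
  u <- model$vectors[, ks, drop = FALSE]
  w <- scale / model$values[ks]
  u %*% (w * t(u))
}

#' Mean-square distance fluctuation matrix
#'
#' Entry (i, j) is \code{C_ii + C_jj - 2 C_ij} where C is the correlation
#' matrix over the selected modes: the mean-square fluctuation of the i-j
#' inter-residue distance in the harmonic model. The diagonal is exactly
#' zero; over the full nonzero spectrum the matrix is entrywise nonnegative.
#'
#' @inheritParams gnm_correlation
#' @return n x n symmetric matrix with zero diagonal.
#' @export
distance_fluctuation <- function(model, mode_subset = NULL, scale = 1) {
  cmat <- gnm_correlation(model, mode_subset, scale)
  v <- diag(cmat)
  out <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * cmat
  diag(out) <- 0
  out
}
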