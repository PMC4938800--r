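#' Essential-dynamics PCA of Calpha fluctuations
#'
#' Eigendecomposes the (population) covariance of the centered Calpha
#' coordinates of a superposed ensemble. The first few principal components
#' span the "essential" subspace of large collective motions; the remaining
#' components describe local fluctuations. Eigenvectors carry a
#' deterministic sign convention (the largest-magnitude component of each
#' eigenvector is positive) so downstream results are reproducible.
#'
#' @param e superposed `ConformerEnsemble`.
#' @param selection residue keys to analyse (NULL = all Calpha).
#' @return object of class `pc_model`: `mean` (n_res x 3), `values`
#'   (eigenvalues, Angstrom^2, descending), `vectors` (orthonormal columns,
#'   length 3 n_res), `proj` (N x K projections, Angstrom), `keys`.
#' @export
fit_pca <- function(e, selection = NULL) {
  if (!e$superposed) stop("ensemble must be superposed before PCA")
  ca <- ensemble_ca(e)
  keep <- if (is.null(selection)) seq_along(ca$keys) else {
    if (is.data.frame(selection)) selection <- res_keys(selection)
    m <- match(selection, ca$keys)
    if (anyNA(m)) stop("selection residues not in ensemble")
    m
  }
  A <- ca$coords[, keep, , drop = FALSE]
  N <- dim(A)[1]
  L <- dim(A)[2]
  if (N <= 3 * L)
    warning(sprintf("only %d conformers for %d coordinates; spectrum tail ill-determined",
                    N, 3 * L))
  X <- cbind(A[, , 1], A[, , 2], A[, , 3]) # N x 3L, (x..., y..., z...)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / N
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(mean = cbind(mu[1:L], mu[L + 1:L], mu[2 * L + 1:L]),
                 values = vals, vectors = vecs, proj = Xc %*% vecs,
                 keys = ca$keys[keep], n = N),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d residues, %d conformers; lambda1-3 = %s A^2 (%.0f%% of total)\n",
              length(x$keys), x$n,
              paste(signif(x$values[1:min(3, length(x$values))], 3),
                    collapse = ", "),
              100 * sum(x$values[1:min(3, length(x$values))]) / max(sum(x$values), 1e-300)))
  invisible(x)
}

#' Eigenvalue spectrum normalized by a reference spectrum's total
#'
#' Relative amplitudes lambda_1..k divided by the summed eigenvalues of the
#' reference model (the convention used to compare flexibilities of
#' different molecules on one scale).
#'
#' @param m,reference `pc_model` objects.
#' @param k components to report.
#' @return numeric length k.
#' @export
normalized_spectrum <- function(m, reference, k = 10L) {
  if (k > length(m$values)) stop("k exceeds available PCs")
  tot <- sum(reference$values)
  if (tot <= 0) stop("reference spectrum sums to zero")
  m$values[seq_len(k)] / tot
}

#' Cumulative variance fraction per PC (anisotropy curve)
#' @param m a `pc_model`.
#' @return monotone nondecreasing vector ending at 1.
#' @export
cumulative_anisotropy <- function(m) {
  tot <- sum(m$values)
  if (tot <= 0) stop("spectrum sums to zero")
  cumsum(m$values) / tot
}

#' Pseudo-trajectory along a single principal component
#'
#' Conformers `mean + a * sqrt(lambda_k) * v_k` for each grid amplitude `a`
#' (in multiples of the PC's sd). Used to attribute angle fluctuations to
#' single PCs.
#'
#' @param m a `pc_model`.
#' @param k PC index (lambda_k must be > 0).
#' @param amplitudes numeric grid in multiples of sqrt(lambda_k).
#' @return object of class `pc_trajectory`: `coords` (M x n_res x 3),
#'   `keys`, `mean`, `k`, `amplitudes`.
#' @export
pc_trajectory <- function(m, k, amplitudes = seq(-2, 2, length.out = 21)) {
  if (k > length(m$values)) stop("k exceeds available PCs")
  if (m$values[k] <= 0) stop("lambda_k is zero; no motion along this PC")
  L <- length(m$keys)
  v <- m$vectors[, k]
  step <- sqrt(m$values[k])
  coords <- array(0, c(length(amplitudes), L, 3))
  for (i in seq_along(amplitudes)) {
    d <- amplitudes[i] * step * v
    coords[i, , ] <- m$mean + cbind(d[1:L], d[L + 1:L], d[2 * L + 1:L])
  }
  structure(list(coords = coords, keys = m$keys, mean = m$mean, k = k,
                 amplitudes = amplitudes),
            class = "pc_trajectory")
}

#' Gaussian-weighted amplitude grid for PC pseudo-trajectories
#'
#' Standard-normal quantiles at mid-probabilities, so that statistics taken
#' uniformly over the resulting [pc_trajectory()] conformers reproduce the
#' Gaussian fluctuation statistics of the PC (e.g. the angular sd measured
#' on the trajectory matches the sd the PC contributes in the ensemble).
#'
#' @param m grid points.
#' @return numeric vector of amplitudes (multiples of sqrt(lambda_k)).
#' @export
gaussian_amplitude_grid <- function(m = 33L) {
  stats::qnorm((seq_len(m) - 0.5) / m)
}

#' Conformer spread over an essential subspace
#'
#' sigma = sqrt(sum of the selected eigenvalues), converted to nm: the
#' combined SD of the statistically independent selected PCs about the
#' average structure. Uncertainty by bootstrap over conformers (resampling
#' the projections and recomputing the per-PC population variances).
#'
#' @param m a `pc_model`.
#' @param pcs PC indices (default 1:3).
#' @param n_boot bootstrap replicates (0 = no uncertainty).
#' @param seed bootstrap seed.
#' @return list(`sigma_nm`, `se_nm`).
#' @export
conformer_spread <- function(m, pcs = 1:3, n_boot = 0L, seed = 1L) {
  stopifnot(length(pcs) >= 1)
  sig <- sqrt(sum(m$values[pcs])) / 10
  se <- NA_real_
  if (n_boot > 0) {
    P <- m$proj[, pcs, drop = FALSE]
    N <- nrow(P)
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      sqrt(sum(apply(P[idx, , drop = FALSE], 2, function(x) mean((x - mean(x))^2)))) / 10
    }, 0))
    se <- sd(reps)
  }
  list(sigma_nm = sig, se_nm = se)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square Calpha fluctuation about the ensemble mean, Angstrom.
#' Identity: `RMSF^2 * 8 pi^2 / 3` equals the raw ensemble B-factor.
#'
#' @param e superposed `ConformerEnsemble`.
#' @return profile data.frame (`chain`, `resno`, `value` in Angstrom).
#' @export
rmsf_profile <- function(e) {
  if (!e$superposed) stop("ensemble must be superposed first")
  ca <- ensemble_ca(e)
  kk <- strsplit(ca$keys, ":", fixed = TRUE)
  data.frame(chain = vapply(kk, `[`, "", 1),
             resno = as.integer(vapply(kk, `[`, "", 2)),
             value = sqrt(residue_msf(ca$coords)),
             stringsAsFactors = FALSE)
}
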