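#' Normalized mutual information between two letter columns
#'
#' nMI = (I(i;j) - eps) / H(i,j): plug-in mutual information corrected for
#' finite-size bias (default eps = (B_i - 1)(B_j - 1) / (2 N ln 2) bits,
#' with B the observed letter counts) and normalized by the joint entropy,
#' clamped to \[0, 1\]. H(i,j) = 0 (both columns constant) is defined as 0.
#'
#' @param col_i,col_j equal-length integer/factor columns (one symbol per
#'   conformer).
#' @param correct_bias apply the finite-size correction.
#' @param normalize divide by the joint entropy (FALSE returns the
#'   bias-corrected MI in bits).
#' @return unitless value in \[0, 1\] (or bits when `normalize = FALSE`).
#' @export
nmi_pair <- function(col_i, col_j, correct_bias = TRUE, normalize = TRUE) {
  if (length(col_i) != length(col_j))
    stop("columns differ in length")
  N <- length(col_i)
  if (N < 2) stop("need at least 2 observations")
  ci <- as.integer(factor(col_i))
  cj <- as.integer(factor(col_j))
  Bi <- max(ci)
  Bj <- max(cj)
  joint <- tabulate(ci + (cj - 1L) * Bi, Bi * Bj) / N
  pi_ <- tabulate(ci, Bi) / N
  pj <- tabulate(cj, Bj) / N
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  Hij <- ent(joint)
  I <- ent(pi_) + ent(pj) - Hij
  if (correct_bias) I <- I - (Bi - 1) * (Bj - 1) / (2 * N * log(2))
  if (!normalize) return(max(I, 0))
  if (Hij == 0) return(0)
  min(max(I / Hij, 0), 1)
}

#' All-pairs nMI matrix over fragment positions
#'
#' @param ft `fragment_trajectory`.
#' @inheritParams nmi_pair
#' @return symmetric n_positions x n_positions matrix, zero diagonal.
#' @export
nmi_matrix <- function(ft, correct_bias = TRUE, normalize = TRUE) {
  W <- ncol(ft$letters)
  M <- matrix(0, W, W)
  for (a in seq_len(W - 1)) for (b in (a + 1):W) {
    M[a, b] <- M[b, a] <- nmi_pair(ft$letters[, a], ft$letters[, b],
                                   correct_bias, normalize)
  }
  M
}

# equal-occupancy (quantile) discretization of a continuous vector
discretize_equal_occupancy <- function(x, n_bins) {
  stopifnot(n_bins >= 1)
  if (n_bins == 1) return(rep(1L, length(x)))
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / length(x)))
}

#' nMI profile between fragment columns and a discretized PC projection
#'
#' The PC-k projections are discretized into equal-occupancy bins and the
#' nMI between every fragment column and the binned projection is returned.
#' High values mark hinges: positions whose local conformational state
#' tracks the collective motion.
#'
#' @param ft `fragment_trajectory`.
#' @param m `pc_model` built from the same ensemble (same N).
#' @param k PC index.
#' @param n_bins equal-occupancy bins (default 10).
#' @inheritParams nmi_pair
#' @return numeric profile, one value per fragment position.
#' @export
nmi_pc_profile <- function(ft, m, k, n_bins = 10L, correct_bias = TRUE) {
  if (nrow(ft$letters) != m$n)
    stop(sprintf("trajectory has %d conformers but PC model has %d",
                 nrow(ft$letters), m$n))
  bins <- discretize_equal_occupancy(m$proj[, k], n_bins)
  vapply(seq_len(ncol(ft$letters)), function(w)
    nmi_pair(ft$letters[, w], bins, correct_bias), 0)
}

#' Significance threshold for nMI values by conformer shuffling
#'
#' Permutes the conformer order of each fragment column independently
#' (destroying any real coupling to the projection while keeping the letter
#' composition) and returns the 95th percentile of the null nMI values.
#'
#' @param ft `fragment_trajectory`.
#' @param m `pc_model`.
#' @param k PC index.
#' @param n_shuffles shuffle replicates.
#' @param seed RNG seed (deterministic).
#' @param n_bins equal-occupancy bins.
#' @return numeric threshold.
#' @export
shuffle_null <- function(ft, m, k, n_shuffles = 200L, seed = 1L,
                         n_bins = 10L) {
  bins <- discretize_equal_occupancy(m$proj[, k], n_bins)
  N <- nrow(ft$letters)
  W <- ncol(ft$letters)
  null <- with_seed(seed, {
    vals <- matrix(0, n_shuffles, W)
    for (s in seq_len(n_shuffles)) for (w in seq_len(W))
      vals[s, w] <- nmi_pair(ft$letters[sample.int(N), w], bins)
    vals
  })
  as.numeric(quantile(null, 0.95, type = 7))
}

#' Build the mutual-information network of an encoded ensemble
#'
#' Bundles the all-pairs nMI matrix (entries below the shuffle-null
#' threshold zeroed), the per-PC nMI profiles, their composite, and the
#' eigenvector centrality of the thresholded matrix.
#'
#' @param ft `fragment_trajectory`.
#' @param m `pc_model` from the same ensemble.
#' @param pcs PCs for the nMI_PC profiles (default 1:3).
#' @param n_bins equal-occupancy bins for the projections.
#' @param n_shuffles shuffle replicates for the null threshold.
#' @param seed shuffle seed.
#' @return object of class `mi_network`: `matrix` (thresholded), `raw`
#'   (unthresholded), `profiles` (list per PC), `composite` (mean profile),
#'   `centrality`, `threshold`, `positions`, `n_bins`.
#' @export
mi_network <- function(ft, m, pcs = 1:3, n_bins = 10L, n_shuffles = 200L,
                       seed = 1L) {
  raw <- nmi_matrix(ft)
  thr <- shuffle_null(ft, m, pcs[1], n_shuffles = n_shuffles, seed = seed,
                      n_bins = n_bins)
  M <- raw
  M[M < thr] <- 0
  diag(M) <- 0
  profiles <- lapply(pcs, function(k) nmi_pc_profile(ft, m, k, n_bins))
  names(profiles) <- paste0("PC", pcs)
  composite <- Reduce(`+`, profiles) / length(profiles)
  cent <- tryCatch(eigenvector_centrality(M), error = function(e) NULL)
  structure(list(matrix = M, raw = raw, profiles = profiles,
                 composite = composite, centrality = cent,
                 threshold = thr, positions = ft$positions,
                 n_bins = n_bins),
            class = "mi_network")
}

#' Eigenvector centrality of an nMI matrix
#'
#' Principal eigenvector by power iteration (tolerance 1e-10), scaled so the
#' maximum entry is 1. Errors on an empty (all-zero) matrix.
#'
#' @param net `mi_network` or a nonnegative symmetric matrix.
#' @return nonnegative numeric vector, max 1.
#' @export
eigenvector_centrality <- function(net) {
  M <- if (inherits(net, "mi_network")) net$matrix else net
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (any(M < 0)) stop("matrix must be nonnegative")
  if (all(M == 0)) stop("empty network: no principal direction")
  v <- rep(1 / sqrt(nrow(M)), nrow(M))
  for (it in seq_len(10000)) {
    w <- as.numeric(M %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed to zero")
    w <- w / nw
    if (max(abs(w - v)) < 1e-10) {
      v <- w
      break
    }
    v <- w
  }
  v <- abs(v)
  v / max(v)
}

#' Top network edges above an nMI threshold
#'
#' @param net `mi_network` (or matrix).
#' @param threshold nMI cutoff (strictly greater).
#' @param chain_map optional character vector mapping each position to a
#'   chain/domain label (defaults to the positions' chains); edges are
#'   classified `intra` (same label) or `inter` (different).
#' @return data.frame (`pos_i`, `pos_j`, `key_i`, `key_j`, `nmi`, `class`)
#'   sorted by descending nMI.
#' @export
top_edges <- function(net, threshold = 0.15, chain_map = NULL) {
  M <- if (inherits(net, "mi_network")) net$raw else net
  pos <- if (inherits(net, "mi_network")) net$positions else
    data.frame(chain = "A", resno = seq_len(nrow(M)))
  if (is.null(chain_map)) chain_map <- pos$chain
  idx <- which(upper.tri(M) & M > threshold, arr.ind = TRUE)
  out <- data.frame(pos_i = idx[, 1], pos_j = idx[, 2],
                    key_i = res_keys(pos[idx[, 1], , drop = FALSE]),
                    key_j = res_keys(pos[idx[, 2], , drop = FALSE]),
                    nmi = M[idx],
                    class = ifelse(chain_map[idx[, 1]] == chain_map[idx[, 2]],
                                   "intra", "inter"),
                    stringsAsFactors = FALSE)
  out[order(-out$nmi), , drop = FALSE]
}

#' Pearson correlation between two profiles
#' @param p1,p2 equal-length numeric profiles.
#' @return Pearson r.
#' @export
profile_pcorr <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles differ in length")
  if (pop_sd(p1) == 0 || pop_sd(p2) == 0) stop("constant profile")
  cor(p1, p2)
}

#' Call network nodes (profile peaks)
#'
#' Local maxima of a profile with topographic prominence at least
#' `min_prominence` times the profile maximum. A peak's prominence is its
#' height above the higher of the two lowest points separating it from
#' higher ground on either side (profile ends count as ground level for the
#' outermost peaks).
#'
#' @param profile numeric profile (e.g. an nMI_PC profile).
#' @param min_prominence fraction of the profile maximum (default 0.2).
#' @param positions optional positions data.frame to attach residue keys.
#' @return data.frame (`index`, `value`, `prominence`, and `key` when
#'   positions are given).
#' @export
call_nodes <- function(profile, min_prominence = 0.2, positions = NULL) {
  n <- length(profile)
  # internal local maxima; a flat summit counts once, at its first index
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (profile[i] > profile[i - 1L]) {
      j <- i
      while (j < n && profile[j + 1L] == profile[i]) j <- j + 1L
      if (j < n && profile[j + 1L] < profile[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prominence <- vapply(peaks, function(i) {
    h <- profile[i]
    lmin <- h
    j <- i
    while (j > 1) {
      j <- j - 1
      if (profile[j] > h) break
      lmin <- min(lmin, profile[j])
    }
    if (j == 1 && profile[1] <= h) lmin <- min(lmin, profile[1])
    rmin <- h
    j <- i
    while (j < n) {
      j <- j + 1
      if (profile[j] > h) break
      rmin <- min(rmin, profile[j])
    }
    if (j == n && profile[n] <= h) rmin <- min(rmin, profile[n])
    h - max(lmin, rmin)
  }, 0)
  keep <- prominence >= min_prominence * max(profile)
  out <- data.frame(index = peaks[keep], value = profile[peaks[keep]],
                    prominence = prominence[keep])
  if (!is.null(positions) && nrow(out))
    out$key <- res_keys(positions[out$index, , drop = FALSE])
  out
}

#' Write a network edge list as TSV
#' @param edges [top_edges()] data.frame.
#' @param path output file.
#' @export
write_edges_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
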