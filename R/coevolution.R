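#' Paired inter-protein alignment
#'
#' Concatenated A|B alignment rows with the A/B boundary recorded, plus the
#' per-row organism id and genomic gene distance between the two genes.
#'
#' @param chars character matrix (rows = sequences, columns = aligned
#'   positions; `-` is the gap).
#' @param boundary last column belonging to protein A.
#' @param organisms per-row organism ids.
#' @param distances per-row gene distances (>= 0).
#' @param col_keys optional data.frame (`chain`, `resno`) mapping columns to
#'   structure residues.
#' @return object of class `paired_msa`.
#' @export
new_paired_msa <- function(chars, boundary, organisms = NULL,
                           distances = NULL, col_keys = NULL) {
  stopifnot(is.matrix(chars), boundary >= 1, boundary < ncol(chars))
  if (!is.null(distances) && any(distances < 0))
    stop("gene distances must be >= 0")
  structure(list(chars = chars, boundary = as.integer(boundary),
                 organisms = organisms %||% rep(NA_character_, nrow(chars)),
                 distances = distances %||% rep(NA_real_, nrow(chars)),
                 col_keys = col_keys),
            class = "paired_msa")
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf("paired_msa: %d sequences x %d columns (A = 1..%d, B = %d..%d)\n",
              nrow(x$chars), ncol(x$chars), x$boundary, x$boundary + 1,
              ncol(x$chars)))
  invisible(x)
}

# integer encoding; the gap (if present) is the last state
msa_states <- function(chars) {
  letters_ <- sort(setdiff(unique(as.vector(chars)), "-"))
  has_gap <- any(chars == "-")
  q <- length(letters_) + as.integer(has_gap)
  states <- matrix(match(chars, letters_, nomatch = q),
                   nrow(chars), ncol(chars))
  list(states = states, q = q, letters = letters_,
       gap_state = if (has_gap) q else 0L)
}

#' Redundancy filter at a sequence-identity level
#'
#' Greedy keep-first removal so that no retained pair of rows exceeds
#' `max_identity` (identity over columns where both rows are non-gap).
#' The output is a fixed point of the filter.
#'
#' @param msa `paired_msa` or character matrix.
#' @param max_identity identity fraction (default 0.8).
#' @return same type as the input, rows filtered; kept row indices in
#'   attribute `"kept"`.
#' @export
filter_redundancy <- function(msa, max_identity = 0.8) {
  chars <- if (inherits(msa, "paired_msa")) msa$chars else msa
  st <- msa_states(chars)
  keep <- cpp_filter_redundancy(st$states, max_identity, st$gap_state)
  if (inherits(msa, "paired_msa")) {
    out <- new_paired_msa(chars[keep, , drop = FALSE], msa$boundary,
                          msa$organisms[keep], msa$distances[keep],
                          msa$col_keys)
  } else {
    out <- chars[keep, , drop = FALSE]
  }
  attr(out, "kept") <- which(keep)
  out
}

#' Pair A and B family sequences by organism and genomic proximity
#'
#' Within each organism, A and B sequences are paired with the smallest
#' genomic gene distance (greedily by default; exhaustive minimum-weight
#' matching for up to 10 paralogs per organism), each sequence used at most
#' once; candidate pairs at `>= max_gene_distance` genes are discarded.
#' Organisms without any admissible pair are skipped and logged.
#'
#' @param msa_a,msa_b character matrices (rows named by sequence id).
#' @param metadata data.frame (`seq_id`, `organism`, `locus`) covering all
#'   rows of both alignments.
#' @param max_gene_distance discard pairs at this distance or more
#'   (default 100).
#' @param method `"greedy"` or `"exhaustive"`.
#' @return `paired_msa`; skipped organisms in attribute `"skipped"`.
#' @export
pair_sequences <- function(msa_a, msa_b, metadata, max_gene_distance = 100L,
                           method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  ids_a <- rownames(msa_a) %||% stop("msa_a needs sequence-id rownames")
  ids_b <- rownames(msa_b) %||% stop("msa_b needs sequence-id rownames")
  miss <- setdiff(c(ids_a, ids_b), metadata$seq_id)
  if (length(miss))
    stop("metadata lacks sequence(s): ", paste(head(miss, 5), collapse = ", "))
  meta <- metadata[match(c(ids_a, ids_b), metadata$seq_id), ]
  ma <- meta[seq_along(ids_a), ]
  mb <- meta[length(ids_a) + seq_along(ids_b), ]

  rows <- list()
  orgs <- character(0)
  dists <- numeric(0)
  skipped <- character(0)
  for (org in unique(ma$organism)) {
    ia <- which(ma$organism == org)
    ib <- which(mb$organism == org)
    if (!length(ia) || !length(ib)) {
      skipped <- c(skipped, org)
      next
    }
    D <- abs(outer(ma$locus[ia], mb$locus[ib], "-"))
    D[D >= max_gene_distance] <- NA
    sel <- if (method == "exhaustive" && length(ia) <= 10 && length(ib) <= 10)
      min_weight_matching(D) else greedy_matching(D)
    if (!nrow(sel)) {
      skipped <- c(skipped, org)
      next
    }
    for (r in seq_len(nrow(sel))) {
      rows[[length(rows) + 1L]] <- c(msa_a[ia[sel[r, 1]], ],
                                     msa_b[ib[sel[r, 2]], ])
      orgs <- c(orgs, org)
      dists <- c(dists, D[sel[r, 1], sel[r, 2]])
    }
  }
  if (!length(rows)) stop("no organism yielded an admissible pair")
  out <- new_paired_msa(do.call(rbind, rows), boundary = ncol(msa_a),
                        organisms = orgs, distances = dists)
  attr(out, "skipped") <- skipped
  out
}

# greedy minimum-distance matching on a distance matrix with NAs
greedy_matching <- function(D) {
  sel <- matrix(integer(0), 0, 2)
  while (any(is.finite(D))) {
    k <- arrayInd(which.min(D), dim(D))
    sel <- rbind(sel, k)
    D[k[1], ] <- NA
    D[, k[2]] <- NA
  }
  sel
}

# exhaustive minimum-total-distance matching (small instances only)
min_weight_matching <- function(D) {
  na <- nrow(D)
  nb <- ncol(D)
  best <- NULL
  best_w <- Inf
  best_n <- 0L
  recurse <- function(a, used_b, pairs, w) {
    if (a > na) {
      n <- nrow(pairs)
      if (n > best_n || (n == best_n && w < best_w)) {
        best <<- pairs
        best_w <<- w
        best_n <<- n
      }
      return()
    }
    recurse(a + 1L, used_b, pairs, w) # leave a unmatched
    for (b in seq_len(nb)) {
      if (!used_b[b] && is.finite(D[a, b])) {
        used_b[b] <- TRUE
        recurse(a + 1L, used_b, rbind(pairs, c(a, b)), w + D[a, b])
        used_b[b] <- FALSE
      }
    }
  }
  recurse(1L, logical(nb), matrix(integer(0), 0, 2), 0)
  best %||% matrix(integer(0), 0, 2)
}

# weighted single and pair frequencies with pseudocount (mean-field DCA
# conventions: fi = pc/q + (1-pc) f^, fij = pc/q^2 + (1-pc) f^ for i != j,
# and the i = j block diagonal with fi so C_ii = diag(fi) - fi fi^T)
msa_frequencies <- function(states, q, weights, pseudocount) {
  L <- ncol(states)
  Meff <- sum(weights)
  w <- weights / Meff
  fhat <- function(col) {
    v <- numeric(q)
    s <- rowsum(w, col)
    v[as.integer(rownames(s))] <- s
    v
  }
  fi <- t(vapply(seq_len(L), function(i)
    pseudocount / q + (1 - pseudocount) * fhat(states[, i]), numeric(q)))
  fij <- array(0, c(L, L, q, q))
  for (i in seq_len(L)) fij[i, i, , ] <- diag(fi[i, ])
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    idx <- states[, i] + (states[, j] - 1L) * q
    JT <- matrix(0, q, q)
    s <- rowsum(w, idx)
    JT[as.integer(rownames(s))] <- s
    blk <- pseudocount / q^2 + (1 - pseudocount) * JT
    fij[i, j, , ] <- blk
    fij[j, i, , ] <- t(blk)
  }
  list(fi = fi, fij = fij, Meff = Meff)
}

# direct information of one pair from its mean-field coupling block
pair_di <- function(W, fi_i, fi_j, n_iter = 1000L) {
  q <- nrow(W)
  mu1 <- rep(1 / q, q)
  mu2 <- rep(1 / q, q)
  for (it in seq_len(n_iter)) {
    s1 <- as.numeric(W %*% mu2)
    s2 <- as.numeric(t(W) %*% mu1)
    n1 <- fi_i / s1
    n1 <- n1 / sum(n1)
    n2 <- fi_j / s2
    n2 <- n2 / sum(n2)
    if (max(abs(n1 - mu1), abs(n2 - mu2)) < 1e-12) {
      mu1 <- n1
      mu2 <- n2
      break
    }
    mu1 <- n1
    mu2 <- n2
  }
  Pdir <- W * outer(mu1, mu2)
  Pdir <- Pdir / sum(Pdir)
  prod_ <- outer(fi_i, fi_j)
  keep <- Pdir > 1e-15
  sum(Pdir[keep] * log(Pdir[keep] / prod_[keep]))
}

#' Mean-field direct coupling analysis of a paired alignment
#'
#' Sequence reweighting at the given identity cutoff, single/pair
#' frequencies with pseudocount, mean-field couplings by inversion of the
#' excess-correlation (connected correlation) matrix, and per-pair direct
#' information (DI) from each pair's two-site model. Inter-boundary pairs
#' (one position in A, one in B) are flagged for the inter-protein network.
#'
#' @param p `paired_msa`.
#' @param pseudocount pseudocount fraction (default 0.5).
#' @param seqid_reweight identity level for reweighting (default 0.8).
#' @return object of class `coupling_network`: `score` (L x L symmetric DI
#'   matrix, zero diagonal), `method = "DI"`, `boundary`, `meff`, `q`.
#' @export
mfdca <- function(p, pseudocount = 0.5, seqid_reweight = 0.8) {
  st <- msa_states(p$chars)
  states <- st$states
  q <- st$q
  L <- ncol(states)
  weights <- cpp_seq_weights(states, seqid_reweight)
  if (sum(weights) < 2) stop("fewer than 2 effective sequences")
  fr <- msa_frequencies(states, q, weights, pseudocount)
  qm <- q - 1L
  C <- matrix(0, L * qm, L * qm)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    block <- fr$fij[i, j, seq_len(qm), seq_len(qm)] -
      outer(fr$fi[i, seq_len(qm)], fr$fi[j, seq_len(qm)])
    C[(i - 1) * qm + seq_len(qm), (j - 1) * qm + seq_len(qm)] <- block
  }
  Jmf <- tryCatch(-solve(C), error = function(e)
    stop("correlation matrix is singular; increase the pseudocount"))
  score <- matrix(0, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    W <- matrix(1, q, q)
    W[seq_len(qm), seq_len(qm)] <-
      exp(Jmf[(i - 1) * qm + seq_len(qm), (j - 1) * qm + seq_len(qm)])
    di <- pair_di(W, fr$fi[i, ], fr$fi[j, ])
    score[i, j] <- score[j, i] <- di
  }
  structure(list(score = score, method = "DI", boundary = p$boundary,
                 meff = sum(weights), q = q),
            class = "coupling_network")
}

# average-product correction: S_ij = M_ij - (Mbar_i. Mbar_.j / Mbar_..),
# means taken excluding the diagonal
apc_correct <- function(M) {
  L <- nrow(M)
  grand <- mean(M[upper.tri(M)])
  if (grand == 0) return(M) # no signal anywhere: nothing to correct
  means <- rowSums(M) / (L - 1)
  S <- M - outer(means, means) / grand
  diag(S) <- 0
  S
}

#' APC-corrected mutual information of a paired alignment
#'
#' Column-pair plug-in mutual information with the average-product
#' correction `APC_ij = MI_i. MI_.j / MI_..` subtracted, the standard
#' background removal for phylogenetic and entropic signal.
#'
#' @param p `paired_msa`.
#' @return `coupling_network` with `method = "APC_MI"`.
#' @export
apc_mi <- function(p) {
  st <- msa_states(p$chars)
  L <- ncol(st$states)
  M <- matrix(0, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    M[i, j] <- M[j, i] <- nmi_pair(st$states[, i], st$states[, j],
                                   correct_bias = FALSE, normalize = FALSE)
  }
  S <- apc_correct(M)
  structure(list(score = S, method = "APC_MI", boundary = p$boundary,
                 meff = nrow(p$chars), q = st$q),
            class = "coupling_network")
}

#' Top-fraction edge list of a coupling network
#'
#' The highest-scoring `ceiling(fraction * n_pairs)` position pairs, plus
#' the empirical upper-tail fractions at 2 and 3 SD of the score
#' distribution (for calibrating the cutoff choice).
#'
#' @param net `coupling_network`.
#' @param fraction fraction of all position pairs (default 0.015).
#' @return data.frame (`i`, `j`, `score`, `inter` = spans the A/B
#'   boundary), sorted descending; tail fractions in attribute `"tails"`.
#' @export
top_fraction <- function(net, fraction = 0.015) {
  L <- nrow(net$score)
  ut <- which(upper.tri(net$score), arr.ind = TRUE)
  sc <- net$score[ut]
  ord <- order(-sc)
  n_top <- min(ceiling(fraction * length(sc)), length(sc))
  take <- if (n_top >= 1) ord[seq_len(n_top)] else integer(0)
  out <- data.frame(i = ut[take, 1], j = ut[take, 2], score = sc[take],
                    inter = ut[take, 1] <= net$boundary &
                      ut[take, 2] > net$boundary)
  attr(out, "tails") <- c(two_sigma = mean(sc > mean(sc) + 2 * pop_sd(sc)),
                          three_sigma = mean(sc > mean(sc) + 3 * pop_sd(sc)))
  out
}

#' Coevolution significance threshold by within-column shuffling
#'
#' Shuffles each alignment column independently across rows (destroying
#' inter-column coupling, preserving composition) and returns the 95th
#' percentile of the null scores.
#'
#' @param p `paired_msa`.
#' @param scorer function(paired_msa) -> `coupling_network` (default
#'   [apc_mi()]; pass [mfdca()] for a DI null).
#' @param n_shuffles shuffle replicates.
#' @param seed RNG seed.
#' @return numeric threshold.
#' @export
msa_shuffle_null <- function(p, scorer = apc_mi, n_shuffles = 20L,
                             seed = 1L) {
  null <- with_seed(seed, {
    vals <- numeric(0)
    for (s in seq_len(n_shuffles)) {
      shuf <- apply(p$chars, 2, sample)
      np <- new_paired_msa(shuf, p$boundary)
      sc <- scorer(np)$score
      vals <- c(vals, sc[upper.tri(sc)])
    }
    vals
  })
  as.numeric(quantile(null, 0.95, type = 7))
}

#' Classify coevolved couplings against structure and the dynamic network
#'
#' Labels each top inter-boundary coupling `interface_contact` when the
#' minimum heavy-atom distance between the two residues in the structure is
#' below the cutoff, else `long_range`; long-range couplings are tested for
#' adjacency (within +/- 1 fragment position) to the dynamic-network nodes.
#'
#' @param cn `coupling_network`.
#' @param nodes called dynamic-network nodes ([call_nodes()] output with
#'   `key`), or NULL.
#' @param s `Structure`.
#' @param col_keys data.frame (`chain`, `resno`) mapping alignment columns
#'   to structure residues (default `cn`'s paired_msa mapping if embedded).
#' @param contact_cutoff Angstrom (default 8).
#' @param fraction top fraction of couplings to classify.
#' @return data.frame per edge (`i`, `j`, `key_i`, `key_j`, `score`,
#'   `min_dist`, `class`, `adjacent_node`); counts in attribute `"counts"`.
#' @export
overlap_dynamics <- function(cn, nodes, s, col_keys, contact_cutoff = 8,
                             fraction = 0.015) {
  edges <- top_fraction(cn, fraction)
  edges <- edges[edges$inter, , drop = FALSE]
  if (!nrow(edges)) {
    out <- data.frame()
    attr(out, "counts") <- c(interface_contact = 0L, long_range = 0L)
    return(out)
  }
  a <- s$atoms[s$atoms$elem != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res_of <- paste(a$chain, a$resno, sep = ":")
  key_i <- res_keys(col_keys[edges$i, , drop = FALSE])
  key_j <- res_keys(col_keys[edges$j, , drop = FALSE])
  min_dist <- vapply(seq_len(nrow(edges)), function(r) {
    pi_ <- xyz[res_of == key_i[r], , drop = FALSE]
    pj <- xyz[res_of == key_j[r], , drop = FALSE]
    if (!nrow(pi_) || !nrow(pj)) return(NA_real_)
    min(sqrt(outer(rowSums(pi_^2), rowSums(pj^2), "+") -
               2 * pi_ %*% t(pj)))
  }, 0)
  cls <- ifelse(min_dist < contact_cutoff, "interface_contact", "long_range")
  adjacent <- rep(NA, nrow(edges))
  if (!is.null(nodes) && nrow(nodes) && !is.null(nodes$key)) {
    node_res <- as.integer(sub(".*:", "", nodes$key))
    near_node <- function(key) {
      rn <- as.integer(sub(".*:", "", key))
      any(abs(node_res - rn) <= 1)
    }
    adjacent <- ifelse(cls == "long_range",
                       vapply(key_i, near_node, TRUE) |
                         vapply(key_j, near_node, TRUE), NA)
  }
  out <- data.frame(i = edges$i, j = edges$j, key_i = key_i, key_j = key_j,
                    score = edges$score, min_dist = min_dist, class = cls,
                    adjacent_node = adjacent, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(interface_contact = sum(cls == "interface_contact"),
                           long_range = sum(cls == "long_range"))
  out
}
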