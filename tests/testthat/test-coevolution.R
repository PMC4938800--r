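toy_msa <- function(rows) {
  do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
}

test_that("redundancy filtering is greedy, order-stable and idempotent", {
  m <- toy_msa(c("ACDEF", "ACDEF", "WYKRH", "ACDEW"))
  kept <- filter_redundancy(m, 0.8)
  expect_equal(nrow(kept), 3) # exact duplicate removed; 4/5 = 0.8 kept
  expect_equal(attr(kept, "kept"), c(1, 3, 4))

  # rows all below the identity level are untouched
  m2 <- toy_msa(c("AAAAA", "WWWWW", "KKKKK"))
  expect_equal(nrow(filter_redundancy(m2, 0.8)), 3)

  # gaps are excluded from the identity denominator
  m3 <- toy_msa(c("AC-EF", "ACDEF"))
  expect_equal(nrow(filter_redundancy(m3, 0.8)), 1) # 4/4 identical

  # fixed point
  once <- filter_redundancy(m, 0.8)
  attr(once, "kept") <- NULL
  twice <- filter_redundancy(once, 0.8)
  attr(twice, "kept") <- NULL
  expect_identical(twice, once)
})

test_that("sequence pairing matches organisms by genomic proximity", {
  msa_a <- toy_msa(c("ACDE", "WKRH"))
  rownames(msa_a) <- c("a1", "a2")
  msa_b <- toy_msa(c("FGH", "MNP"))
  rownames(msa_b) <- c("b1", "b2")
  meta <- data.frame(
    seq_id = c("a1", "a2", "b1", "b2"),
    organism = c("o1", "o2", "o1", "o2"),
    locus = c(100, 100, 118, 250))
  p <- pair_sequences(msa_a, msa_b, meta)
  expect_equal(nrow(p$chars), 1) # o2 pair at distance 150 discarded
  expect_equal(p$organisms, "o1")
  expect_equal(p$distances, 18)
  expect_equal(ncol(p$chars), 7)
  expect_equal(p$boundary, 4)

  # paralogous organism: greedy and exhaustive agree with a brute-force
  # minimum-weight matching on the toy instance
  msa_a2 <- toy_msa(c("AAAA", "CCCC"))
  rownames(msa_a2) <- c("x1", "x2")
  msa_b2 <- toy_msa(c("GGG", "TTT"))
  rownames(msa_b2) <- c("y1", "y2")
  meta2 <- data.frame(
    seq_id = c("x1", "x2", "y1", "y2"),
    organism = "o",
    locus = c(0, 10, 4, 11))
  # brute force over both perfect matchings: {x1-y1 (4), x2-y2 (1)} = 5 vs
  # {x1-y2 (11), x2-y1 (6)} = 17
  pe <- pair_sequences(msa_a2, msa_b2, meta2, method = "exhaustive")
  expect_equal(sum(pe$distances), 5)
  pg <- pair_sequences(msa_a2, msa_b2, meta2, method = "greedy")
  expect_equal(sum(pg$distances), 5)

  expect_error(pair_sequences(msa_a, msa_b, meta[-1, ]), "lacks")
})

test_that("mean-field DI matches an independent two-site computation", {
  # 2-column alignment over 2 letters with a known joint distribution
  set.seed(1)
  N <- 400
  a <- sample(c("A", "C"), N, replace = TRUE)
  b <- ifelse(runif(N) < 0.8, a, sample(c("A", "C"), N, replace = TRUE))
  p <- new_paired_msa(cbind(a, b), boundary = 1)
  net <- mfdca(p, pseudocount = 0.2, seqid_reweight = 1.01) # no reweighting

  # independent oracle: same statistical model, assembled via the explicit
  # 2x2 block-inverse formula and direct-information integral computed by
  # grid optimization of the two-site fields
  q <- 2
  st <- ifelse(cbind(a, b) == "A", 1, 2)
  fi <- function(i) 0.2 / q + 0.8 * tabulate(st[, i], q) / N
  fij <- matrix(0.2 / q^2, q, q)
  for (r in seq_len(N)) fij[st[r, 1], st[r, 2]] <-
    fij[st[r, 1], st[r, 2]] + 0.8 / N
  f1 <- fi(1)
  f2 <- fi(2)
  C11 <- f1[1] - f1[1]^2
  C22 <- f2[1] - f2[1]^2
  C12 <- fij[1, 1] - f1[1] * f2[1]
  # block inverse of [[C11, C12], [C12, C22]]: off-diagonal element
  inv_off <- -C12 / (C11 * C22 - C12^2)
  e12 <- -inv_off
  W <- matrix(1, 2, 2)
  W[1, 1] <- exp(e12)
  # two-site model marginal matching by direct 1-parameter search
  obj <- function(par) {
    x <- c(exp(par[1]), 1)
    y <- c(exp(par[2]), 1)
    P <- W * outer(x, y)
    P <- P / sum(P)
    sum((rowSums(P) - f1)^2 + (colSums(P) - f2)^2)
  }
  par <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 1000))$par
  x <- c(exp(par[1]), 1)
  y <- c(exp(par[2]), 1)
  P <- W * outer(x, y)
  P <- P / sum(P)
  di_oracle <- sum(P * log(P / outer(f1, f2)))
  expect_equal(net$score[1, 2], di_oracle, tolerance = 1e-8)
})

test_that("DCA and APC-MI recover planted couplings and reject noise", {
  pm <- sample_potts_msa(L = 16, q = 6, n_seq = 1200,
                         coupled_pairs = cbind(5L, 13L), J = 2.5, seed = 2)
  di <- mfdca(pm$paired)
  # planted inter-boundary pair is the top inter-boundary DI score
  inter <- di$score
  inter[1:8, 1:8] <- 0
  inter[9:16, 9:16] <- 0
  expect_equal(sort(as.integer(arrayInd(which.max(inter), dim(inter)))),
               c(5L, 13L))
  mi <- apc_mi(pm$paired)
  expect_equal(sort(as.integer(arrayInd(which.max(mi$score), dim(mi$score)))),
               c(5L, 13L))
  expect_true(isSymmetric(di$score))

  # i.i.d. columns: observed DI indistinguishable from the shuffle null
  p0 <- sample_potts_msa(L = 10, q = 4, n_seq = 400, coupled_pairs = cbind(2L, 8L),
                         J = 0, seed = 3)
  net0 <- mfdca(p0$paired)
  thr <- msa_shuffle_null(p0$paired, scorer = mfdca, n_shuffles = 10,
                          seed = 1)
  expect_gt(mean(net0$score[upper.tri(net0$score)] <= thr), 0.90)

  # pseudocount 0 on redundant columns: singular matrix error with advice
  dup <- new_paired_msa(pm$paired$chars[1:50, ], boundary = 8)
  expect_error(mfdca(dup, pseudocount = 0), "pseudocount")
})

test_that("APC removes a rank-one background", {
  u <- runif(8, 0.5, 2)
  M <- outer(u, u)
  diag(M) <- 0
  S <- ensmech:::apc_correct(M)
  # a multiplicative (rank-one) background is annihilated up to the
  # diagonal-exclusion residue
  expect_lt(max(abs(S)), 0.05 * max(M))
})

test_that("top-fraction edge lists are sorted, sized and tail-calibrated", {
  set.seed(4)
  L <- 46 # 1035 pairs
  sc <- matrix(0, L, L)
  vals <- runif(L * (L - 1) / 2)
  sc[upper.tri(sc)] <- vals
  sc <- sc + t(sc)
  net <- structure(list(score = sc, method = "DI", boundary = L %/% 2),
                   class = "coupling_network")
  expect_equal(nrow(top_fraction(net, 0)), 0)
  expect_equal(nrow(top_fraction(net, 1)), L * (L - 1) / 2)
  t15 <- top_fraction(net, 0.015)
  expect_equal(nrow(t15), ceiling(0.015 * L * (L - 1) / 2))
  expect_equal(t15$score, sort(vals, decreasing = TRUE)[seq_len(nrow(t15))])
  tails <- attr(t15, "tails")
  expect_true(all(tails >= 0 & tails <= 1))
})

test_that("shuffle null for alignments is deterministic and conservative", {
  m <- toy_msa(rep(c("ACDEF", "ACDFF", "WCDEF", "AKDEF"), 5))
  p <- new_paired_msa(m, boundary = 2)
  t1 <- msa_shuffle_null(p, n_shuffles = 10, seed = 1)
  expect_identical(t1, msa_shuffle_null(p, n_shuffles = 10, seed = 1))
  # constant columns give a degenerate (zero) null
  pc <- new_paired_msa(toy_msa(rep("AAAA", 6)), boundary = 2)
  expect_equal(msa_shuffle_null(pc, n_shuffles = 5, seed = 1), 0)
})

test_that("coupling overlap with structure and dynamics is classified", {
  # structure: two chains, residues 1-4 (A) and 1-4 (B); A:2-B:2 in contact,
  # A:4-B:4 far apart
  xyz <- rbind(helix_ca(4),
               sweep(helix_ca(4), 2, c(5, 0, 0), "+"))
  xyz[8, ] <- xyz[8, ] + c(40, 0, 0) # B:4 pushed far away
  s <- new_structure(data.frame(
    elety = "CA", resid = "ALA", chain = rep(c("A", "B"), each = 4),
    resno = rep(1:4, 2), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 0, elem = "C"))
  # coupling network over 8 columns (4 per protein): plant scores
  sc <- matrix(0, 8, 8)
  sc[2, 6] <- sc[6, 2] <- 1.0 # A:2 - B:2 contact pair
  sc[4, 8] <- sc[8, 4] <- 0.9 # A:4 - B:4 distal pair
  cn <- structure(list(score = sc, method = "DI", boundary = 4),
                  class = "coupling_network")
  col_keys <- data.frame(chain = rep(c("A", "B"), each = 4),
                         resno = rep(1:4, 2))
  nodes <- data.frame(index = 1, value = 1, prominence = 1, key = "B:3")
  ov <- overlap_dynamics(cn, nodes, s, col_keys, contact_cutoff = 8,
                         fraction = 2 / 28)
  expect_equal(nrow(ov), 2)
  counts <- attr(ov, "counts")
  expect_equal(unname(counts["interface_contact"]), 1L)
  expect_equal(unname(counts["long_range"]), 1L)
  lr <- ov[ov$class == "long_range", ]
  expect_true(lr$adjacent_node) # B:4 flanks the called node B:3
})

test_that("DI and APC-MI rank the planted pair first across replicate MSAs", {
  hits <- vapply(1:5, function(r) {
    pm <- sample_potts_msa(L = 12, q = 6, n_seq = 800,
                           coupled_pairs = cbind(3L, 9L), J = 2.5,
                           seed = 100 + r)
    di <- mfdca(pm$paired)
    mi <- apc_mi(pm$paired)
    top_di <- sort(as.integer(arrayInd(which.max(di$score), c(12, 12))))
    top_mi <- sort(as.integer(arrayInd(which.max(mi$score), c(12, 12))))
    identical(top_di, c(3L, 9L)) && identical(top_mi, c(3L, 9L))
  }, TRUE)
  expect_true(all(hits))
})
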