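# plug-in MI / joint entropy oracle by exhaustive summation over the table
oracle_nmi <- function(ci, cj) {
  N <- length(ci)
  tab <- table(ci, cj) / N
  pi_ <- rowSums(tab)
  pj <- colSums(tab)
  I <- 0
  H <- 0
  for (a in seq_along(pi_)) for (b in seq_along(pj)) {
    p <- tab[a, b]
    if (p > 0) {
      I <- I + p * log2(p / (pi_[a] * pj[b]))
      H <- H - p * log2(p)
    }
  }
  I <- as.numeric(I)
  H <- as.numeric(H)
  c(I = I, H = H, nmi = if (H > 0) I / H else 0)
}

test_that("nMI agrees with an exhaustive-sum oracle and is symmetric", {
  set.seed(1)
  ci <- sample(1:4, 60, replace = TRUE)
  cj <- sample(1:3, 60, replace = TRUE)
  o <- oracle_nmi(ci, cj)
  expect_equal(nmi_pair(ci, cj, correct_bias = FALSE), unname(o["nmi"]),
               tolerance = 1e-12)
  expect_equal(nmi_pair(ci, cj, correct_bias = FALSE, normalize = FALSE),
               unname(o["I"]), tolerance = 1e-12)
  expect_equal(nmi_pair(ci, cj), nmi_pair(cj, ci), tolerance = 1e-12)

  # identical non-constant columns, bias correction off: exactly 1
  expect_equal(nmi_pair(ci, ci, correct_bias = FALSE), 1)
  # constant columns: joint entropy zero, defined as 0
  expect_equal(nmi_pair(rep(1, 10), rep(2, 10)), 0)
  expect_error(nmi_pair(1:4, 1:5), "length")

  # independent uniform columns: corrected nMI near zero
  set.seed(2)
  vals <- replicate(50, {
    a <- sample(1:4, 500, replace = TRUE)
    b <- sample(1:4, 500, replace = TRUE)
    nmi_pair(a, b)
  })
  expect_lt(mean(vals), 0.01)
})

test_that("merging letters cannot increase nMI (data processing)", {
  set.seed(3)
  ci <- sample(1:5, 400, replace = TRUE)
  cj <- (ci + sample(0:1, 400, replace = TRUE)) %% 5 + 1
  merged <- pmin(cj, 3) # collapse letters 3-5
  expect_lte(nmi_pair(ci, merged, correct_bias = FALSE, normalize = FALSE),
             nmi_pair(ci, cj, correct_bias = FALSE, normalize = FALSE) + 1e-9)
})

test_that("nMI_PC profiles localize hinges and respect degenerate binning", {
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 12, n = 512, seed = 4)
  m <- suppressWarnings(fit_pca(ens))
  ft <- encode_ensemble(ens, default_alphabet())
  pr <- nmi_pc_profile(ft, m, 1, 10)
  # global maximum at a hinge-spanning position (boundary residues 19|20)
  expect_true(ft$positions$resno[which.max(pr)] %in% 16:20)

  # degenerate binning: a single bin carries no information
  expect_equal(nmi_pc_profile(ft, m, 1, 1), rep(0, ncol(ft$letters)))

  # rigid ensemble: profile identically zero
  rigid <- make_hinge_ensemble(c(19, 19), bend_sd = 0, n = 16, seed = 5)
  mr <- suppressWarnings(fit_pca(rigid))
  ftr <- encode_ensemble(rigid, default_alphabet())
  expect_equal(nmi_pc_profile(ftr, mr, 1, 10), rep(0, ncol(ftr$letters)))

  # conformer-count mismatch is an error
  expect_error(nmi_pc_profile(ftr, m, 1, 10), "conformers")
})

test_that("shuffle null thresholds separate signal from noise", {
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 12, n = 256, seed = 6)
  m <- suppressWarnings(fit_pca(ens))
  ft <- encode_ensemble(ens, default_alphabet())
  thr <- shuffle_null(ft, m, 1, n_shuffles = 100, seed = 1)
  expect_gte(thr, 0)
  # deterministic under the seed
  expect_identical(thr, shuffle_null(ft, m, 1, n_shuffles = 100, seed = 1))

  # seed stability on a non-degenerate null: random letter columns
  ftr <- ft
  set.seed(42)
  ftr$letters <- matrix(sample(1:5, length(ft$letters), replace = TRUE),
                        nrow(ft$letters))
  t1 <- shuffle_null(ftr, m, 1, n_shuffles = 200, seed = 1)
  t2 <- shuffle_null(ftr, m, 1, n_shuffles = 200, seed = 2)
  expect_lt(abs(t1 - t2) / t1, 0.10)

  # constant columns: null threshold 0
  ftc <- ft
  ftc$letters[] <- 1L
  expect_equal(shuffle_null(ftc, m, 1, n_shuffles = 20, seed = 1), 0)

  # independent (rigid) data: >= 95% of observed values below the threshold
  pr <- nmi_pc_profile(ft, m, 1, 10)
  null_cols <- ft$positions$resno < 14 | ft$positions$resno > 22
  expect_gte(mean(pr[null_cols] <= thr), 0.95)
})

test_that("eigenvector centrality identifies hubs, matches a dense solver", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  ce <- eigenvector_centrality(star)
  expect_equal(which.max(ce), 1)
  expect_equal(max(ce), 1)

  # two disconnected cliques of unequal weight: supported on the heavier one
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- 0.9
  M[4:6, 4:6] <- 0.3
  diag(M) <- 0
  c2 <- eigenvector_centrality(M)
  expect_true(all(c2[1:3] > 0.99))
  expect_true(all(c2[4:6] < 1e-6))
  # dense eigensolver oracle
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev) / max(abs(ev))
  expect_equal(c2, ev, tolerance = 1e-6)

  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "empty")
})

test_that("top edges are thresholded, sorted and monotone", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 0.5
  M[1, 3] <- M[3, 1] <- 0.2
  M[2, 4] <- M[4, 2] <- 0.16
  M[3, 4] <- M[4, 3] <- 0.05
  e15 <- top_edges(M, 0.15)
  expect_equal(nrow(e15), 3)
  expect_equal(e15$nmi, c(0.5, 0.2, 0.16))
  expect_equal(nrow(top_edges(M, 0.9)), 0)
  e20 <- top_edges(M, 0.2)
  expect_true(all(paste(e20$pos_i, e20$pos_j) %in%
                    paste(e15$pos_i, e15$pos_j)))
  # inter/intra classification by chain map
  em <- top_edges(M, 0.15, chain_map = c("A", "A", "B", "B"))
  expect_setequal(em$class[em$pos_i == 1 & em$pos_j == 2], "intra")
  expect_setequal(em$class[em$pos_i == 2 & em$pos_j == 4], "inter")
})

test_that("profile correlation matches the textbook formula", {
  set.seed(7)
  p1 <- rnorm(10)
  expect_equal(profile_pcorr(p1, 2 * p1 + 3), 1)
  expect_equal(profile_pcorr(p1, -p1), -1)
  p2 <- rnorm(10)
  r_oracle <- sum((p1 - mean(p1)) * (p2 - mean(p2))) /
    sqrt(sum((p1 - mean(p1))^2) * sum((p2 - mean(p2))^2))
  expect_equal(profile_pcorr(p1, p2), r_oracle, tolerance = 1e-12)
  expect_error(profile_pcorr(p1, rep(1, 10)), "constant")
  expect_error(profile_pcorr(p1, p2[1:5]), "length")
})

test_that("node calling finds prominent peaks only", {
  expect_equal(nrow(call_nodes(1:10 / 10)), 0) # monotone: no internal peaks
  two <- c(0, 1, 0, 1, 0)
  nodes <- call_nodes(two, 0.2)
  expect_equal(nodes$index, c(2, 4))
  expect_equal(nodes$prominence, c(1, 1))
  # small bumps below the prominence floor are not called
  bumpy <- c(0, 1, 0.9, 0.95, 0, 0.1, 0.05)
  called <- call_nodes(bumpy, 0.2)
  expect_equal(called$index, 2)

  # hinge fixture: the called node set contains the hinge +/- 1 fragment
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 12, n = 512, seed = 8)
  m <- suppressWarnings(fit_pca(ens))
  ft <- encode_ensemble(ens, default_alphabet())
  pr <- nmi_pc_profile(ft, m, 1, 10)
  nodes <- call_nodes(pr, 0.2, ft$positions)
  expect_true(any(as.integer(sub("A:", "", nodes$key)) %in% 16:20))
})

test_that("the assembled network is internally consistent", {
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 12, n = 256, seed = 9)
  m <- suppressWarnings(fit_pca(ens))
  ft <- encode_ensemble(ens, default_alphabet())
  net <- mi_network(ft, m, n_shuffles = 50, seed = 1)
  expect_true(isSymmetric(net$matrix))
  expect_equal(diag(net$matrix), rep(0, ncol(ft$letters)))
  expect_true(all(net$matrix[net$matrix > 0] >= net$threshold))
  expect_equal(length(net$composite), ncol(ft$letters))
  # composite nMI_PC correlates with centrality on the hinge fixture
  expect_gt(profile_pcorr(net$composite, net$centrality), 0.8)
})
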