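test_that("constraint extraction enumerates bonds, contacts and hbonds", {
  # 3-residue extended trace: 2 covalent virtual bonds + 1 (i, i+2) contact
  s <- ca_structure(cbind(0, 0, c(0, 3.8, 7.6)))
  cs <- extract_constraints(s)
  expect_equal(sum(cs$class == "covalent"), 2)
  expect_equal(sum(cs$class == "contact"), 1) # 7.6 A < 8 A cutoff
  expect_equal(nrow(cs), 3)

  # hand enumeration oracle: every pair at most once, bounds bracket the
  # reference distance
  ref <- as.matrix(s$atoms[, c("x", "y", "z")])
  for (r in seq_len(nrow(cs))) {
    d <- sqrt(sum((ref[cs$i[r], ] - ref[cs$j[r], ])^2))
    expect_gte(d, cs$lo[r])
    expect_lte(d, cs$hi[r])
  }

  # ideal 13-residue helix backbone: every (i, i+4) N-O pair constrained
  pep <- build_peptide(13)
  csp <- extract_constraints(pep)
  hb <- csp[csp$class == "hbond", ]
  a <- pep$atoms
  pair_res <- cbind(a$resno[hb$j], a$resno[hb$i]) # j = O donor side here
  res_i4 <- apply(csp[csp$class == "hbond", c("i", "j")], 1, function(p) {
    abs(a$resno[p[1]] - a$resno[p[2]])
  })
  # geometry oracle: O(i)..N(i+4) = 3.09 A in this build, so all 9 pairs
  expect_gte(sum(res_i4 == 4), 9)

  # missing CA is named
  noca <- pep
  noca$atoms <- noca$atoms[!(noca$atoms$elety == "CA" & noca$atoms$resno == 5), ]
  expect_error(extract_constraints(new_structure(noca$atoms)), "A 5")
})

test_that("deletion ligation becomes a covalent-class constraint", {
  s <- ca_structure(helix_ca(12))
  d <- delete_residues(s, "A", 5, 7)
  cs <- extract_constraints(d)
  lig <- cs[cs$class == "ligation", ]
  expect_equal(nrow(lig), 1)
  ca_res <- d$atoms$resno[c(lig$i, lig$j)]
  expect_setequal(ca_res, c(4, 8))
})

test_that("lability scoring counts shell polar atoms plus the exposure proxy", {
  # fully buried apolar pocket: hbond N-O plus >= burial_min apolar atoms
  mk <- function(polar_n, apolar_n) {
    mid <- c(0, 0, 1.5)
    rows <- list(
      data.frame(elety = "N", resid = "ALA", chain = "A", resno = 1,
                 x = 0, y = 0, z = 0, b = 0, elem = "N"),
      data.frame(elety = "O", resid = "ALA", chain = "A", resno = 5,
                 x = 0, y = 0, z = 3, b = 0, elem = "O"))
    add_shell <- function(n, resid, elety, elem, r0) {
      if (n == 0) return(NULL)
      th <- 2 * pi * seq_len(n) / n
      data.frame(elety = elety, resid = resid, chain = "A",
                 resno = 10 + seq_len(n) + (resid == "SER") * 50,
                 x = r0 * cos(th), y = r0 * sin(th), z = 1.5, b = 0,
                 elem = elem)
    }
    rows <- c(rows, list(add_shell(polar_n, "SER", "OG", "O", 3.0),
                         add_shell(apolar_n, "LEU", "CD1", "C", 3.8)))
    atoms <- do.call(rbind, rows)
    new_structure(atoms)
  }
  cfg <- engine_config()
  s0 <- mk(0, 12) # buried, apolar only
  i <- which(s0$atoms$elety == "N")[1]
  j <- which(s0$atoms$elety == "O" & s0$atoms$resid == "ALA")
  expect_equal(score_lability(s0, i, j, cfg), 0)

  s5 <- mk(5, 12) # 5 polar side-chain atoms, still buried
  i <- which(s5$atoms$elety == "N")[1]
  j <- which(s5$atoms$elety == "O" & s5$atoms$resid == "ALA")
  expect_equal(score_lability(s5, i, j, cfg), 5)
  expect_gte(score_lability(s5, i, j, cfg), cfg$lability_threshold) # demoted

  # shell radius 0: only the exposure proxy remains
  cfg0 <- engine_config(lability_shell = 0)
  expect_equal(score_lability(s5, i, j, cfg0), 1)
})

test_that("single-conformer generation satisfies bounds or reports failure", {
  # two atoms, exact 1 A constraint
  ref <- rbind(c(0, 0, 0), c(1, 0, 0))
  cs <- data.frame(i = 1L, j = 2L, lo = 1, hi = 1, class = "covalent")
  g <- generate_conformer(cs, ref, seed = 3, config = engine_config())
  expect_true(g$converged)
  expect_equal(sqrt(sum((g$coords[1, ] - g$coords[2, ])^2)), 1,
               tolerance = 0.06)

  # rigid triangle: admissible geometry only the reference one
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.6, 0))
  d <- as.matrix(dist(tri))
  cs2 <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                    lo = d[cbind(c(1, 1, 2), c(2, 3, 3))] - 0.01,
                    hi = d[cbind(c(1, 1, 2), c(2, 3, 3))] + 0.01,
                    class = "covalent")
  g2 <- generate_conformer(cs2, tri, seed = 11, config = engine_config())
  expect_true(g2$converged)
  dd <- as.matrix(dist(g2$coords))
  expect_equal(dd[cbind(c(1, 1, 2), c(2, 3, 3))],
               d[cbind(c(1, 1, 2), c(2, 3, 3))], tolerance = 0.1)

  # bounds the reference itself violates: rejected before iterating
  ref3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  bad <- data.frame(i = c(1L, 2L, 1L), j = c(2L, 3L, 3L),
                    lo = c(1, 1, 5), hi = c(1, 1, 5.1), class = "contact")
  expect_error(generate_conformer(bad, ref3, seed = 1), "inconsistent")

  # constraints too tight to satisfy within the sweep limit: failure is
  # reported, not raised, after exactly max_iter sweeps
  cfg_tight <- engine_config(tol = 1e-9, max_iter = 5, box_halfwidth = 3)
  gf <- generate_conformer(cs2, tri, seed = 1, config = cfg_tight)
  expect_false(gf$converged)
  expect_equal(gf$iterations, 5)
})

test_that("ensembles converge, audit clean, and are seed-deterministic", {
  tri <- ca_structure(rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0)))
  gen <- generate_ensemble(tri, n = 100, seed = 2)
  expect_equal(gen$report$n_converged, 100)
  cs <- extract_constraints(tri)
  expect_lt(max_constraint_violation(gen$ensemble, cs),
            engine_config()$tol + 1e-9)

  gen2 <- generate_ensemble(tri, n = 100, seed = 2)
  expect_identical(gen$ensemble$coords, gen2$ensemble$coords)
  gen3 <- generate_ensemble(tri, n = 100, seed = 3)
  expect_false(identical(gen$ensemble$coords, gen3$ensemble$coords))
})

test_that("deletion-mimic regeneration drops exactly the deleted atoms", {
  hs <- make_hinge_structure(c(10, 10))
  del <- delete_residues(hs$structure, "A", 9, 11) # PEV-like triplet
  gen <- generate_ensemble(del, n = 20, seed = 5)
  expect_equal(dim(gen$ensemble$coords)[2],
               nrow(hs$structure$atoms) - 3) # 3 CA atoms fewer
})

test_that("loose inter-domain coupling shows up as a flexible hinge", {
  # two-domain toy with tight intra-domain bounds and loose inter-domain
  # coupling only (the junction contacts are removed); a wide starting box
  # lets the sampler explore the unconstrained relative orientation
  toy <- two_domain_toy(19)
  cs <- extract_constraints(toy)
  a <- toy$atoms
  dom <- function(i) ifelse(a$resno[i] <= 19, 1L,
                            ifelse(a$resno[i] >= 23, 2L, 0L))
  same_dom <- dom(cs$i) == dom(cs$j) & dom(cs$i) > 0
  ref <- as.matrix(a[, c("x", "y", "z")])
  d <- sqrt(rowSums((ref[cs$i, ] - ref[cs$j, ])^2))
  sel <- same_dom & cs$class == "contact"
  cs$lo[sel] <- d[sel] - 0.05
  cs$hi[sel] <- d[sel] + 0.05
  cs <- cs[!(cs$class == "contact" & !same_dom), ]
  gen <- generate_ensemble(toy, n = 300, seed = 7, constraints = cs,
                           config = engine_config(box_halfwidth = 4))
  defs <- list(A1 = vector_def("A1", "line", "A", c(1, 9)),
               A2 = vector_def("A2", "line", "A", c(11, 19)),
               B1 = vector_def("B1", "line", "A", c(23, 31)))
  # matched lever lengths: intra pair inside domain 1, inter pair straddles
  # the freed junction
  inter <- angle_series(gen$ensemble, c("A2", "B1"), defs)
  intra <- angle_series(gen$ensemble, c("A1", "A2"), defs)
  expect_gt(angle_sigma(inter), angle_sigma(intra))
})

test_that("tightening bounds can only reduce ensemble variance", {
  hs <- make_hinge_structure(c(8, 8))
  loose <- generate_ensemble(hs$structure, n = 150, seed = 9,
                             config = engine_config(contact_slack = 1.0))
  tight <- generate_ensemble(hs$structure, n = 150, seed = 9,
                             config = engine_config(contact_slack = 0.3))
  total_var <- function(e) {
    ca <- e$coords
    mu <- apply(ca, c(2, 3), mean)
    sum(sweep(ca, c(2, 3), mu)^2) / dim(ca)[1]
  }
  expect_lt(total_var(tight$ensemble), total_var(loose$ensemble))
})

test_that("RMSF profiles of disjoint half-ensembles agree at n >= 500", {
  gen <- generate_ensemble(two_domain_toy(10), n = 500, seed = 13)
  e <- gen$ensemble
  n <- dim(e$coords)[1]
  half <- function(idx) {
    sub <- new_ensemble(e$reference, e$coords[idx, , , drop = FALSE],
                        superposed = TRUE)
    rmsf_profile(sub)$value
  }
  r <- cor(half(seq_len(n %/% 2)), half((n %/% 2 + 1):n))
  expect_gt(r, 0.9)
})
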