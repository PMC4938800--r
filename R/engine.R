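#' Constraint-engine configuration
#'
#' Tunable parameters of the reduced-representation distance-constraint
#' engine. All lengths in Angstrom.
#'
#' @param tol convergence tolerance: a conformer is accepted when the
#'   maximum bound violation after a sweep is below this.
#' @param box_halfwidth half-width of the per-atom random starting box
#'   around the reference coordinates.
#' @param seq_bond,seq_tol sequential CA-CA virtual bond length and half
#'   width (3.80 +/- 0.05).
#' @param cis_pro_lower widened lower bound for X-PRO virtual bonds
#'   (cis-proline shortens the CA-CA distance).
#' @param contact_cutoff,contact_slack CA pairs within the cutoff get loose
#'   bounds observed distance +/- slack.
#' @param hbond_cutoff,hbond_slack backbone N-O donor-acceptor cutoff and
#'   tight bound half width.
#' @param salt_cutoff,salt_slack charged-centroid pair cutoff and bound
#'   half width.
#' @param lability_shell,lability_threshold shell radius around an hbond
#'   midpoint for the lability score, and the score at which the bond is
#'   demoted from tight hbond to loose contact bounds.
#' @param burial_min heavy atoms within the shell needed to call the bond
#'   midpoint buried (exposure proxy 0).
#' @param max_iter iteration (sweep) limit per conformer.
#' @return named list of engine parameters.
#' @export
engine_config <- function(tol = 0.05, box_halfwidth = 1.5,
                          seq_bond = 3.80, seq_tol = 0.05,
                          cis_pro_lower = 2.90,
                          contact_cutoff = 8.0, contact_slack = 1.0,
                          hbond_cutoff = 3.5, hbond_slack = 0.15,
                          salt_cutoff = 4.5, salt_slack = 0.25,
                          lability_shell = 4.5, lability_threshold = 3,
                          burial_min = 10, max_iter = 500L) {
  as.list(environment())
}

.polar_residues <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS",
                     "LYS", "ARG", "ASP", "GLU", "TRP")
.backbone_names <- c("N", "CA", "C", "O")

#' Hydrogen-bond lability score
#'
#' Counts polar/charged side-chain heavy atoms within a shell around the
#' bond midpoint, plus a solvent-exposure proxy (1 when fewer than
#' `burial_min` heavy atoms of any kind occupy the shell, i.e. the midpoint
#' is exposed; 0 when buried). Bonds scoring at or above the configured
#' threshold are treated as labile and demoted to loose contact bounds.
#'
#' @param s a `Structure`.
#' @param i,j atom indices of the donor/acceptor pair.
#' @param config [engine_config()] list.
#' @return unitless integer score.
#' @export
score_lability <- function(s, i, j, config = engine_config()) {
  a <- s$atoms
  mid <- (as.numeric(a[i, c("x", "y", "z")]) +
          as.numeric(a[j, c("x", "y", "z")])) / 2
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- colSums((t(xyz) - mid)^2)
  shell <- d2 <= config$lability_shell^2 & a$elem != "H"
  shell[c(i, j)] <- FALSE
  polar <- shell & !(a$elety %in% .backbone_names) &
    (a$resid %in% .polar_residues)
  exposure <- as.integer(sum(shell) < config$burial_min)
  sum(polar) + exposure
}

#' Extract the distance-constraint set of a structure
#'
#' Builds the constraint table the conformer generator iterates over:
#' sequential CA-CA virtual bonds (3.80 +/- 0.05, widened lower bound before
#' proline), tight backbone N-O hydrogen-bond bounds (unless labile, see
#' [score_lability()]), charged side-chain centroid salt bridges, loose
#' all-pair CA contacts within the cutoff, and covalent-class bounds for
#' ligation records left by [delete_residues()]. Residues are bonded
#' sequentially only when their numbering is consecutive; numbering gaps are
#' chain breaks unless a ligation record bridges them.
#'
#' @param s a `Structure` (every residue must have a CA atom).
#' @param config [engine_config()] list.
#' @return data.frame (`i`, `j` atom indices, `lo`, `hi`, `class`) of class
#'   `constraint_set`; lability scores of demoted bonds in attribute
#'   `"lability"`.
#' @export
extract_constraints <- function(s, config = engine_config()) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  caidx <- ca_indices(s) # errors if a residue lacks CA
  rt <- residue_table(s)
  n_res <- nrow(rt)
  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  rows <- list()
  add <- function(i, j, lo, hi, class) {
    rows[[length(rows) + 1L]] <<- data.frame(i = i, j = j, lo = lo, hi = hi,
                                             class = class)
  }

  # sequential CA-CA virtual bonds (consecutive numbering within a chain)
  for (k in seq_len(n_res - 1)) {
    if (rt$chain[k] != rt$chain[k + 1]) next
    if (rt$resno[k + 1] - rt$resno[k] != 1) next
    lo <- config$seq_bond - config$seq_tol
    if (rt$resid[k + 1] == "PRO") lo <- config$cis_pro_lower
    add(caidx[k], caidx[k + 1], lo, config$seq_bond + config$seq_tol,
        "covalent")
  }

  # ligation records: bond the flanking residues across the deletion gap
  for (lg in s$ligations) {
    ki <- which(rt$chain == lg$chain & rt$resno == lg$res_before)
    kj <- which(rt$chain == lg$chain & rt$resno == lg$res_after)
    if (length(ki) != 1 || length(kj) != 1)
      stop("ligation record refers to missing residues")
    add(caidx[ki], caidx[kj], config$seq_bond - config$seq_tol,
        config$seq_bond + config$seq_tol, "ligation")
  }

  # backbone N-O hydrogen bonds, residues >= 2 apart in sequence
  lab_scores <- numeric(0)
  Ni <- which(a$elety == "N")
  Oi <- which(a$elety == "O")
  if (length(Ni) && length(Oi)) {
    for (i in Ni) for (j in Oi) {
      if (a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) < 2) next
      d <- dist_ij(i, j)
      if (d > config$hbond_cutoff) next
      sc <- score_lability(s, i, j, config)
      if (sc >= config$lability_threshold) {
        lab_scores <- c(lab_scores, sc)
        add(i, j, max(0.1, d - config$contact_slack), d + config$contact_slack,
            "contact")
      } else {
        add(i, j, d - config$hbond_slack, d + config$hbond_slack, "hbond")
      }
    }
  }

  # salt bridges between charged side-chain centroid pseudo-atoms
  neg <- which(a$elety == "SCC" & a$resid %in% c("ASP", "GLU"))
  pos <- which(a$elety == "SCC" & a$resid %in% c("LYS", "ARG", "HIS"))
  for (i in neg) for (j in pos) {
    d <- dist_ij(i, j)
    if (d <= config$salt_cutoff)
      add(i, j, d - config$salt_slack, d + config$salt_slack, "salt_bridge")
  }

  # loose contacts: all remaining CA pairs within the cutoff
  bonded <- character(0)
  if (length(rows)) {
    cur <- do.call(rbind, rows)
    bonded <- paste(pmin(cur$i, cur$j), pmax(cur$i, cur$j))
  }
  cd <- as.matrix(stats::dist(xyz[caidx, , drop = FALSE]))
  for (p in seq_len(n_res - 1)) for (q in (p + 1):n_res) {
    if (cd[p, q] > config$contact_cutoff) next
    i <- caidx[p]; j <- caidx[q]
    if (paste(min(i, j), max(i, j)) %in% bonded) next
    add(i, j, max(0.1, cd[p, q] - config$contact_slack),
        cd[p, q] + config$contact_slack, "contact")
  }

  cs <- do.call(rbind, rows)

  # a ligation is a deliberate edit: the engine must close the deletion gap,
  # so observed-distance constraints that straddle the junction (and would
  # pin the two sides at their pre-ligation separation) are removed
  for (lg in s$ligations) {
    side1 <- a$chain == lg$chain & a$resno <= lg$res_before
    side2 <- a$chain == lg$chain & a$resno >= lg$res_after
    straddles <- cs$class %in% c("contact", "hbond", "salt_bridge") &
      ((side1[cs$i] & side2[cs$j]) | (side2[cs$i] & side1[cs$j]))
    cs <- cs[!straddles, , drop = FALSE]
  }

  stopifnot(all(cs$lo <= cs$hi))
  rownames(cs) <- NULL
  class(cs) <- c("constraint_set", "data.frame")
  attr(cs, "config") <- config
  attr(cs, "lability") <- lab_scores
  cs
}

#' Generate a single conformer by iterative constraint satisfaction
#'
#' Atoms start at the reference plus a uniform random displacement inside the
#' bounding box; constraint pairs outside their bounds are corrected
#' symmetrically along the pair vector, sweeping the constraints in a freshly
#' shuffled order, until the maximum violation drops below the tolerance or
#' the iteration limit (default 500 sweeps) is hit. Non-convergence is
#' reported (`converged = FALSE`), not raised.
#'
#' @param cs [extract_constraints()] table.
#' @param ref_coords n_atoms x 3 reference coordinates that must satisfy all
#'   bounds (otherwise the set is inconsistent and an error is raised).
#' @param seed integer seed of this conformer's private RNG stream.
#' @param config [engine_config()] list.
#' @return list(`coords`, `converged`, `iterations`).
#' @export
generate_conformer <- function(cs, ref_coords, seed,
                               config = attr(cs, "config") %||% engine_config()) {
  pairs <- as.matrix(cs[, c("i", "j")])
  # consistency: the reference must satisfy every bound except ligation
  # records, which are deliberate targets the parent structure violates
  chk <- cs$class != "ligation"
  v0 <- cpp_max_violation(ref_coords, as.matrix(cs[chk, c("i", "j")]),
                          cs$lo[chk], cs$hi[chk])
  if (v0 > config$tol)
    stop(sprintf("inconsistent constraint set: reference violates bounds by %.3f",
                 v0))
  cpp_generate_conformer(ref_coords, pairs, cs$lo, cs$hi,
                         config$box_halfwidth, config$tol,
                         as.integer(config$max_iter), as.numeric(seed))
}

#' Generate an equilibrium conformer ensemble from one structure
#'
#' Runs `n` independent [generate_conformer()] attempts with per-conformer
#' seeds derived reproducibly from the master seed, keeps the converged ones,
#' and superposes the ensemble on all Calpha atoms.
#'
#' @param s a `Structure`.
#' @param n conformers requested (default 4096; the full-scale analysis uses
#'   65536).
#' @param seed master seed.
#' @param config [engine_config()] list.
#' @param constraints optional pre-built constraint set.
#' @return list(`ensemble` = superposed `ConformerEnsemble`,
#'   `report` = generation report with `n_requested`, `n_converged`,
#'   per-conformer iteration counts and the seed).
#' @export
generate_ensemble <- function(s, n = 4096L, seed = 1L,
                              config = engine_config(), constraints = NULL) {
  stopifnot(n >= 1)
  cs <- constraints %||% extract_constraints(s, config)
  ref <- as.matrix(s$atoms[, c("x", "y", "z")])
  keep <- vector("list", n)
  iters <- integer(n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    g <- generate_conformer(cs, ref, seed * 2^20 + k, config)
    ok[k] <- g$converged
    iters[k] <- g$iterations
    if (g$converged) keep[[k]] <- g$coords
  }
  report <- list(n_requested = n, n_converged = sum(ok),
                 iterations = iters, converged = ok, seed = seed,
                 config = config)
  if (!any(ok)) {
    e <- simpleError("no conformer converged")
    e$report <- report
    stop(e)
  }
  coords <- array(0, c(sum(ok), nrow(ref), 3))
  kk <- 1L
  for (k in seq_len(n)) if (ok[k]) { coords[kk, , ] <- keep[[k]]; kk <- kk + 1L }
  ens <- superpose(new_ensemble(s, coords, seed = seed))
  list(ensemble = ens, report = report)
}

#' Audit that every conformer satisfies every constraint
#'
#' Post-hoc check, independent of the generator's own convergence test.
#'
#' @param e a `ConformerEnsemble`.
#' @param cs constraint set (bounds are re-checked on raw distances, which
#'   are invariant to the superposition).
#' @param tol violation tolerance.
#' @return largest violation over all conformers and constraints.
#' @export
max_constraint_violation <- function(e, cs, tol = NULL) {
  pairs <- as.matrix(cs[, c("i", "j")])
  v <- vapply(seq_len(n_conformers(e)), function(r)
    cpp_max_violation(e$coords[r, , , drop = TRUE], pairs, cs$lo, cs$hi),
    0)
  max(v)
}

#' Reduce a structure to backbone + side-chain centroid representation
#'
#' Keeps backbone N, CA, C, O and adds one side-chain centroid pseudo-atom
#' (`SCC`, element `X`) per residue with side-chain heavy atoms, carrying a
#' residue-type radius. This is the representation the constraint engine and
#' SASA stage run on for real structures; Calpha-only inputs pass through
#' unchanged.
#'
#' @param s a `Structure`.
#' @return reduced `Structure`.
#' @export
reduce_structure <- function(s) {
  a <- s$atoms
  bb <- a[a$elety %in% .backbone_names, , drop = FALSE]
  sc <- a[!(a$elety %in% .backbone_names) & a$elem != "H", , drop = FALSE]
  cent <- NULL
  if (nrow(sc)) {
    key <- paste(sc$chain, sc$resno)
    cent <- do.call(rbind, lapply(split(sc, match(key, unique(key))), function(g) {
      data.frame(elety = "SCC", resid = g$resid[1], chain = g$chain[1],
                 resno = g$resno[1], x = mean(g$x), y = mean(g$y),
                 z = mean(g$z), b = mean(g$b), elem = "X",
                 radius = .centroid_radii[g$resid[1]] %|na|% 2.3,
                 stringsAsFactors = FALSE)
    }))
  }
  bb$radius <- NA_real_
  new_structure(rbind(bb, cent), title = s$title, ligations = s$ligations)
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

# effective side-chain centroid radii by residue type (coarse sphere that
# covers the side-chain heavy atoms)
.centroid_radii <- c(GLY = 1.0, ALA = 1.8, SER = 1.9, CYS = 2.0, THR = 2.0,
                     VAL = 2.1, PRO = 2.1, ILE = 2.3, LEU = 2.3, ASP = 2.2,
                     ASN = 2.2, MET = 2.4, GLU = 2.4, GLN = 2.4, LYS = 2.6,
                     HIS = 2.4, PHE = 2.5, ARG = 2.7, TYR = 2.6, TRP = 2.7)
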