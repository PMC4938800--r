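#' Ideal helical Calpha trace
#'
#' Calpha positions of an ideal alpha helix (radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees of turn per residue) along +z.
#'
#' @param n residues.
#' @param theta0 starting azimuth (degrees).
#' @param z0 starting height.
#' @return n x 3 matrix.
#' @export
helix_ca <- function(n, theta0 = 0, z0 = 0) {
  th <- deg2rad(theta0 + 100 * (seq_len(n) - 1))
  cbind(2.3 * cos(th), 2.3 * sin(th), z0 + 1.5 * (seq_len(n) - 1))
}

#' Segmented-helix hinge structure (Calpha trace)
#'
#' One continuous ideal helix partitioned into segments; hinge k sits at the
#' boundary between segments k and k+1. The default segment length of 19
#' residues is chosen so that (at 100 degrees/residue) the first-to-last
#' Calpha line of a segment is exactly parallel to the helix axis and the
#' plane through residues (i-9, i, i+9) has its normal exactly perpendicular
#' to it, which makes bend and twist angles identifiable exactly from
#' line / plane-normal vector pairs.
#'
#' @param segments residue counts per segment (each >= 4).
#' @return list(`structure` = Calpha-only `Structure`,
#'   `boundaries` = residue index of the last residue of each non-terminal
#'   segment, `segments`).
#' @export
make_hinge_structure <- function(segments = c(19, 19)) {
  stopifnot(length(segments) >= 2)
  if (any(segments < 4))
    stop("segments must have >= 4 residues to be encodable as fragments")
  L <- sum(segments)
  xyz <- helix_ca(L)
  atoms <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                      resno = seq_len(L), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], b = 0, elem = "C",
                      stringsAsFactors = FALSE)
  list(structure = new_structure(atoms, title = "hinge_fixture"),
       boundaries = cumsum(segments)[-length(segments)],
       segments = segments)
}

draw_angles <- function(n, sigma, model, delta) {
  if (model == "two_state") {
    sign <- ifelse(runif(n) < 0.5, -1, 1)
    sign * delta + rnorm(n, 0, sigma)
  } else {
    rnorm(n, 0, sigma)
  }
}

#' Synthetic hinge-polymer conformer ensemble with known ground truth
#'
#' Builds the [make_hinge_structure()] trace and, per conformer, applies an
#' independent bend and twist rotation at every hinge: the twist axis is the
#' preceding segment's helix axis, the bend axis is perpendicular to it, both
#' expressed in the frame of the preceding segment (so serial hinges
#' compound). Angles are drawn from a Gaussian well (sd `bend_sd` /
#' `twist_sd` degrees) or a symmetric two-state model (+/- `delta` with
#' within-state sd). Optional isotropic Gaussian coordinate jitter emulates
#' elastic fluctuations. The ensemble is superposed on all Calpha and the
#' generator's ground truth (including the per-conformer angle draws) is
#' attached.
#'
#' @param segments residue counts per segment.
#' @param bend_sd,twist_sd per-hinge angular sd, degrees (recycled).
#' @param bend_model,twist_model `"gaussian"` or `"two_state"`.
#' @param bend_delta,twist_delta two-state half separation, degrees.
#' @param n conformers.
#' @param noise_sd isotropic Calpha jitter sd, Angstrom (0 = rigid segments).
#' @param seed RNG seed (bit-reproducible).
#' @return `ConformerEnsemble` with attribute `"truth"` (a
#'   `hinge_ground_truth` list: parameters, hinge residue indices, and the
#'   per-conformer bend/twist draws).
#' @export
make_hinge_ensemble <- function(segments = c(19, 19), bend_sd = 10,
                                twist_sd = 0,
                                bend_model = "gaussian",
                                twist_model = "gaussian",
                                bend_delta = 0, twist_delta = 0,
                                n = 1024L, noise_sd = 0, seed = 1L) {
  stopifnot(all(bend_sd >= 0), all(twist_sd >= 0),
            bend_delta >= 0, twist_delta >= 0)
  hs <- make_hinge_structure(segments)
  s <- hs$structure
  ref <- ca_coords(s)
  L <- nrow(ref)
  nh <- length(hs$boundaries)
  bend_sd <- rep_len(bend_sd, nh)
  twist_sd <- rep_len(twist_sd, nh)

  with_seed(seed, {
    bends <- sapply(seq_len(nh), function(k)
      draw_angles(n, bend_sd[k], bend_model, bend_delta))
    twists <- sapply(seq_len(nh), function(k)
      draw_angles(n, twist_sd[k], twist_model, twist_delta))
    bends <- matrix(bends, n, nh)
    twists <- matrix(twists, n, nh)
    noise <- if (noise_sd > 0) array(rnorm(n * L * 3, 0, noise_sd),
                                     c(n, L, 3)) else NULL
  })

  coords <- array(0, c(n, L, 3))
  for (r in seq_len(n)) {
    xyz <- ref
    frame <- diag(3)
    for (k in seq_len(nh)) {
      b <- hs$boundaries[k]
      pivot <- xyz[b, ]
      axis_twist <- as.numeric(frame %*% c(0, 0, 1))
      # bend axis perpendicular to the segment axis, chosen parallel to the
      # segment ring normal (RNk) so signed bend angles are identifiable
      axis_bend <- as.numeric(frame %*% c(0, 1, 0))
      R <- rotation_about(axis_twist, deg2rad(twists[r, k])) %*%
        rotation_about(axis_bend, deg2rad(bends[r, k]))
      distal <- (b + 1):L
      xyz[distal, ] <- sweep(sweep(xyz[distal, , drop = FALSE], 2, pivot) %*%
                               t(R), 2, pivot, "+")
      frame <- R %*% frame
    }
    if (!is.null(noise)) xyz <- xyz + noise[r, , ]
    coords[r, , ] <- xyz
  }

  ens <- superpose(new_ensemble(s, coords, seed = seed))
  truth <- structure(list(segments = segments, hinges = hs$boundaries,
                          bend_sd = bend_sd, twist_sd = twist_sd,
                          bend_model = bend_model, twist_model = twist_model,
                          bend_delta = bend_delta, twist_delta = twist_delta,
                          n = n, noise_sd = noise_sd, seed = seed,
                          bends = bends, twists = twists),
                     class = "hinge_ground_truth")
  attr(ens, "truth") <- truth
  ens
}

#' Vector definitions matched to the hinge fixture
#'
#' For each segment: an axis line `AXk` (first to last Calpha, exactly along
#' the segment axis for 19-residue segments) and a ring plane normal `RNk`
#' through residues (first+0, first+9, first+18), exactly perpendicular to
#' the axis. Bend across hinge k is the signed angle `AXk . AXk+1` (sign
#' reference `RNk`); twist is the signed angle `RNk . RNk+1` (sign reference
#' `AXk`).
#'
#' @param segments residue counts per segment (19 required for exact
#'   geometry).
#' @return list of [vector_def()] entries.
#' @export
hinge_vector_defs <- function(segments = c(19, 19)) {
  starts <- cumsum(c(1, segments))[seq_along(segments)]
  defs <- list()
  for (k in seq_along(segments)) {
    a <- starts[k]
    b <- a + segments[k] - 1
    defs[[paste0("AX", k)]] <-
      vector_def(paste0("AX", k), "line", "A", c(a, b))
    if (segments[k] >= 19)
      defs[[paste0("RN", k)]] <-
        vector_def(paste0("RN", k), "plane_normal", "A", c(a, a + 9, a + 18))
  }
  defs
}

#' Paired MSA sampled from a pairwise-coupled (Potts) model
#'
#' Gibbs-samples `n_seq` sequences of length `L` over a `q`-letter alphabet
#' from a Potts model with like-state couplings `J` on the declared position
#' pairs, splits the columns into two pseudo-proteins at `boundary`, and
#' attaches synthetic organism ids and genomic gene distances so the pairing
#' stage can be exercised. Ground truth (coupled pairs, strengths, seed) is
#' attached.
#'
#' @param L alignment length (>= 2).
#' @param q alphabet size (>= 2), mapped onto the first `q` amino-acid
#'   letters.
#' @param n_seq sequences.
#' @param coupled_pairs 2-column matrix of coupled position pairs (1-based
#'   columns of the concatenated alignment).
#' @param J coupling strength(s) on the like-state diagonal (recycled).
#' @param fields optional L x q field matrix (default 0).
#' @param boundary last column of pseudo-protein A (default `L/2`).
#' @param n_sweeps Gibbs sweeps per sequence.
#' @param gene_dist_mean,gene_dist_sd synthetic genomic distance model
#'   (absolute-normal, genes).
#' @param seed RNG seed.
#' @param j_warn couplings above this trigger a slow-mixing warning in the
#'   report.
#' @return list(`paired` = `paired_msa` object, `msa_a`, `msa_b` character
#'   matrices, `metadata` data.frame, `truth`, `report`).
#' @export
sample_potts_msa <- function(L = 24L, q = 8L, n_seq = 2000L,
                             coupled_pairs = NULL, J = 2,
                             fields = NULL, boundary = NULL,
                             n_sweeps = 200L,
                             gene_dist_mean = 18, gene_dist_sd = 24,
                             seed = 1L, j_warn = 5) {
  stopifnot(q >= 2, L >= 2)
  boundary <- boundary %||% (L %/% 2)
  # default: one inter-boundary coupled pair
  coupled_pairs <- coupled_pairs %||%
    cbind(max(1L, boundary %/% 2L), min(L, boundary + (L - boundary) %/% 2L))
  coupled_pairs <- matrix(as.integer(coupled_pairs), ncol = 2)
  if (any(coupled_pairs < 1) || any(coupled_pairs > L))
    stop("coupled positions must lie in 1..L")
  if (any(coupled_pairs[, 1] == coupled_pairs[, 2]))
    stop("coupled pairs must be distinct positions")
  J <- rep_len(J, nrow(coupled_pairs))
  fields <- fields %||% matrix(0, L, q)
  states <- cpp_sample_potts(as.integer(n_seq), as.integer(L), as.integer(q),
                             coupled_pairs, J, fields, as.integer(n_sweeps),
                             as.numeric(seed))
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][seq_len(q)]
  chars <- matrix(alphabet[states], n_seq, L)

  with_seed(seed + 1L, {
    dists <- pmin(round(abs(rnorm(n_seq, gene_dist_mean, gene_dist_sd))), 99)
  })
  orgs <- sprintf("org%05d", seq_len(n_seq))
  metadata <- data.frame(
    seq_id = c(sprintf("A_%05d", seq_len(n_seq)),
               sprintf("B_%05d", seq_len(n_seq))),
    protein = rep(c("A", "B"), each = n_seq),
    organism = rep(orgs, 2),
    locus = c(rep(1000L, n_seq), 1000L + dists),
    stringsAsFactors = FALSE)

  paired <- new_paired_msa(chars, boundary = boundary, organisms = orgs,
                           distances = dists)
  truth <- list(L = L, q = q, coupled_pairs = coupled_pairs, J = J,
                n_seq = n_seq, seed = seed, boundary = boundary)
  report <- list(mixing_warning = any(J > j_warn))
  if (report$mixing_warning)
    warning("coupling J exceeds ", j_warn, "; Gibbs chains may mix slowly")
  list(paired = paired,
       msa_a = chars[, seq_len(boundary), drop = FALSE],
       msa_b = chars[, (boundary + 1):L, drop = FALSE],
       metadata = metadata, truth = truth, report = report)
}

#' Ideal peptide backbone from internal coordinates
#'
#' NeRF chain builder with standard bond lengths/angles; per-residue phi/psi
#' set the conformation (alpha helix: -57/-47). Returns a backbone-only
#' `Structure` (N, CA, C, O) useful as a hydrogen-bond-bearing engine
#' fixture.
#'
#' @param n residues.
#' @param phi,psi backbone dihedrals, degrees (recycled).
#' @param resid residue names (recycled).
#' @return a `Structure`.
#' @export
build_peptide <- function(n, phi = -57, psi = -47, resid = "ALA") {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  resid <- rep_len(resid, n)
  atoms <- list()
  addr <- function(elety, elem, resno, p)
    data.frame(elety = elety, resid = resid[resno], chain = "A",
               resno = resno, x = p[1], y = p[2], z = p[3], b = 0,
               elem = elem, stringsAsFactors = FALSE)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(-cos(deg2rad(180 - 111.2)), sin(deg2rad(180 - 111.2)), 0)
  atoms[[1]] <- addr("N", "N", 1, N)
  atoms[[2]] <- addr("CA", "C", 1, CA)
  atoms[[3]] <- addr("C", "C", 1, C)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n)) {
    if (i < n) {
      Nn <- place_atom(prevC, prevCA, prevN, 1.329, 116.2, psi[i])
      O <- place_atom(prevC, prevCA, Nn, 1.231, 120.8, 180)
      atoms[[length(atoms) + 1L]] <- addr("O", "O", i, O)
      CAn <- place_atom(Nn, prevC, prevCA, 1.458, 121.7, 180)
      Cn <- place_atom(CAn, Nn, prevC, 1.525, 111.2, phi[i + 1])
      atoms[[length(atoms) + 1L]] <- addr("N", "N", i + 1, Nn)
      atoms[[length(atoms) + 1L]] <- addr("CA", "C", i + 1, CAn)
      atoms[[length(atoms) + 1L]] <- addr("C", "C", i + 1, Cn)
      prevN <- Nn; prevCA <- CAn; prevC <- Cn
    } else {
      O <- place_atom(prevC, prevCA, prevN, 1.231, 120.8, psi[i] + 180)
      atoms[[length(atoms) + 1L]] <- addr("O", "O", i, O)
    }
  }
  new_structure(do.call(rbind, atoms), title = "ideal_peptide")
}
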