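#' Conformer ensembles
#'
#' A `ConformerEnsemble` holds N conformers of one molecule (an
#' `N x n_atoms x 3` coordinate array, Angstrom) together with the parent
#' reference `Structure` whose atom ordering every conformer shares, the
#' selection used for superposition, a superposed flag and the RNG seed that
#' produced it.
#'
#' @param reference a `Structure`.
#' @param coords numeric array `N x n_atoms x 3`.
#' @param seed seed recorded for provenance.
#' @param superposed logical flag.
#' @param selection integer atom indices used for the rigid-body fit (NULL if
#'   not yet superposed).
#' @return object of class `ConformerEnsemble`.
#' @export
new_ensemble <- function(reference, coords, seed = NA, superposed = FALSE,
                         selection = NULL) {
  stopifnot(inherits(reference, "Structure"), length(dim(coords)) == 3,
            dim(coords)[2] == nrow(reference$atoms), dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("non-finite conformer coordinates")
  structure(list(reference = reference, coords = coords, seed = seed,
                 superposed = superposed, selection = selection),
            class = "ConformerEnsemble")
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  cat(sprintf("ConformerEnsemble: %d conformers x %d atoms (%s), seed %s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (x$superposed) "superposed" else "not superposed",
              format(x$seed)))
  invisible(x)
}

n_conformers <- function(e) dim(e$coords)[1]

# N x n_res x 3 Calpha coordinate array + residue keys
ensemble_ca <- function(e) {
  idx <- ca_indices(e$reference)
  keys <- paste(e$reference$atoms$chain[idx], e$reference$atoms$resno[idx],
                sep = ":")
  list(coords = e$coords[, idx, , drop = FALSE], keys = keys, atom_idx = idx)
}

# mean Calpha coordinates (the "ensemble-average structure")
ensemble_mean_ca <- function(e) {
  ca <- ensemble_ca(e)
  m <- apply(ca$coords, c(2, 3), mean)
  rownames(m) <- ca$keys
  m
}

# map residue keys ("chain:resno") to CA atom indices
selection_atoms <- function(s, selection) {
  idx <- ca_indices(s)
  keys <- paste(s$atoms$chain[idx], s$atoms$resno[idx], sep = ":")
  if (is.null(selection)) return(idx)
  if (is.data.frame(selection)) selection <- res_keys(selection)
  bad <- setdiff(selection, keys)
  if (length(bad))
    stop("selection residues not in structure: ", paste(bad, collapse = ", "))
  idx[match(selection, keys)]
}

#' Superpose every conformer onto the reference structure
#'
#' Least-squares (Kabsch) rigid-body fit of each conformer onto the reference
#' over the Calpha atoms of `selection`; the fitted transform is applied to
#' all atoms. Per-conformer RMSD over the fit selection is attached as
#' attribute `"rmsd"`.
#'
#' @param e a `ConformerEnsemble`.
#' @param selection residue keys (`"chain:resno"` character or a
#'   `chain`/`resno` data.frame); NULL = all Calpha.
#' @return superposed `ConformerEnsemble`.
#' @export
superpose <- function(e, selection = NULL) {
  idx <- selection_atoms(e$reference, selection)
  if (length(idx) < 3) stop("superposition needs at least 3 selection atoms")
  ref <- as.matrix(e$reference$atoms[idx, c("x", "y", "z")])
  N <- n_conformers(e)
  out <- e$coords
  rmsd <- numeric(N)
  for (r in seq_len(N)) {
    P <- e$coords[r, idx, , drop = TRUE]
    fit <- kabsch(P, ref)
    out[r, , ] <- apply_fit(e$coords[r, , , drop = TRUE], fit)
    rmsd[r] <- fit$rmsd
  }
  res <- new_ensemble(e$reference, out, seed = e$seed, superposed = TRUE,
                      selection = idx)
  attr(res, "rmsd") <- rmsd
  res
}

#' Ensemble-derived B-factor profile
#'
#' Per-residue \eqn{B = (8 pi^2 / 3) <|dr_CA|^2>} from the superposed
#' ensemble, normalized to zero mean / unit population SD via
#' [normalized_profile()]. The raw Angstrom^2 values are kept in attribute
#' `"raw"`.
#'
#' @param e superposed `ConformerEnsemble`.
#' @return profile data.frame (`chain`, `resno`, `value`).
#' @export
ensemble_bfactors <- function(e) {
  if (!e$superposed) stop("ensemble must be superposed first")
  ca <- ensemble_ca(e)
  msf <- residue_msf(ca$coords)
  raw <- (8 * pi^2 / 3) * msf
  kk <- strsplit(ca$keys, ":", fixed = TRUE)
  prof <- data.frame(chain = vapply(kk, `[`, "", 1),
                     resno = as.integer(vapply(kk, `[`, "", 2)),
                     value = normalized_profile(raw),
                     stringsAsFactors = FALSE)
  attr(prof, "raw") <- raw
  prof
}

# per-residue mean-square fluctuation about the ensemble mean
residue_msf <- function(ca_arr) {
  mu <- apply(ca_arr, c(2, 3), mean)
  d2 <- sweep(ca_arr, c(2, 3), mu)^2
  apply(d2, 2, sum) / dim(ca_arr)[1]
}

# van der Waals radii (Angstrom) for SASA; pseudo-atoms carry their own
# radius in the atom table's optional `radius` column
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                FE = 1.40, ZN = 1.39, MG = 1.73)

atom_radii <- function(s) {
  r <- rep(NA_real_, nrow(s$atoms))
  if (!is.null(s$atoms$radius)) r <- s$atoms$radius
  need <- is.na(r)
  el <- s$atoms$elem[need]
  unknown <- setdiff(unique(el), names(.vdw_radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r[need] <- .vdw_radii[el]
  r
}

#' Ensemble SASA profile (Shrake-Rupley)
#'
#' Per-conformer, per-residue solvent-accessible surface area in Angstrom^2
#' (numerical Shrake-Rupley quadrature on a deterministic spherical lattice),
#' summarized as ensemble mean and SD per residue.
#'
#' @param e a `ConformerEnsemble`.
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_sphere_points quadrature points per atom.
#' @return profile data.frame (`chain`, `resno`, `value` = mean SASA,
#'   `sigma` = SD across conformers).
#' @export
sasa_profile <- function(e, probe_radius = 1.4, n_sphere_points = 960) {
  radii <- atom_radii(e$reference)
  a <- e$reference$atoms
  rt <- residue_table(e$reference)
  grp <- match(paste(a$chain, a$resno), paste(rt$chain, rt$resno))
  N <- n_conformers(e)
  per <- matrix(0, N, nrow(rt))
  for (r in seq_len(N)) {
    at <- cpp_sasa(e$coords[r, , , drop = TRUE], radii, probe_radius,
                   as.integer(n_sphere_points))
    per[r, ] <- as.numeric(tapply(at, grp, sum))
  }
  data.frame(chain = rt$chain, resno = rt$resno,
             value = colMeans(per),
             sigma = apply(per, 2, pop_sd), stringsAsFactors = FALSE)
}

#' SASA of a single structure (same quadrature as [sasa_profile()])
#' @inheritParams sasa_profile
#' @param s a `Structure`.
#' @return per-atom SASA vector, Angstrom^2.
#' @export
structure_sasa <- function(s, probe_radius = 1.4, n_sphere_points = 960) {
  cpp_sasa(as.matrix(s$atoms[, c("x", "y", "z")]), atom_radii(s),
           probe_radius, as.integer(n_sphere_points))
}

#' Write an ensemble as a multi-model PDB file
#' @param e a `ConformerEnsemble`.
#' @param path output file.
#' @export
write_ensemble_pdb <- function(e, path) {
  a <- e$reference$atoms
  xyz <- t(apply(e$coords, 1, function(m) as.numeric(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   chain = a$chain, elety = a$elety, b = a$b)
  invisible(path)
}

#' Write a per-residue profile as TSV (chain, resnum, value, sigma)
#' @param profile profile data.frame.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  if (is.null(profile$sigma)) profile$sigma <- NA
  write.table(profile[, c("chain", "resno", "value", "sigma")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
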