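# shared fixture builders (all fixtures are generated in code)

# Calpha-only structure from a coordinate matrix
ca_structure <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                         resid = "ALA", b = 0) {
  new_structure(data.frame(elety = "CA", resid = resid, chain = chain,
                           resno = resno, x = xyz[, 1], y = xyz[, 2],
                           z = xyz[, 3], b = b, elem = "C",
                           stringsAsFactors = FALSE))
}

# ensemble from an explicit list of conformer coordinate matrices
ensemble_from_list <- function(s, conformers, superposed = FALSE) {
  coords <- array(0, c(length(conformers), nrow(s$atoms), 3))
  for (r in seq_along(conformers)) coords[r, , ] <- conformers[[r]]
  new_ensemble(s, coords, superposed = superposed)
}

# small 5-letter alphabet used by the encoding tests (correctness never
# depends on the shipped library)
toy_alphabet <- function() {
  frags <- list(
    helix_ca(4),                                  # alpha
    cbind(c(0, 0.5, 0, 0.5), 0, 3.4 * (0:3)),     # extended
    cbind(c(0, 1, 2, 3), c(0, 1, 0, -1) * 1.5, c(0, 1, 3, 4)), # turn
    cbind(0, c(0, 1.2, 2.4, 3.6), c(0, 2, 4, 6)), # steep rise
    cbind(c(0, 2, 2, 0), c(0, 0, 2, 2), c(0, 1, 2, 3))) # zigzag
  coords <- array(0, c(5, 4, 3))
  for (l in 1:5) coords[l, , ] <- frags[[l]]
  make_alphabet(c("h", "e", "t", "s", "z"), coords,
                c("helix", "sheet", "loop", "loop", "loop"))
}

# fixed-width PDB text for hand-built fixtures
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, elem = "C", record = "ATOM",
                          alt = "") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, alt, resid, chain, resno, x, y, z,
          occ, b, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# two-residue minimal PDB fixture (N, CA per residue)
minimal_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, elem = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0),
    pdb_atom_line(3, "N", "GLY", "A", 2, 3.3, 1, 0, elem = "N"),
    pdb_atom_line(4, "CA", "GLY", "A", 2, 4.3, 1.5, 0.5)))
}

# independent line-by-line text oracle parser (deliberately naive; no bio3d)
oracle_parse_pdb <- function(path, model_index = 1) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    model_ends <- grep("^ENDMDL", lines)
    block <- lines[(model_starts[model_index] + 1):(model_ends[model_index] - 1)]
  } else {
    block <- lines
  }
  at <- block[grepl("^(ATOM|HETATM)", block)]
  data.frame(
    name = trimws(substr(at, 13, 16)),
    resno = as.integer(substr(at, 23, 26)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    stringsAsFactors = FALSE)
}

# two helical domains joined by a 3-residue extended linker with no
# cross-domain contacts: the only inter-domain coupling is the sequential
# chain through the linker, so the junction behaves as a loose hinge
two_domain_toy <- function(n_per = 10) {
  h1 <- helix_ca(n_per)
  top <- h1[n_per, ]
  linker <- cbind(top[1], top[2], top[3] + 3.8 * (1:3))
  h2 <- helix_ca(n_per)
  shift <- c(top[1], top[2], linker[3, 3] + 3.8) - h2[1, ]
  h2 <- sweep(h2, 2, shift, "+")
  ca_structure(rbind(h1, linker, h2))
}

# full report content minus the hash field (for bit-identity comparisons)
report_fingerprint <- function(r) {
  r$hash <- NULL
  r
}

# random rigid rototranslation
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- ensmech:::rotation_about(ax / sqrt(sum(ax^2)), runif(1, 0, 2 * pi))
  sweep(xyz %*% t(R), 2, rnorm(3, sd = 5), "+")
}
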