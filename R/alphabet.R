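#' Structural alphabet library
#'
#' A finite library of canonical 4-residue Calpha fragments ("letters") used
#' to encode local backbone conformation. Canonical fragments are stored
#' centered at the origin; each carries a coarse secondary-structure class.
#'
#' @param ids letter ids (unique, >= 2).
#' @param coords numeric array n_letters x 4 x 3 of canonical Calpha
#'   coordinates (will be centered).
#' @param class per-letter class, one of `"helix"`, `"sheet"`, `"loop"`.
#' @return object of class `alphabet_library`.
#' @export
make_alphabet <- function(ids, coords, class) {
  stopifnot(length(ids) >= 2, !anyDuplicated(ids),
            length(dim(coords)) == 3, dim(coords)[2] == 4,
            dim(coords)[3] == 3, length(class) == length(ids))
  for (l in seq_along(ids))
    coords[l, , ] <- sweep(coords[l, , ], 2, colMeans(coords[l, , ]))
  # all letters must be geometrically distinct
  for (a in seq_len(length(ids) - 1)) for (b in (a + 1):length(ids)) {
    r <- cpp_fragment_rmsds(coords[a, , ], matrix(coords[b, , ], 4, 3), 4L)
    if (r < 1e-6)
      stop(sprintf("letters %s and %s are identical fragments", ids[a], ids[b]))
  }
  structure(list(ids = as.character(ids), coords = coords,
                 class = as.character(class)),
            class = "alphabet_library")
}

# letters stacked (4*nl) x 3 for the C++ encoder
lib_stack <- function(lib) {
  nl <- length(lib$ids)
  do.call(rbind, lapply(seq_len(nl), function(l) lib$coords[l, , ]))
}

#' Procedurally generated fragment library
#'
#' Builds a structural alphabet from ideal-geometry seeds: an alpha-helix
#' 4-mer, an extended strand, a polyproline-like fragment, and helix 4-mers
#' kinked at their midpoint over a grid of bend angles about two
#' perpendicular axes. This is a synthetic stand-in library (the empirical
#' 25-letter fragment alphabet derived from high-resolution crystal
#' structures is an external dataset); its letters discretize local bend
#' geometry finely enough for hinge detection on idealized traces.
#'
#' @param bend_grid kink angles (degrees) for the bent-helix letters.
#' @return `alphabet_library` with `2 + 1 + 2 * length(bend_grid)` letters.
#' @export
synthetic_alphabet <- function(bend_grid = c(-60, -45, -30, -15, 15, 30, 45, 60)) {
  frag_helix <- helix_ca(4)
  # extended strand: ~3.4 A rise, alternating lateral displacement
  frag_strand <- cbind(c(0, 0.5, 0, 0.5), 0, 3.4 * (0:3))
  frag_pp2 <- helix_ca(4, theta0 = 0)
  frag_pp2 <- {
    th <- deg2rad(-120 * (0:3))
    cbind(1.3 * cos(th), 1.3 * sin(th), 3.1 * (0:3))
  }
  # 3-10-like tighter helix and a left-handed mirror of the alpha 4-mer
  frag_310 <- {
    th <- deg2rad(120 * (0:3))
    cbind(1.9 * cos(th), 1.9 * sin(th), 2.0 * (0:3))
  }
  frag_left <- frag_helix %*% diag(c(1, -1, 1))
  kink <- function(axis, ang, f = frag_helix) {
    pivot <- f[2, ]
    R <- rotation_about(axis, deg2rad(ang))
    f[3:4, ] <- sweep(sweep(f[3:4, , drop = FALSE], 2, pivot) %*% t(R), 2,
                      pivot, "+")
    f
  }
  ids <- c("H", "E", "P", "G", "L")
  frags <- list(frag_helix, frag_strand, frag_pp2, frag_310, frag_left)
  cls <- c("helix", "sheet", "loop", "helix", "loop")
  for (ang in c(-60, -30, 30, 60)) { # strand kinks (turn-like letters)
    ids <- c(ids, sprintf("T%+03d", ang))
    frags <- c(frags, list(kink(c(1, 0, 0), ang, frag_strand)))
    cls <- c(cls, "loop")
  }
  for (ang in bend_grid) {
    ids <- c(ids, sprintf("X%+03d", ang))
    frags <- c(frags, list(kink(c(1, 0, 0), ang)))
    cls <- c(cls, if (abs(ang) <= 15) "helix" else "loop")
  }
  for (ang in bend_grid) {
    ids <- c(ids, sprintf("Y%+03d", ang))
    frags <- c(frags, list(kink(c(0, 1, 0), ang)))
    cls <- c(cls, if (abs(ang) <= 15) "helix" else "loop")
  }
  coords <- array(0, c(length(ids), 4, 3))
  for (l in seq_along(ids)) coords[l, , ] <- frags[[l]]
  make_alphabet(ids, coords, cls)
}

#' Read / write an alphabet library (TSV: id, class, x1..z4)
#' @param path TSV file.
#' @return `alphabet_library`.
#' @export
read_alphabet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  nl <- nrow(d)
  coords <- array(0, c(nl, 4, 3))
  for (a in 1:4) {
    coords[, a, 1] <- d[[paste0("x", a)]]
    coords[, a, 2] <- d[[paste0("y", a)]]
    coords[, a, 3] <- d[[paste0("z", a)]]
  }
  make_alphabet(d$id, coords, d$class)
}

#' @rdname read_alphabet
#' @param lib `alphabet_library` to write.
#' @export
write_alphabet <- function(lib, path) {
  d <- data.frame(id = lib$ids, class = lib$class)
  for (a in 1:4) {
    d[[paste0("x", a)]] <- lib$coords[, a, 1]
    d[[paste0("y", a)]] <- lib$coords[, a, 2]
    d[[paste0("z", a)]] <- lib$coords[, a, 3]
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default shipped library (synthetic 25-letter stand-in)
#' @return `alphabet_library`.
#' @export
default_alphabet <- function() {
  read_alphabet(system.file("extdata", "alphabet_synthetic_25.tsv",
                            package = "ensmech", mustWork = TRUE))
}

#' Encode one 4-residue fragment as a letter
#'
#' The letter whose canonical coordinates have minimal Kabsch-superposed
#' RMSD to the fragment; ties break to the lowest letter index.
#'
#' @param coords 4 x 3 Calpha coordinates.
#' @param lib `alphabet_library`.
#' @return list(`letter`, `index`, `rmsd`).
#' @export
encode_fragment <- function(coords, lib) {
  stopifnot(is.matrix(coords), nrow(coords) == 4, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite fragment coordinates")
  if (min(stats::dist(coords)) < 1e-6)
    stop("degenerate fragment: coincident Calpha positions")
  r <- cpp_fragment_rmsds(coords, lib_stack(lib), 4L)
  i <- which.min(r)
  list(letter = lib$ids[i], index = i, rmsd = r[i])
}

#' Encode every conformer of an ensemble as fragment-letter strings
#'
#' Every overlapping 4-residue window of every conformer is encoded
#' ([encode_fragment()] semantics, vectorized in C++). Windows are indexed
#' by their first residue; chain changes and residue-numbering gaps
#' (deletion sites) terminate windows rather than bridging them.
#'
#' @param e superposed `ConformerEnsemble`.
#' @param lib `alphabet_library` (default the shipped synthetic library).
#' @return object of class `fragment_trajectory`: `letters` (N x n_windows
#'   integer matrix), `ids`, `positions` (data.frame `chain`,
#'   `resno` of each window's first residue), `lib`.
#' @export
encode_ensemble <- function(e, lib = default_alphabet()) {
  if (!e$superposed) stop("ensemble must be superposed first")
  ca <- ensemble_ca(e)
  kk <- strsplit(ca$keys, ":", fixed = TRUE)
  chain <- vapply(kk, `[`, "", 1)
  resno <- as.integer(vapply(kk, `[`, "", 2))
  L <- length(chain)
  starts <- integer(0)
  for (i in seq_len(L - 3)) {
    w <- i:(i + 3)
    if (length(unique(chain[w])) == 1 && all(diff(resno[w]) == 1))
      starts <- c(starts, i)
  }
  if (!length(starts)) stop("no encodable 4-residue window")
  flat <- cbind(ca$coords[, , 1], ca$coords[, , 2], ca$coords[, , 3])
  letters <- cpp_encode_ensemble(flat, L, as.integer(starts), lib_stack(lib), 4L)
  structure(list(letters = letters, ids = lib$ids,
                 positions = data.frame(chain = chain[starts],
                                        resno = resno[starts],
                                        stringsAsFactors = FALSE),
                 lib = lib),
            class = "fragment_trajectory")
}

#' @export
print.fragment_trajectory <- function(x, ...) {
  cat(sprintf("fragment_trajectory: %d conformers x %d fragment positions, %d letters\n",
              nrow(x$letters), ncol(x$letters), length(x$ids)))
  invisible(x)
}

#' Per-position letter frequency table
#' @param ft `fragment_trajectory`.
#' @return n_letters x n_positions matrix of ensemble fractions (the
#'   "populated ensemble fraction" greyscale).
#' @export
column_frequencies <- function(ft) {
  nl <- length(ft$ids)
  apply(ft$letters, 2, function(col) tabulate(col, nl) / length(col))
}

#' Shannon entropy per fragment position (bits)
#' @param ft `fragment_trajectory`.
#' @return numeric vector, one value per position.
#' @export
column_entropy <- function(ft) {
  f <- column_frequencies(ft)
  apply(f, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Write encoded fragment strings (FASTA-like, one string per conformer)
#' @param ft `fragment_trajectory`.
#' @param path output file.
#' @export
write_fragment_strings <- function(ft, path) {
  sym <- if (all(nchar(ft$ids) == 1)) ft$ids else
    strsplit("abcdefghijklmnopqrstuvwxyzABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]][seq_along(ft$ids)]
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(ft$letters))) {
    writeLines(sprintf(">conformer_%d", r), con)
    writeLines(paste(sym[ft$letters[r, ]], collapse = ""), con)
  }
  invisible(path)
}
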