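#' @title Atomic structures
#' @description A `Structure` is a light container around an atom table
#'   (one row per atom: `elety` atom name, `resid` residue name, `chain`,
#'   `resno` source-file residue number, `x`/`y`/`z` in Angstrom, `b`
#'   experimental B-factor in Angstrom^2, `elem` element). Residue numbers
#'   from the source file are kept verbatim everywhere (never renumbered,
#'   also after deletions) so positions can be cited by their published ids.
#' @param atoms data.frame with the columns listed above.
#' @param title character source id.
#' @param ligations list of ligation records, each
#'   `list(chain, res_before, res_after)`, marking residue pairs made
#'   adjacent by a deletion that the constraint engine must bond.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, title = "structure", ligations = list()) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z", "b", "elem")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title, ligations = ligations),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              x$title, nrow(x$atoms), nrow(residue_table(x)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Residue table of a structure
#'
#' @param s a `Structure`.
#' @return data.frame with one row per residue: `chain`, `resno`, `resid`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- !duplicated(paste(a$chain, a$resno))
  data.frame(chain = a$chain[key], resno = a$resno[key], resid = a$resid[key],
             stringsAsFactors = FALSE)
}

# residue keys "chain:resno"
res_keys <- function(df) paste(df$chain, df$resno, sep = ":")

# indices of Calpha atoms, in residue order; errors if a residue lacks one
ca_indices <- function(s, strict = TRUE) {
  a <- s$atoms
  idx <- which(a$elety == "CA")
  if (strict) {
    rt <- residue_table(s)
    have <- paste(a$chain[idx], a$resno[idx])
    missing <- setdiff(paste(rt$chain, rt$resno), have)
    if (length(missing))
      stop("residue(s) without a CA atom: ", paste(missing, collapse = ", "))
  }
  idx
}

#' Calpha coordinates of a structure
#' @param s a `Structure`.
#' @return n_res x 3 matrix, rownames `chain:resno`.
#' @export
ca_coords <- function(s) {
  idx <- ca_indices(s)
  m <- as.matrix(s$atoms[idx, c("x", "y", "z")])
  rownames(m) <- paste(s$atoms$chain[idx], s$atoms$resno[idx], sep = ":")
  m
}

#' Read a structure from a PDB file
#'
#' Wraps bio3d's PDB reader. Only the requested model and chains are kept;
#' waters and non-polymer HETATM records are discarded (HETATM residues with
#' a CA atom, i.e. modified residues, are kept); alternate locations are
#' resolved to the highest occupancy (ties: first encountered).
#'
#' @param path PDB file.
#' @param model_index 1-based model to extract.
#' @param chains optional chain ids to keep (default all).
#' @return a [new_structure()] `Structure`.
#' @export
read_structure <- function(path, model_index = 1L, chains = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > nmod)
    stop(sprintf("model %d requested but file has models 1..%d",
                 model_index, nmod))
  a <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]

  have_chains <- unique(a$chain)
  if (!is.null(chains)) {
    bad <- setdiff(chains, have_chains)
    if (length(bad))
      stop(sprintf("chain(s) %s not in file (has: %s)",
                   paste(bad, collapse = ","),
                   paste(have_chains, collapse = ",")))
    a <- a[a$chain %in% chains, , drop = FALSE]
  }

  # drop waters and non-polymer HETATM (keep modified residues carrying a CA)
  water <- a$resid %in% c("HOH", "WAT", "DOD", "H2O")
  a <- a[!water, , drop = FALSE]
  het <- a$type == "HETATM"
  if (any(het)) {
    rk <- paste(a$chain, a$resno)
    has_ca <- rk %in% rk[a$elety == "CA"]
    a <- a[!het | has_ca, , drop = FALSE]
  }

  # altloc: per (chain, resno, atom name) keep highest occupancy, ties first
  alt <- !is.na(a$alt) & a$alt != ""
  if (any(alt)) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(match(key, unique(key)), -occ)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$elety)), , drop = FALSE]
  }

  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  atoms <- data.frame(elety = a$elety, resid = a$resid, chain = a$chain,
                      resno = a$resno, x = a$x, y = a$y, z = a$z,
                      b = ifelse(is.na(a$b), 0, a$b),
                      elem = toupper(trimws(elem)), stringsAsFactors = FALSE)
  new_structure(atoms, title = basename(path))
}

#' Delete a residue range (deletion-mimic engineering)
#'
#' Removes residues `first..last` of `chain`. The remaining residues keep
#' their source numbering (a gap is left), and a ligation record naming the
#' now-adjacent flanking residues is attached so the constraint engine can
#' bond them across the gap.
#'
#' @param s a `Structure`.
#' @param chain chain id.
#' @param first,last inclusive residue-number range to remove.
#' @return edited `Structure` with an extra ligation record.
#' @export
delete_residues <- function(s, chain, first, last) {
  stopifnot(first <= last)
  a <- s$atoms
  in_chain <- a$chain == chain
  if (!any(in_chain)) stop("chain ", chain, " not present")
  resnos <- sort(unique(a$resno[in_chain]))
  if (!(first %in% resnos) || !(last %in% resnos))
    stop(sprintf("residue range %d-%d not found in chain %s", first, last, chain))
  before <- resnos[resnos < first]
  after <- resnos[resnos > last]
  if (!length(before) || !length(after))
    stop(sprintf("range %d-%d spans an end of chain %s; nothing to ligate",
                 first, last, chain))
  drop <- in_chain & a$resno >= first & a$resno <= last
  lig <- list(chain = chain, res_before = max(before), res_after = min(after))
  new_structure(a[!drop, , drop = FALSE],
                title = sprintf("%s_del%s%d-%d", s$title, chain, first, last),
                ligations = c(s$ligations, list(lig)))
}

#' Normalize a per-residue profile to zero mean and unit (population) SD
#'
#' The standard B-factor style normalization \eqn{(v - mean) / sd}, with the
#' population SD (divide by N). Errors on constant input (SD 0).
#'
#' @param values numeric vector (order preserved), or a profile data.frame
#'   with a `value` column.
#' @return same shape as the input, normalized.
#' @export
normalized_profile <- function(values) {
  if (is.data.frame(values)) {
    values$value <- normalized_profile(values$value)
    return(values)
  }
  if (length(values) < 2) stop("need at least 2 residues")
  s <- pop_sd(values)
  if (s <= 0) stop("constant profile: population SD is zero")
  (values - mean(values)) / s
}
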