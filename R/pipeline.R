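#' Pipeline run configuration
#'
#' Collects every stage parameter with its default into one validated list.
#' Unknown keys are rejected. The configuration is serialized verbatim into
#' every report, and a single master seed fans out to per-stage streams
#' (ensemble generation, shuffles, bootstraps) so any stage can be rerun in
#' isolation reproducibly.
#'
#' @param input input description: either
#'   `list(type = "hinge_fixture", ...)` with [make_hinge_ensemble()]
#'   arguments, or `list(type = "pdb", path =, model_index =, chains =)`.
#' @param seed master seed.
#' @param use_engine regenerate the ensemble with the constraint engine from
#'   the input structure (always TRUE for pdb input).
#' @param n_conformers conformers for the engine.
#' @param engine [engine_config()] overrides (named list).
#' @param alphabet `"synthetic"` (shipped library) or a path to a library
#'   TSV.
#' @param pcs PCs analysed.
#' @param n_bins equal-occupancy bins for nMI_PC.
#' @param n_shuffles shuffle replicates for the significance threshold.
#' @param min_prominence node-calling prominence fraction.
#' @param vector_defs list of [vector_def()] (NULL: hinge-fixture defaults
#'   when the input is a fixture).
#' @param angle_pairs list of `list(pair = c(v1, v2), signed =, sign_ref =)`
#'   entries (NULL: fixture defaults).
#' @param deletion optional `list(chain, first, last)` deletion-mimic edit;
#'   the pipeline then reports the native/deleted comparison.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = list(type = "hinge_fixture"),
                       seed = 1L,
                       use_engine = FALSE,
                       n_conformers = 1024L,
                       engine = list(),
                       alphabet = "synthetic",
                       pcs = 1:3,
                       n_bins = 10L,
                       n_shuffles = 100L,
                       min_prominence = 0.2,
                       vector_defs = NULL,
                       angle_pairs = NULL,
                       deletion = NULL,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  known_input <- c("type", "path", "model_index", "chains", "segments",
                   "bend_sd", "twist_sd", "bend_model", "twist_model",
                   "bend_delta", "twist_delta", "n", "noise_sd", "seed")
  bad <- setdiff(names(cfg$input), known_input)
  if (length(bad)) stop("unknown input key(s): ", paste(bad, collapse = ", "))
  if (!cfg$input$type %in% c("hinge_fixture", "pdb"))
    stop("input$type must be 'hinge_fixture' or 'pdb'")
  bad <- setdiff(names(cfg$engine), names(engine_config()))
  if (length(bad)) stop("unknown engine key(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE) # canonical serialization for hashing only
  unname(tools::md5sum(f))
}

load_input <- function(cfg) {
  inp <- cfg$input
  if (inp$type == "hinge_fixture") {
    args <- inp[setdiff(names(inp), "type")]
    args$seed <- args$seed %||% cfg$seed
    args$n <- args$n %||% cfg$n_conformers
    ens <- do.call(make_hinge_ensemble, args)
    list(structure = ens$reference, ensemble = ens,
         truth = attr(ens, "truth"),
         defs = hinge_vector_defs(attr(ens, "truth")$segments))
  } else {
    s <- read_structure(inp$path, inp$model_index %||% 1L, inp$chains)
    list(structure = reduce_structure(s), ensemble = NULL, truth = NULL,
         defs = NULL)
  }
}

analyse_ensemble <- function(ens, cfg, defs, label) {
  lib <- if (identical(cfg$alphabet, "synthetic")) default_alphabet()
         else read_alphabet(cfg$alphabet)
  m <- suppressWarnings(fit_pca(ens))
  ft <- encode_ensemble(ens, lib)
  net <- mi_network(ft, m, pcs = cfg$pcs, n_bins = cfg$n_bins,
                    n_shuffles = cfg$n_shuffles, seed = cfg$seed + 1L)
  nodes <- call_nodes(net$composite, cfg$min_prominence, net$positions)
  mech <- NULL
  if (!is.null(defs) && !is.null(cfg$angle_pairs)) {
    mech <- lapply(cfg$angle_pairs, function(ap) {
      s_full <- angle_series(ens, ap$pair, defs,
                             signed = ap$signed %||% NULL,
                             sign_ref = ap$sign_ref %||% NULL)
      per_pc <- vapply(cfg$pcs, function(k) {
        if (m$values[k] <= 0) return(0)
        tr <- pc_trajectory(m, k, amplitudes = gaussian_amplitude_grid(33L))
        angle_sigma(angle_series(tr, ap$pair, defs,
                                 signed = ap$signed %||% NULL,
                                 sign_ref = ap$sign_ref %||% NULL))
      }, 0)
      list(pair = ap$pair, sigma = angle_sigma(s_full),
           sigma_per_pc = setNames(per_pc, paste0("PC", cfg$pcs)))
    })
    names(mech) <- vapply(cfg$angle_pairs, function(ap)
      paste(ap$pair, collapse = "."), "")
  }
  list(label = label,
       n_conformers = n_conformers(ens),
       eigenvalues = m$values[seq_len(min(10, length(m$values)))],
       anisotropy = cumulative_anisotropy(m)[seq_len(min(10, length(m$values)))],
       spread_nm = conformer_spread(m, cfg$pcs)$sigma_nm,
       rmsf = rmsf_profile(ens)$value,
       entropy = column_entropy(ft),
       nmi_threshold = net$threshold,
       nmi_pc = net$profiles,
       composite = net$composite,
       centrality = net$centrality,
       nodes = nodes,
       mechanics = mech,
       positions = net$positions)
}

#' Run the full ensemble-mechanics pipeline
#'
#' Stages in dependency order: input structure or fixture ensemble ->
#' (optional) constraint-engine regeneration -> superposition -> PCA +
#' structural-alphabet encoding -> nMI networks + node calling + vector-pair
#' mechanics -> (optional) deletion-mimic comparison. Rerunning with an
#' identical configuration gives a bit-identical report (`report$hash`).
#'
#' @param cfg [run_config()].
#' @return report list: `config`, `hash`, `seed`, per-ensemble analysis
#'   blocks, and the native/deleted `comparison` when a deletion was
#'   requested.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- load_input(cfg)
  ens <- inp$ensemble
  gen_report <- NULL
  if (is.null(ens) || isTRUE(cfg$use_engine)) {
    eng_cfg <- do.call(engine_config, cfg$engine)
    gen <- generate_ensemble(inp$structure, n = cfg$n_conformers,
                             seed = cfg$seed, config = eng_cfg)
    ens <- gen$ensemble
    gen_report <- gen$report[c("n_requested", "n_converged", "seed")]
  }
  angle_pairs <- cfg$angle_pairs
  if (is.null(angle_pairs) && !is.null(inp$truth)) {
    ns <- length(inp$truth$segments)
    angle_pairs <- lapply(seq_len(ns - 1), function(k)
      list(pair = c(paste0("AX", k), paste0("AX", k + 1)), signed = TRUE,
           sign_ref = paste0("RN", k)))
    cfg$angle_pairs <- angle_pairs
  }
  main <- analyse_ensemble(ens, cfg, inp$defs, "native")

  comparison <- NULL
  deleted <- NULL
  if (!is.null(cfg$deletion)) {
    sdel <- delete_residues(inp$structure, cfg$deletion$chain,
                            cfg$deletion$first, cfg$deletion$last)
    eng_cfg <- do.call(engine_config, cfg$engine)
    gen2 <- generate_ensemble(sdel, n = cfg$n_conformers, seed = cfg$seed,
                              config = eng_cfg)
    del_cfg <- cfg
    del_cfg$angle_pairs <- NULL # anchors may be gone; recompute nothing named
    deleted <- analyse_ensemble(gen2$ensemble, del_cfg, NULL, "deleted")
    comparison <- compare_reports(main, deleted)
  }

  report <- list(config = cfg, seed = cfg$seed, generation = gen_report,
                 native = main, deleted = deleted, comparison = comparison)
  report$hash <- config_hash(report[setdiff(names(report), "hash")])
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# residue-key aligned deltas between two analysis blocks
compare_reports <- function(a, b) {
  ka <- res_keys(a$positions)
  kb <- res_keys(b$positions)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  list(common_positions = length(common),
       d_composite = b$composite[ib] - a$composite[ia],
       d_entropy = b$entropy[ib] - a$entropy[ia],
       d_spread_nm = b$spread_nm - a$spread_nm,
       nodes_native = a$nodes$key %||% character(0),
       nodes_deleted = b$nodes$key %||% character(0))
}

#' Compare two pipeline reports of the same molecule
#'
#' Aligns the common fragment positions and reports deltas in spread,
#' composite nMI_PC, entropy, node sets and (where both reports carry them)
#' per-pair hinge angle widths.
#'
#' @param report_a,report_b [run_pipeline()] reports.
#' @return delta report list.
#' @export
compare_ensembles <- function(report_a, report_b) {
  a <- report_a$native
  b <- report_b$native
  if (!length(intersect(res_keys(a$positions), res_keys(b$positions))))
    stop("reports describe different molecules: no common positions")
  out <- compare_reports(a, b)
  if (!is.null(a$mechanics) && !is.null(b$mechanics)) {
    shared <- intersect(names(a$mechanics), names(b$mechanics))
    out$d_sigma <- vapply(shared, function(nm)
      b$mechanics[[nm]]$sigma - a$mechanics[[nm]]$sigma, 0)
  }
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report_to_json(report),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  blk <- report$native
  prof <- data.frame(chain = blk$positions$chain, resno = blk$positions$resno,
                     value = blk$composite, sigma = NA)
  write_profile_tsv(prof, file.path(out_dir, "composite_nmi_pc.tsv"))
  invisible(out_dir)
}

# strip S3 classes so the report serializes as plain JSON structures
report_to_json <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), report_to_json))
  if (is.function(x)) return(NULL)
  if (is.atomic(x)) {
    nm <- names(x)
    x <- as.vector(x)
    names(x) <- nm
  }
  x
}
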