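#!/usr/bin/env Rscript
# Distance-constraint conformer generation: convergence behaviour, ensemble
# B-factor and SASA profiles, and the flexibility signature of a loosely
# coupled two-domain polymer.

suppressMessages(library(ensmech))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

# two helical domains joined by an extended linker (no cross-domain
# contacts); intra-domain contacts tightened so the junction is the only
# compliant element
two_domain <- function(n_per = 19) {
  h1 <- helix_ca(n_per)
  top <- h1[n_per, ]
  linker <- cbind(top[1], top[2], top[3] + 3.8 * (1:3))
  h2 <- helix_ca(n_per)
  h2 <- sweep(h2, 2, c(top[1], top[2], linker[3, 3] + 3.8) - h2[1, ], "+")
  xyz <- rbind(h1, linker, h2)
  new_structure(data.frame(elety = "CA", resid = "ALA", chain = "A",
                           resno = seq_len(nrow(xyz)), x = xyz[, 1],
                           y = xyz[, 2], z = xyz[, 3], b = 0, elem = "C"))
}

toy <- two_domain()
cs <- extract_constraints(toy)
message(sprintf("constraint classes: %s",
                paste(names(table(cs$class)), table(cs$class),
                      collapse = ", ", sep = "=")))

# tighten intra-domain contacts (secondary-structure-like rigidity) and
# free the junction, then sample with a wide starting box so the
# unconstrained inter-domain orientation is explored
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

gen <- generate_ensemble(toy, n = 512, seed = seed, constraints = cs,
                         config = engine_config(box_halfwidth = 4))
rep <- gen$report
message(sprintf("converged %d/%d conformers, median %d sweeps",
                rep$n_converged, rep$n_requested,
                as.integer(median(rep$iterations[rep$converged]))))
message(sprintf("post-hoc audit: max violation %.4f A (tolerance %.2f)",
                max_constraint_violation(gen$ensemble, cs),
                engine_config()$tol))

bf <- ensemble_bfactors(gen$ensemble)
write_profile_tsv(bf, "results/engine_bfactors.tsv")
sasa <- sasa_profile(gen$ensemble, n_sphere_points = 240)
write_profile_tsv(sasa, "results/engine_sasa.tsv")
message(sprintf("B-factor profile peaks at residue %d; SASA sigma peaks at residue %d",
                bf$resno[which.max(attr(bf, "raw"))],
                sasa$resno[which.max(sasa$sigma)]))

# hinge flexibility: inter-domain vs intra-domain angle widths
defs <- list(A1 = vector_def("A1", "line", "A", c(1, 9)),
             A2 = vector_def("A2", "line", "A", c(11, 19)),
             B1 = vector_def("B1", "line", "A", c(23, 31)))
inter <- angle_sigma(angle_series(gen$ensemble, c("A2", "B1"), defs))
intra <- angle_sigma(angle_series(gen$ensemble, c("A1", "A2"), defs))
message(sprintf("angle sigma: inter-domain %.2f deg vs intra-domain %.2f deg",
                inter, intra))

write.table(data.frame(measure = c("inter_domain_sigma", "intra_domain_sigma",
                                   "n_converged", "median_sweeps"),
                       value = c(inter, intra, rep$n_converged,
                                 median(rep$iterations[rep$converged]))),
            "results/engine_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/engine_bfactors.tsv, engine_sasa.tsv, engine_summary.tsv")
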