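#!/usr/bin/env Rscript
# Structural-alphabet encoding and the mutual-information network: fragment
# entropy, nMI_PC hinge profiles, eigenvector centrality and node calling on
# a hinge fixture with two serial hinges of unequal width.

suppressMessages(library(ensmech))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

ens <- make_hinge_ensemble(c(19, 19, 19), bend_sd = c(8, 14), twist_sd = 4,
                           n = 2048, seed = seed)
m <- suppressWarnings(fit_pca(ens))
message(sprintf("PC1-3 capture %.1f%% of the variance; conformer spread %.3f nm",
                100 * cumulative_anisotropy(m)[3],
                conformer_spread(m)$sigma_nm))

ft <- encode_ensemble(ens, default_alphabet())
ent <- column_entropy(ft)
net <- mi_network(ft, m, pcs = 1:3, n_shuffles = 100, seed = seed)
nodes <- call_nodes(net$composite, 0.2, net$positions)

message(sprintf("shuffle-null nMI threshold: %.4f", net$threshold))
message(sprintf("called nodes at fragments: %s (hinges straddle residues 19|20 and 38|39)",
                paste(nodes$key, collapse = ", ")))
message(sprintf("composite nMI_PC vs centrality: r = %.3f",
                profile_pcorr(net$composite, net$centrality)))
message(sprintf("composite nMI_PC vs RMSF:       r = %.3f",
                profile_pcorr(net$composite,
                              rmsf_profile(ens)$value[seq_len(ncol(ft$letters))])))

prof <- data.frame(chain = net$positions$chain, resno = net$positions$resno,
                   entropy_bits = ent, composite_nmi_pc = net$composite,
                   centrality = net$centrality)
write.table(prof, "results/network_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_edges_tsv(top_edges(net, 0.15), "results/network_top_edges.tsv")
message("wrote results/network_profiles.tsv, network_top_edges.tsv")
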