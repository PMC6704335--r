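# Build the per-stratum functional co-occurrence networks at pathway
# level: Pearson correlations, permutation-null p-values, p < 0.01 edge
# calling, topology metrics and the top-ten hubs.
#
# B controls the permutation count; 1000 keeps this driver quick, the
# study-scale setting is 10000.

source("analysis/00_common.R")
inp <- read_inputs()
prof_l3 <- read_profile(file.path(AN_DIR, "profile_L3.tsv"))
B <- 1000L

metrics <- list()
for (g in c("F", "M")) {
  for (grp in c("Vata", "Pitta", "Kapha")) {
    net <- group_network(prof_l3, inp$metadata, grp, g, B = B,
                         alpha_edge = 0.01, seed = SEED)
    write_network(net, file.path(AN_DIR,
                                 sprintf("network_%s_%s.tsv", grp, g)),
                  graphml_path = file.path(AN_DIR,
                                           sprintf("network_%s_%s.graphml",
                                                   grp, g)))
    m <- compute_metrics(net)
    m$gender <- g; m$group <- grp
    metrics[[length(metrics) + 1L]] <- m
    hubs <- top_hubs(net, k = 10)
    write_tsv(hubs, sprintf("hubs_%s_%s.tsv", grp, g))
    message(sprintf(
      "%s %s: %d nodes, %d edges, density %.4f, diameter %d, clustering %.3f",
      g, grp, m$nodes, m$edges, m$density, m$diameter,
      m$clustering_coefficient))
  }
}
write_tsv(do.call(rbind, metrics), "network_metrics.tsv")
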