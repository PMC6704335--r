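# Attribute the imputed functional categories to phyla, per gender:
# which taxa carry each level-1 category, and in what proportion.

source("analysis/00_common.R")
inp <- read_inputs()
norm <- normalize_copy_number(inp$otu_table, inp$copy_numbers)

for (g in c("F", "M")) {
  ids <- inp$metadata$sample_id[inp$metadata$gender == g]
  tensor <- compute_contributions(norm[ids, , drop = FALSE],
                                  inp$gene_content, inp$taxonomy,
                                  inp$hierarchy, rank = "phylum")
  s <- summarize_attribution(tensor)
  tab <- do.call(rbind, lapply(colnames(s$AAF), function(ct) {
    data.frame(taxon = rownames(s$AAF), category = ct,
               AAF = round(s$AAF[, ct], 2), AAT = round(s$AAT[, ct], 2),
               TotalAA = round(s$TotalAA, 2), row.names = NULL)
  }))
  write_tsv(tab, sprintf("attribution_phylum_%s.tsv", g))
  top <- sort(s$TotalAA, decreasing = TRUE)[1:2]
  message(sprintf(
    "%s: top contributors %s = %.2f and %s = %.2f (ratio %.1f:1)",
    g, names(top)[1], top[1], names(top)[2], top[2], top[1] / top[2]))
  dom <- dominant_taxa(s, "Metabolism")
  message(sprintf("%s: Metabolism dominated by %s (AAF %.1f%%)",
                  g, dom$taxon[1], dom$AAF[1]))
}
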