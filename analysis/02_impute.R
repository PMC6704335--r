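# Impute the metagenome: 16S copy-number normalization, gene-content
# multiplication, collapse to pathway levels, and the shared-function
# set analysis across groups within each gender.

source("analysis/00_common.R")
inp <- read_inputs()

norm <- normalize_copy_number(inp$otu_table, inp$copy_numbers)
prof_gene <- predict_metagenome(norm, inp$gene_content)
prof_l3 <- collapse_to_level(prof_gene, inp$hierarchy, "L3")
prof_l2 <- collapse_to_level(prof_gene, inp$hierarchy, "L2")

write_profile(norm, file.path(AN_DIR, "normalized_otu.tsv"))
write_profile(prof_gene, file.path(AN_DIR, "profile_gene.tsv"))
write_profile(prof_l3, file.path(AN_DIR, "profile_L3.tsv"))
write_profile(prof_l2, file.path(AN_DIR, "profile_L2.tsv"))

venn_rows <- list()
for (g in c("F", "M")) {
  ids_of <- function(grp) inp$metadata$sample_id[
    inp$metadata$gender == g & inp$metadata$group == grp]
  v <- venn_functions(list(Vata = prof_gene[ids_of("Vata"), , drop = FALSE],
                           Pitta = prof_gene[ids_of("Pitta"), , drop = FALSE],
                           Kapha = prof_gene[ids_of("Kapha"), , drop = FALSE]))
  message(sprintf(
    "%s: %d functions detected overall, %d common to all three groups",
    g, length(unique(unlist(v$sets))), v$common))
  venn_rows[[g]] <- data.frame(gender = g, region = names(v$regions),
                               n_functions = unname(v$regions))
}
write_tsv(do.call(rbind, venn_rows), "venn_regions.tsv")
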