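# Shared settings for the analysis drivers. Each numbered script can be
# run on its own (later ones read the artifacts of earlier ones from
# `results/analysis`).

suppressPackageStartupMessages(library(imputome))

AN_DIR <- "results/analysis"
IN_DIR <- file.path(AN_DIR, "inputs")
SEED <- 101L
dir.create(AN_DIR, recursive = TRUE, showWarnings = FALSE)

read_inputs <- function() {
  meta <- read_metadata(file.path(IN_DIR, "metadata.tsv"))
  list(otu_table = read_otu_table(file.path(IN_DIR, "otu_table.tsv"), meta),
       taxonomy = read_lineages(file.path(IN_DIR, "taxonomy.tsv")),
       copy_numbers = read_copy_numbers(file.path(IN_DIR,
                                                  "copy_numbers.tsv")),
       gene_content = read_gene_content(file.path(IN_DIR,
                                                  "gene_content.tsv")),
       hierarchy = read_hierarchy(file.path(IN_DIR, "hierarchy.tsv")),
       traits = read_traits(file.path(IN_DIR, "traits.tsv")),
       metadata = meta)
}

write_tsv <- function(df, file) {
  utils::write.table(df, file.path(AN_DIR, file), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("wrote ", file.path(AN_DIR, file))
}
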