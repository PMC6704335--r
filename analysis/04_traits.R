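# Aggregate organism-level phenotype traits (oxygen tolerance, gram
# stain, pathogenic potential, mobile elements, biofilms, stress
# tolerance) into per-sample shares and per-stratum summaries, plus the
# phylum breakdown of each trait's abundance mass.

source("analysis/00_common.R")
inp <- read_inputs()
norm <- normalize_copy_number(inp$otu_table, inp$copy_numbers)

tp <- aggregate_traits(norm, inp$traits)
write_profile(tp, file.path(AN_DIR, "trait_profile.tsv"))

summ <- group_trait_summary(tp, inp$metadata)
summ$mean <- round(summ$mean, 4); summ$sd <- round(summ$sd, 4)
write_tsv(summ, "trait_summary.tsv")

for (tr in c("anaerobic", "potential_pathogen", "stress_tolerance")) {
  s <- summ[summ$trait == tr, ]
  lead <- s[which.max(s$mean), ]
  message(sprintf("%s: highest mean share %.3f in %s %s", tr, lead$mean,
                  lead$gender, lead$group))
}

bd <- trait_phylum_breakdown(norm, inp$traits, inp$taxonomy)
bd_mean <- apply(bd, c(1, 2), mean, na.rm = TRUE)
write_tsv(data.frame(trait = rownames(bd_mean), round(bd_mean, 4),
                     check.names = FALSE),
          "trait_phylum_breakdown.tsv")
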