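# Discover group-enriched functional signatures per gender stratum by
# the three routes: rank tests + LDA effect size (strict and
# less-strict), ANOVA/Tukey-Kramer with BH correction, and
# random-forest importance after filtering + cumulative sum scaling.
# Scores the planted truth at the end.

source("analysis/00_common.R")
inp <- read_inputs()
prof_l3 <- read_profile(file.path(AN_DIR, "profile_L3.tsv"))
prof_l2 <- read_profile(file.path(AN_DIR, "profile_L2.tsv"))
prof_gene <- read_profile(file.path(AN_DIR, "profile_gene.tsv"))
truth <- read.delim(file.path(AN_DIR, "planted_truth.tsv"))

for (g in c("F", "M")) {
  ids <- inp$metadata$sample_id[inp$metadata$gender == g]
  grp <- inp$metadata$group[match(ids, inp$metadata$sample_id)]
  for (lv in c("L3", "L2")) {
    prof <- get(paste0("prof_", tolower(lv)))[ids, , drop = FALSE]
    for (mode in c("strict", "less-strict")) {
      sig <- lefse(prof, grp, mode = mode, seed = SEED)
      write_tsv(sig, sprintf("lefse_%s_%s_%s.tsv", lv, g, mode))
      message(sprintf("lefse %s %s %s: %d signatures (%s)", g, lv, mode,
                      nrow(sig),
                      paste(sprintf("%d %s",
                                    table(factor(sig$enriched_group,
                                                 c("Vata", "Pitta",
                                                   "Kapha"))),
                                    c("Vata", "Pitta", "Kapha")),
                            collapse = ", ")))
    }
    st <- stamp_anova(prof, grp, q_max = 0.05)
    write_tsv(st, sprintf("stamp_%s_%s.tsv", lv, g))
    message(sprintf("stamp %s %s: %d features at q <= 0.05", g, lv,
                    nrow(st)))
  }
  filt <- filter_features(prof_gene[ids, , drop = FALSE])
  css <- css_normalize(filt)
  rf <- importance_rank(css, grp, n_top = 30, seed = SEED)
  write_tsv(rf$ranking, sprintf("rf_importance_%s.tsv", g))
  message(sprintf("random forest %s: OOB error %.3f over %d features", g,
                  rf$oob_error, ncol(css)))
}

# planted-truth scoring on the female strict route at level 3
sig <- read.delim(file.path(AN_DIR, "lefse_L3_F_strict.tsv"))
tr <- setNames(truth$group, truth$pathway)
tp <- sum(sig$function_id %in% names(tr) &
            sig$enriched_group == tr[sig$function_id])
message(sprintf("planted recovery (F, strict, L3): %d of %d pathways",
                tp, nrow(truth)))
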