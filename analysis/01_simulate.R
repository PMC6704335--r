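# Build the synthetic study cohort: 63 females (29 Vata / 11 Pitta /
# 23 Kapha) and 50 males (13 / 18 / 19), with two level-3 pathways per
# group planted at fold 8 in the female stratum so that every later
# signature stage has a known ground truth.

source("analysis/00_common.R")

# learn the (planting-invariant) pathway membership from a null draw,
# then plant whole pathways with balanced per-group function load
null_bundle <- generate_cohort(cohort_config(seed = SEED))
h <- unique(null_bundle$hierarchy[, c("function_id", "level3")])
sizes <- sort(table(h$level3), decreasing = TRUE)
cand <- names(sizes)[sizes >= 4 & sizes <= 12]
groups <- c("Vata", "Pitta", "Kapha")
sel <- setNames(rep(list(character()), 3), groups)
load <- setNames(numeric(3), groups)
used <- character()
for (p in cand) {
  if (all(lengths(sel) >= 2)) break
  funs <- h$function_id[h$level3 == p]
  if (length(intersect(funs, used))) next
  g <- names(which.min(ifelse(lengths(sel) >= 2, Inf, load)))
  sel[[g]] <- c(sel[[g]], p); load[[g]] <- load[[g]] + length(funs)
  used <- c(used, funs)
}
effects <- lapply(groups, function(g)
  plant_effect(g, h$function_id[h$level3 %in% sel[[g]]], fold = 8,
               gender = "F"))

cfg <- cohort_config(planted_effects = effects, seed = SEED)
bundle <- generate_cohort(cfg)
write_bundle(bundle, IN_DIR)

truth <- data.frame(group = rep(groups, times = lengths(sel)),
                    pathway = unlist(sel))
write_tsv(truth, "planted_truth.tsv")
write_tsv(bundle$truth, "planted_truth_functions.tsv")

message(sprintf("cohort: %d samples (%d F, %d M), %d OTUs, %d functions",
                nrow(bundle$otu_table),
                sum(bundle$metadata$gender == "F"),
                sum(bundle$metadata$gender == "M"),
                ncol(bundle$otu_table), ncol(bundle$gene_content)))
message("planted (female stratum, fold 8): ",
        paste(sprintf("%s=%s", truth$group, truth$pathway), collapse = ", "))
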