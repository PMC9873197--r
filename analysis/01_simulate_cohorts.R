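#!/usr/bin/env Rscript
# Generate the four synthetic cohorts that the downstream analyses use:
# a null cohort (no planted structure), a block/hub-structured cohort,
# a two-group cohort with rewired association support, and an
# enterotype-style mixture cohort.  Counts, taxonomies, truth labels and
# the generating specs are written under results/data/.

suppressPackageStartupMessages(library(splitbias))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
master_seed <- 20260901

specs <- list(
  null = synthetic_spec(n_taxa = 40, n_samples = 600, seed = master_seed),
  structured = synthetic_spec(n_taxa = 40, n_samples = 1400,
                              seed = master_seed + 1),
  twogroup = synthetic_spec(n_taxa = 40, n_samples = 400,
                            group_rewire_fraction = 0.3,
                            seed = master_seed + 2),
  enterotype = synthetic_spec(n_taxa = 30, n_samples = 300,
                              n_sample_clusters = 3, cluster_separation = 2,
                              seed = master_seed + 3))

for (nm in names(specs)) write_synthetic_spec(specs[[nm]],
                                              file.path(out_dir, paste0(nm, "_spec.json")))

nul <- generate_null_counts(specs$null)
write_synthetic_dataset(nul, out_dir, "null")

str_d <- generate_taxon_structured_counts(specs$structured)
write_synthetic_dataset(str_d, out_dir, "structured")
writeLines(str_d$truth$hub_taxa, file.path(out_dir, "structured_hub_taxa.txt"))

tg <- generate_two_group_counts(specs$twogroup)
write_count_table(tg$counts_a, file.path(out_dir, "twogroup_counts_a.tsv"))
write_count_table(tg$counts_b, file.path(out_dir, "twogroup_counts_b.tsv"))

ent <- generate_enterotype_counts(specs$enterotype)
write_synthetic_dataset(ent, out_dir, "enterotype")

message("cohorts written to ", out_dir, ":")
message("  null        ", nrow(nul$counts), " x ", ncol(nul$counts),
        "  (zero fraction ", round(mean(nul$counts == 0), 2), ")")
message("  structured  ", nrow(str_d$counts), " x ", ncol(str_d$counts),
        "  (hubs: ", paste(str_d$truth$hub_taxa, collapse = ", "), ")")
message("  twogroup    2 x ", nrow(tg$counts_a), " x ", ncol(tg$counts_a))
message("  enterotype  ", nrow(ent$counts), " x ", ncol(ent$counts),
        "  (", length(unique(ent$truth$sample_cluster_labels)), " clusters)")
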