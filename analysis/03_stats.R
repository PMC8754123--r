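#!/usr/bin/env Rscript
# Step 3: distribution statistics.
#
# Per-order positive-rate table (with the at-least-5 ND rule), single-gene
# presence rates, and the habitat-association contingency test over the
# calls from step 2.

suppressPackageStartupMessages(library(nanclust))

calls <- read_calls("results/sac_calls.tsv")
meta <- read_metadata("results/synthetic/metadata.tsv")

rates <- positive_rates(calls, meta, rank = "order",
                        type_strains_only = TRUE)
utils::write.table(rates, "results/order_rates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(rates)

for (role in c("nanA", "nanK", "nanE")) {
  print(gene_presence_rates(role, calls, meta))
}

hab <- habitat_association(calls, meta)
cat("\nhabitat x SAC contingency table:\n")
print(hab$table)
cat(sprintf("positive rate, animal-associated: %.2f%%\n",
            hab$rates[["animal"]]))
cat(sprintf("positive rate, non-animal:        %.2f%%\n",
            hab$rates[["non_animal"]]))
cat(sprintf("two-sided Fisher p = %.4g (%d of unknown source excluded)\n",
            hab$p_value, hab$n_unknown))
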