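#!/usr/bin/env Rscript
# Stage 3: marker partition and metabolite -> enzyme mapping.
#
# The two disease marker lists are split into PD-specific, VP-specific and
# shared sets; the metabolites found significant in stage 2 are mapped to
# their biosynthesis/degradation enzymes via the shipped enzyme map.

suppressMessages(library(metaboreg))

part <- partition_markers(read_marker_list("results/inputs/markers_pd.txt"),
                          read_marker_list("results/inputs/markers_vp.txt"),
                          labels = c("PD", "VP"))
print(part)

cl <- read.delim("results/screening/classification.tsv")
sig <- cl$metabolite[cl$category != "none"]
emap <- read_enzyme_map()
enzymes <- enzymes_for_metabolites(sig, emap)
cat(sprintf("%d significant metabolites map to %d distinct enzymes\n",
            length(sig), nrow(enzymes)))
if (length(attr(enzymes, "unmapped")))
  cat("Unmapped metabolites:",
      paste(attr(enzymes, "unmapped"), collapse = ", "), "\n")

dir.create("results/sets", showWarnings = FALSE)
jsonlite::write_json(list(A_only = part$A_only, B_only = part$B_only,
                          shared = part$shared, labels = part$labels),
                     "results/sets/marker_partition.json", pretty = TRUE)
write.table(enzymes, "results/sets/enzymes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Partition and enzyme table written under results/sets/\n")
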