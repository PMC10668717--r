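#!/usr/bin/env Rscript
# Step 2 — screen and classify the sign records.
#
# Applies the genuineness screen (undocumented or suspect records are
# discarded), the C1/C2/C3 decision table, and the cross-record passes
# (scat-on-track, kill-combination, DNA-certified tracks), then stamps each
# record's monitoring year.

suppressMessages(library(wolfalps))

signs <- utils::read.csv("results/synthetic/signs.csv")
classified <- classify_signs(signs)
utils::write.csv(classified, "results/classified_signs.csv", row.names = FALSE)

cat("Validation categories:\n")
print(table(classified$category))
cat("\nBy evidence type (kept records):\n")
print(table(classified$evidence_type[classified$category != "discarded"],
            classified$category[classified$category != "discarded"]))
cat("\nWrote results/classified_signs.csv\n")
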