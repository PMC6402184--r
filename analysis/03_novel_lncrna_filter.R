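#!/usr/bin/env Rscript
## Stage 3: five-step novel-lncRNA filter cascade (length >= 200 nt,
## ORF < 300 nt, coding potential < -1, no known-transcript overlap, no
## domain pattern) on the engineered six-transcript fixture.

library(lincnet)

model <- toy_cp_model(seed = 101)
fx <- novel_cascade_fixture(model, seed = 7)
verdicts <- filter_cascade(fx$transcripts, model, tx_coords = fx$tx_coords,
                           known = fx$known, patterns = fx$patterns)
write.table(verdicts, "results/novel_verdicts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("novel lncRNAs: %d of %d candidates\n",
            sum(verdicts$verdict == "novel_lncRNA"), nrow(verdicts)))
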