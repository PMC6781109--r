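#!/usr/bin/env Rscript
# Stage 6: render the run report -- class counts, the consistency histogram
# split by methylation class, the marginal contrast table and the fitted
# model tables -- from the files the earlier stages wrote.

suppressPackageStartupMessages(library(gbmnoise))

outdir <- "results/run"
summarize_run(outdir)
cat(readLines(file.path(outdir, "report.txt")), sep = "\n")
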