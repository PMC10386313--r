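#!/usr/bin/env Rscript
# Step 5: Tukey HSD comparisons of the published macro-composition summary
# statistics (mean, SD, n = 15 per month) across the three production
# months, with compact-letter annotations.

library(pecomics)

tab <- macro_composition_table()
out <- tukey_table(tab, alpha = 0.05)

write.csv(out$pairwise, "results/tukey_pairwise.csv", row.names = FALSE)
write.csv(out$letters, "results/tukey_letters.csv", row.names = FALSE)

message("parameters with at least one significant seasonal difference:")
sig <- unique(out$pairwise$parameter[out$pairwise$significant])
print(sig)
message("compact letter display:")
print(out$letters)
message("wrote results/tukey_{pairwise,letters}.csv")
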