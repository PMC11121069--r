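#!/usr/bin/env Rscript
# Runs the full analysis chain in order.  Equivalent single call:
#   devage::run_pipeline(list(seed = 1L, out = "results/pipeline"))
for (script in sprintf("analysis/%s.R",
                       c("01_simulate", "02_junctions", "03_methylation",
                         "04_snpdm", "05_decounts")))
  source(script, echo = FALSE)
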