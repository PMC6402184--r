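#!/usr/bin/env Rscript
## Run the complete demo analysis stage by stage.  Equivalent single call:
##   lincnet::run_pipeline(lincnet::pipeline_config(seed = 7,
##                                                  out_dir = "results/demo_run"))

for (script in sort(list.files("analysis", pattern = "^0[1-8]_.*\\.R$",
                               full.names = TRUE)))
  source(script, echo = FALSE)
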