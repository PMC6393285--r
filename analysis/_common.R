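# Shared setup for the numbered analysis scripts: builds (or reloads) the
# default synthetic experiment once, caching the heavy fragment-level
# objects under scratch/ so each script stays fast. All results tables go
# under results/.

suppressMessages(library(pol3dyn))

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

default_cfg <- function(seed = 1L) sim_config(seed = seed)

# Full pipeline on the default configuration, cached across scripts.
load_pipeline <- function(seed = 1L, rebuild = FALSE) {
  cache <- file.path(SCRATCH, sprintf("pipeline_seed%d.rds", seed))
  if (!rebuild && file.exists(cache)) return(readRDS(cache))
  res <- run_pipeline(default_cfg(seed))
  saveRDS(res, cache)
  res
}
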