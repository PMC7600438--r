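# Shared setup for the numbered analysis scripts: one configuration, one
# workspace, one results directory.  Run the scripts in order from the
# repository root; each is a thin driver over the cffpipe package.

suppressMessages(library(cffpipe))

SEED <- as.integer(Sys.getenv("CFFPIPE_SEED", "1"))
CFG <- default_config(seed = SEED)
WORKSPACE <- file.path("results", "workspace")
dir.create(WORKSPACE, recursive = TRUE, showWarnings = FALSE)

say <- function(...) cat(sprintf(...), "\n")
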