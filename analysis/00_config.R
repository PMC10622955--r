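# Shared configuration for the numbered analysis scripts. Everything flows
# from ROOT_SEED; re-running 01..05 in order reproduces all tables exactly.

library(brainager)

ROOT_SEED <- 20260901L

PHANTOM <- phantom_spec()                       # 32^3 desk-scale grid, 5 mm
COHORT <- cohort_spec(n_training = 200L,        # healthy training phantoms
                      n_controls = 24L,         # study controls
                      n_patients = 70L,         # SLE-like patients
                      seed = ROOT_SEED)
TRAINING <- training_config(seed = ROOT_SEED)   # published SGD/MAE protocol
OCCLUSION <- occlusion_config()                 # 8^3 non-overlapping mask

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
dir.create(COHORT_DIR, showWarnings = FALSE, recursive = TRUE)

say <- function(...) cat(sprintf(...), "\n")
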