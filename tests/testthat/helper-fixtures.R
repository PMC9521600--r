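# Shared fixtures. The base configuration is deterministic, so it is built
# once per test run and reused read-only.
.fixtures <- new.env(parent = emptyenv())

base_cfg <- function() {
  if (is.null(.fixtures$cfg)) .fixtures$cfg <- builtin_basecase()
  .fixtures$cfg
}

DELTA_YEARS <- 42 / 365.25

# A configuration whose uncertain-parameter table is trimmed to a few rows,
# for fast sensitivity-module tests.
trimmed_cfg <- function(paths = c("treatments.lurasidone.hr_relapse_vs_quetiapine",
                                  "costs.outpatient_stable",
                                  "utilities.u_stable")) {
  cfg <- base_cfg()
  cfg$estimates <- cfg$estimates[cfg$estimates$path %in% paths, ]
  cfg
}

# Serialised text of a configuration, for before/after mutation checks.
config_text <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(cfg, f)
  readLines(f)
}
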