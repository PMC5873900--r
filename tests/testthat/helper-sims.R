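# Shared simulated studies, generated once per session and reused by the
# recovery-oriented tests (each sim writes a full miniature study to disk).

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("sim_", key))
    .sim_cache[[key]] <- simulate_study(config, dir)
  }
  .sim_cache[[key]]
}

# the default study conditions at 20 fixed seeds
default_sims <- function(seeds = 101:120) {
  lapply(seeds, function(s) {
    cached_sim(paste0("default_", s), sim_config(seed = s))
  })
}

noiseless_sims <- function(seeds = 101:120) {
  lapply(seeds, function(s) {
    cached_sim(paste0("clean_", s),
               sim_config(seed = s, jitter_sd = 0, dropout = 0))
  })
}

cached_classify <- function(key, sim) {
  ckey <- paste0("cl_", key)
  if (is.null(.sim_cache[[ckey]])) .sim_cache[[ckey]] <- classify_sim(sim)
  .sim_cache[[ckey]]
}

# classify the panel of one simulated study the way the pipeline does
classify_sim <- function(sim) suppressMessages({
  assembly <- sim$assembly
  blacklist <- read_bed(sim$paths$blacklist, assembly, label = "blacklist")
  proc <- lapply(names(sim$paths$peaks), function(su) {
    raw <- read_bed(sim$paths$peaks[[su]], assembly, label = su)
    recursive_merge(filter_blacklist(raw, blacklist))
  })
  names(proc) <- names(sim$paths$peaks)
  atpase <- sim$config$atpase
  panel <- subunit_panel(proc[[atpase]],
                         proc[setdiff(names(proc), atpase)])
  classify_peaks(panel)
})
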