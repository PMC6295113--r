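# The desk-scale replication study is expensive (~15 min), so it is run
# once per test session and shared by the acceptance test blocks.
.study_cache <- new.env(parent = emptyenv())

desk_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  cfg <- study_config("desk", seed = 20240901,
                      regression = c("none", "regress-to-A",
                                     "oracle-rescale"))
  .study_cache$study <- run_study(cfg)
  .study_cache$study
}
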