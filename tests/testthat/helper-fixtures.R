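# Shared fixtures, built in code.
fixture_assay <- function() example_assay()

# small background contig for classifier tests (distinct from the default
# 100 kb one to keep tests fast)
fixture_background <- function() synthetic_background(20000L, seed = 99L)

sim_to_reads <- function(sim) {
  data.frame(read_id = sim$read_id, sequence = sim$sequence,
             start_time = sim$start_time, stringsAsFactors = FALSE)
}

run_sim_pipeline <- function(sim, assay, background = NULL,
                             adapter = character(), seed = 5L,
                             config = lamp_config()) {
  st <- pipeline_state(assay, config, background, adapter, seed)
  pipeline_update(st, sim_to_reads(sim))
  pipeline_report(st)
}

diag_classes <- function(report)
  vapply(report$diagnoses, `[[`, character(1), "class")

diag_calls <- function(report)
  vapply(report$diagnoses, function(d)
    if (!is.null(d$consensus)) d$consensus$call else NA_character_,
    character(1))

# minimal read_diagnosis stub for reporter tests
stub_diag <- function(class = "TARGET", call = "T", start_time = NA_real_) {
  structure(list(read_id = "r", class = class,
                 consensus = if (class == "TARGET")
                   list(call = call, support = 1L, tie_broken = FALSE),
                 n_subreads = 1L, n_design_hits = 4L,
                 start_time = start_time), class = "read_diagnosis")
}
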