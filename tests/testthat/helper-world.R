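# the default synthetic world and its pipeline run are expensive (~30 s);
# build them once and share across test files
.world_cache <- new.env(parent = emptyenv())

shared_world <- function() {
  if (is.null(.world_cache$world)) {
    dir <- file.path(tempdir(), "lncorth-shared-world")
    .world_cache$world <- generate_world(world_spec(), dir)
  }
  .world_cache$world
}

shared_run <- function() {
  if (is.null(.world_cache$run)) {
    .world_cache$run <- run_pipeline(world_config(shared_world()))
  }
  .world_cache$run
}
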