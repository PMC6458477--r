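# Shared fixtures, memoised for the session: meshes and runs are expensive,
# so every test file draws on the same cached objects.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_cfg <- function() default_parameters("test")

tiny_mesh <- function() memo("tiny_mesh", function()
  generate_mesh(build_domain_spec(tiny_cfg()), tiny_cfg()$mesh))

# short coupled run on the minimal mesh: 1 ms pre-stimulus, 2 ms of TES
tiny_run <- function() memo("tiny_run", function() {
  cfg <- tiny_cfg()
  cfg$stepping$t_end <- 3
  cfg$stepping$t_tes_on <- 1
  cfg$output$checkpoint_every <- 0.5
  simulate_tes(cfg, tiny_mesh())
})

# the full default 20 ms protocol on the coarse desk-scale mesh; this is the
# run the acceptance checks measure
coarse_run <- function() memo("coarse_run", function()
  simulate_tes(default_parameters("coarse")))

site_index <- function(run, s) which.min(abs(run$pairing$s - s))
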