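# Shared fixtures: designs are expensive to solve, so the standard ones
# are computed lazily and cached for the whole test run.

.design_cache <- new.env(parent = emptyenv())

cached_design <- function(key, fn) {
  if (is.null(.design_cache[[key]])) .design_cache[[key]] <- fn()
  .design_cache[[key]]
}

design_124 <- function() cached_design("d124", function()
  vb_design(vb_params(), vb_prior()))

design_124_fine <- function() cached_design("d124f", function()
  vb_design(vb_params(), vb_prior(), dp_config(mu_grid_step = 25)))

design_248 <- function() cached_design("d248", function()
  vb_design(vb_params(t_max = 248), vb_prior(),
            dp_config(mu_grid_step = 25), thresholds = FALSE))

# a small complete synthetic cohort reused across tests
complete_cohort <- function() cached_design("cohort_complete", function()
  generate_cohort(synth_config(n_pairs = 124), seed = 421))
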