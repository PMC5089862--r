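# Shared crowded-run fixture: the eightfold-scaled synthetic cytoplasm
# composition (648 spheres, volume fraction 0.45) propagated for 1
# microsecond of Brownian dynamics at the 8 ps timestep.  Built once per
# test session on first use; the first 10% of the run is discarded as
# equilibration before analysis.
.crowded_cache <- new.env(parent = emptyenv())

crowded_fixture <- function() {
  if (!is.null(.crowded_cache$traj)) return(.crowded_cache$traj)
  tab <- synthetic_cytoplasm(scale_factor = 8)
  box <- synthetic_cytoplasm_box(scale_factor = 8)
  sys <- gen_packed_configuration(tab, box, seed = 11)
  bd <- bd_params(timestep = 8, steps = 125000, output_stride = 125,
                  seed = 12)
  tr <- run_simulation(sys, bd)
  keep <- which(tr$times >= 0.1 * max(tr$times))
  tr <- trajectory(tr$times[keep], tr$coords[keep, , , drop = FALSE],
                   tr$species_index, tr$table, tr$box, wrapped = FALSE)
  .crowded_cache$traj <- tr
  tr
}

crowded_species_diffusion <- function() {
  if (is.null(.crowded_cache$sd))
    .crowded_cache$sd <- species_diffusion(crowded_fixture(),
                                           tau_max = 1e5, dt_i = 1000)
  .crowded_cache$sd
}
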