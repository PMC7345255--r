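# reduced-scale in-silico recovery experiment shared by the heavier
# acceptance checks: one specimen per seed, macroscale Nelder-Mead fit,
# then per-window mesoscale identification on the nV = 6 grid

run_reduced_recovery <- function(seed, windows = 1:4, Ns = 50,
                                 solver = "fixed_point", ...) {
  adm <- reduced_admissible()
  ex <- generate_specimen(experiment_config(seed = seed))
  mac <- identify_macro(strain_from_displacement(ex$macro$grid, ex$macro),
                        ex$macro$grid, ex$load, c(10, 4))
  fits <- lapply(windows, function(q) {
    bs <- elastid:::seed_for(seed, 100 + q)
    if (solver == "fixed_point")
      fixed_point_identify(ex$windows[[q]], mac$moduli, adm, Ns,
                           base_seed = bs, ...)
    else
      genetic_identify(ex$windows[[q]], mac$moduli, adm, Ns,
                       base_seed = bs, ...)
  })
  list(adm = adm, experiment = ex, mac = mac, fits = fits)
}
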