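# shared fixtures: small random SPD Kelvin matrices, reference moduli and
# the reduced-scale admissible box used by the recovery experiments

random_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  (A + t(A)) / 2 + n * diag(n)
}

random_stiffness <- function(seed, form = "full3d") {
  n <- if (form == "full3d") 6 else 3
  elastic_tensor(random_spd(n, seed), "stiffness", form)
}

# reference moduli pairs of the validation studies (GPa)
REF_2D_MACRO <- c(kappa = 13.901, mu = 3.685)   # E 10.158, nu 0.3782
REF_3D_MACRO <- c(kappa = 138.783, mu = 64.355) # E 167.218, nu 0.2992
REF_BONE_MACRO <- c(kappa = 11.335, mu = 4.781) # E 12.575, nu 0.3151
REF_2D_MESO <- c(delta = 0.40, ell = 125e-6, kappa = 13.75, mu = 3.587)

# per-window identified values of the 2D validation (fixed-point solver)
TABLE_FP_DELTA <- c(0.306, 0.500, 0.417, 0.417, 0.444, 0.417, 0.361, 0.361,
                    0.444, 0.333, 0.333, 0.389, 0.389, 0.389, 0.389, 0.361)
TABLE_FP_ELL <- c(147.778, 224.444, 122.222, 122.222, 147.778, 122.222,
                  147.778, 147.778, 147.778, 147.778, 122.222, 96.667,
                  147.778, 122.222, 147.778, 122.222)
TABLE_FP_NQ <- c(3, 4, 3, 3, 3, 4, 4, 4, 3, 4, 4, 3, 4, 3, 4, 4)
TABLE_GA_NQ <- c(193, 202, 189, 197, 207, 201, 192, 199, 210, 205, 203,
                 198, 194, 208, 190, 208)
TABLE_3D_DELTA <- c(0.311, 0.367, 0.311)
TABLE_3D_ELL <- c(65.556, 88.889, 81.111)
TABLE_3D_NQ <- c(3, 4, 3)

# admissible box of the reduced-scale recovery experiment: the reference
# truth lies on every nV = 6 grid
reduced_admissible <- function()
  admissible_set(delta = c(0.25, 0.50), ell = c(75e-6, 200e-6),
                 kappa = c(12.5, 15.625), mu = c(3.087, 4.337), nV = 6L)

snap_to_grid <- function(b, adm)
  mapply(function(nm) adm$grids[[nm]][which.min(abs(adm$grids[[nm]] - b[[nm]]))],
         names(adm$grids))
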