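# shared fixtures, built lazily and cached for the whole test run

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# small sphere packing (fast to build, still dense)
fix_spheres_small <- function() {
  fix_get("spheres_small", function()
    buildSphereSubstrate(nSpheres = 60, diameter = 5e-6,
                         packingFraction = 0.55, seed = 42))
}

# full-size yeast-like packing
fix_spheres_full <- function() {
  fix_get("spheres_full", function() buildSphereSubstrate(seed = 1))
}

fix_cylinders <- function() {
  fix_get("cylinders", function() buildCylinderSubstrate(seed = 1))
}

# a quick impermeable sphere ensemble shared by acquisition tests
fix_ens_spheres_p0 <- function() {
  fix_get("ens_spheres_p0", function() {
    wp <- walkParams(nWalkers = 2500, nSteps = 1500, duration = 0.4,
                     transitProb = 0, seed = 7)
    simulateWalk(fix_spheres_small(), wp)
  })
}

# free-diffusion ensemble long enough for a DEXSY sequence
fix_ens_free <- function() {
  fix_get("ens_free", function() {
    wp <- walkParams(nWalkers = 4000, nSteps = 1500, duration = 0.4,
                     transitProb = 0, seed = 8)
    simulateWalk(NULL, wp)
  })
}

# wrap a plain signal matrix into a SignalMatrix object
make_signal_matrix <- function(S, G, delta = 0.015, Delta = 0.017,
                               tm = 0.1, se = matrix(0, 0, 0)) {
  b <- bValue(G, delta, Delta)
  new("SignalMatrix", values = S, G1 = G, G2 = G, b1 = b, b2 = b,
      delta = rep(delta, 2), Delta = rep(Delta, 2), tm = tm,
      gamma = dexsim::GAMMA_H, direction = c(1, 0, 0), se = se,
      meta = list())
}

# noiseless synthetic DEXSY matrix for a given component spectrum
synth_matrix <- function(weights, D1, D2, nG = 16, Gmax = 0.9) {
  G <- seq(0, Gmax, length.out = nG)
  b <- bValue(G, 0.015, 0.017)
  make_signal_matrix(forwardSignal(weights, D1, D2, b, b), G)
}
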