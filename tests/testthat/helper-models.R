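# shared fixture builders; everything is generated in code

# single delayed circuit with fast dynamics (seconds-to-minutes horizon)
fastDelayedModel <- function(cTilde = 0.75, enzyme = 2, ...) {
  circuitModel(linkerCircuit("AB", 0.6, 1, cTilde = cTilde,
                             delayed = cTilde > 0),
               enzyme = enzyme, kCat = 2e-3, ...)
}

uniformDmap <- function(d) {
  diffusionMap(dInside = c(trigger = d, inhibited = d, rna = d, linker = d),
               dOutside = c(trigger = d, inhibited = d, rna = d, linker = d))
}

# small-domain grid for oracle comparisons
smallGrid <- function(n = 8, spacing = 2.5, radius = 6)
  gridSpec(n, n, spacing, radius)

# per-species totals that must be conserved along a trajectory
triggerTotals <- function(traj, label) {
  s <- traj@states
  sapply(1:2, function(i) {
    s[, paste0("T.", label, ".", i)] + s[, paste0("iT.", label, ".", i)] +
      s[, paste0("Sb.", label, ".", i)] + s[, paste0("Sd.", label, ".", i)]
  })
}

inhibitorTotals <- function(traj, label) {
  s <- traj@states
  sapply(1:2, function(i) {
    s[, paste0("R.", label, ".", i)] + s[, paste0("iT.", label, ".", i)]
  })
}
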