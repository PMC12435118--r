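# Exhaustive NNLS oracle: the constrained optimum equals the best objective
# over all supports whose unconstrained least-squares solution is feasible
# (non-negative).  Tractable for <= 8 atoms; independent of the active-set
# solver it checks.
nnls_enumeration_oracle <- function(A, y) {
  n <- ncol(A)
  best <- sum(y^2)  # empty support
  for (k in seq_len(n)) {
    cmb <- utils::combn(n, k)
    for (ci in seq_len(ncol(cmb))) {
      S <- cmb[, ci]
      z <- tryCatch(qr.coef(qr(A[, S, drop = FALSE]), y),
                    error = function(e) NULL)
      if (is.null(z) || anyNA(z) || any(z < 0)) next
      r <- y - A[, S, drop = FALSE] %*% z
      best <- min(best, sum(r^2))
    }
  }
  best
}

# nearest dictionary atom for each requested diffusivity
snap_to_atoms <- function(dictionary, dcs) {
  vapply(dcs, function(x)
    dictionary$atoms[which.min(abs(dictionary$atoms - x))], numeric(1))
}

# compartment set with explicit values (bypasses random sampling)
fixed_compartments <- function(dcs, amps) {
  structure(list(dcs = dcs, amps = amps, n = length(dcs)),
            class = "compartment_set")
}

# spectrum with explicit amplitudes over a dictionary
fixed_spectrum <- function(dictionary, amplitudes, residual_norm = 0) {
  structure(list(dictionary = dictionary, amplitudes = amplitudes,
                 residual_norm = residual_norm),
            class = "sda_spectrum")
}
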