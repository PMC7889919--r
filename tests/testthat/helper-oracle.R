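# Independent 2x2 transfer-matrix oracle for stratified normal-incidence
# plane waves. Formulated as interface/propagation matrix products acting on
# (forward, backward) amplitude pairs -- a different derivation path from the
# package's cascade-reflection recursion, kept deliberately separate.

# eps: complex permittivities including ambient (first) and terminal (last);
# h: thicknesses of the interior layers (length = length(eps) - 2); f in Hz.
tm_oracle <- function(eps, h, frequency, c0 = 299792458) {
  n <- sqrt(as.complex(eps))
  n[Re(n) < 0] <- -n[Re(n) < 0]
  k0 <- 2 * pi * frequency / c0
  k <- k0 * n
  N <- length(eps)
  stopifnot(length(h) == N - 2)

  iface <- function(na, nb) {
    t <- 2 * na / (na + nb)
    r <- (na - nb) / (na + nb)
    matrix(c(1, r, r, 1), 2, 2) / t
  }
  prop <- function(kk, hh) diag(c(exp(1i * kk * hh), exp(-1i * kk * hh)))

  # M maps the (forward, backward) pair at the terminal-layer top to the
  # ambient pair at the first interface: M = I1 P2 I2 P3 ... I_{N-1}
  M <- iface(n[1], n[2])
  if (N > 2) {
    for (j in 2:(N - 1)) {
      M <- M %*% prop(k[j], h[j - 1]) %*% iface(n[j], n[j + 1])
    }
  }
  R0 <- M[2, 1] / M[1, 1]

  # field at global depth z >= 0 (z = 0 at the ambient/first interface),
  # relative to the incident forward amplitude
  bounds <- c(0, cumsum(h))
  field <- function(z) {
    vapply(z, function(zz) {
      li <- min(max(findInterval(zz, bounds, left.open = TRUE), 1L) + 1L, N)
      amp <- c(1 + 0i, R0)                 # ambient pair at interface 1
      ztop <- 0
      for (j in 2:N) {
        amp <- solve(iface(n[j - 1], n[j]), amp)   # pair at top of layer j
        if (j == li) {
          zeta <- zz - ztop
          return(amp[1] * exp(-1i * k[j] * zeta) +
                 amp[2] * exp(1i * k[j] * zeta))
        }
        amp <- c(amp[1] * exp(-1i * k[j] * h[j - 1]),
                 amp[2] * exp(1i * k[j] * h[j - 1]))
        ztop <- ztop + h[j - 1]
      }
      stop("unreachable")
    }, complex(1))
  }
  list(R0 = R0, TC = 1 - Mod(R0)^2, field = field)
}

# random lossy stack with n_layers tissue layers (terminal semi-infinite)
random_stack <- function(n_layers) {
  eps <- complex(real = runif(n_layers, 2, 50),
                 imaginary = -runif(n_layers, 0.1, 20))
  # interior thicknesses capped so the field stays well above round-off at
  # every sampled depth (keeps relative comparisons meaningful)
  h <- runif(max(n_layers - 1, 0), 0.05e-3, 1.5e-3)
  layers <- lapply(seq_len(n_layers), function(i) {
    tissue_layer(paste0("L", i), if (i < n_layers) h[i] else Inf, eps[i],
                 lambda = 0.4, rho = 1000,
                 perfusion = if (i == n_layers) 2000 else 0)
  })
  tissue_stack(layers, layers, 26e9)
}

# EM-view geometry of a stack as plain vectors for the oracle
stack_eps_h <- function(stack, eps_ambient = 1 + 0i) {
  eps <- c(eps_ambient, vapply(stack$em, function(l) l$eps, complex(1)))
  h <- vapply(stack$em, function(l) l$thickness, numeric(1))
  list(eps = eps, h = h[is.finite(h)])
}
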