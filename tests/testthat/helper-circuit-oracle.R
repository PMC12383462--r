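# Independent brute-force circuit oracle: every gate is embedded as a full
# 2^n x 2^n matrix built elementwise from bit arithmetic, and the circuit is
# the ordinary matrix product applied to |0...0>. Deliberately shares no code
# with simulate_statevector().

oracle_gate_matrix <- function(gate, params) {
  th <- if (length(params)) params[1] else NA_real_
  switch(gate,
    H = matrix(c(1, 1, 1, -1), 2) / sqrt(2),
    RX = matrix(c(cos(th / 2), -1i * sin(th / 2),
                  -1i * sin(th / 2), cos(th / 2)), 2),
    RZ = diag(c(exp(-1i * th / 2), exp(1i * th / 2))),
    # two-qubit matrices: sub-bit 0 is the FIRST listed qubit
    RZZ = diag(exp(-1i * th / 2 * c(1, -1, -1, 1))),
    CRZ = diag(c(1, exp(-1i * th / 2), 1, exp(1i * th / 2))),
    CNOT = {
      m <- matrix(0, 4, 4)
      m[1, 1] <- 1; m[3, 3] <- 1 # control (sub-bit 0) clear
      m[2, 4] <- 1; m[4, 2] <- 1 # control set: flip sub-bit 1
      m
    }
  )
}

oracle_embed <- function(u, qubits, n) {
  dim <- 2L^n
  i <- rep(0:(dim - 1L), times = dim)
  j <- rep(0:(dim - 1L), each = dim)
  mask <- sum(2L^qubits)
  same_rest <- bitwAnd(i, bitwNot(mask)) == bitwAnd(j, bitwNot(mask))
  sub <- function(x) {
    s <- integer(length(x))
    for (m in seq_along(qubits)) {
      s <- s + bitwAnd(bitwShiftR(x, qubits[m]), 1L) * 2L^(m - 1L)
    }
    s
  }
  vals <- u[cbind(sub(i) + 1L, sub(j) + 1L)]
  vals[!same_rest] <- 0
  matrix(vals, dim, dim)
}

oracle_statevector <- function(spec) {
  dim <- 2L^spec$n_qubits
  psi <- complex(dim)
  psi[1] <- 1 + 0i
  for (r in seq_len(nrow(spec$gates))) {
    m <- oracle_embed(
      oracle_gate_matrix(spec$gates$gate[[r]], spec$gates$params[[r]]),
      spec$gates$qubits[[r]], spec$n_qubits)
    psi <- as.vector(m %*% psi)
  }
  psi
}

# CRZ in oracle convention: sub-bit 0 = control, sub-bit 1 = target.
# basis order (target, control): 00, 01(c=1), 10(t=1), 11.
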