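#' Gate operations and circuit specifications
#'
#' A `circuit_spec` is an ordered list of gates on `n_qubits` qubits, stored
#' as a tibble with columns `gate` (name), `params` (list of numeric angle
#' vectors, radians) and `qubits` (list of 0-based ordered qubit indices).
#' Supported gates: `H`, `RX`, `RZ` (phase convention
#' `diag(exp(-i theta/2), exp(+i theta/2))`), `RZZ`
#' (`exp(-i theta/2 Z (x) Z)`), `CRZ` (control first, RZ on target when the
#' control is 1) and `CNOT` (control first).
#'
#' @param gate Gate name.
#' @param qubits 0-based qubit indices (control first for two-qubit gates).
#' @param params Numeric angle parameters (radians).
#' @return `gate_op()` returns a one-row gate tibble; `circuit_spec()` an
#'   object of class `circuit_spec`.
#' @export
gate_op <- function(gate, qubits, params = numeric(0)) {
  arity <- c(H = 1L, RX = 1L, RZ = 1L, RZZ = 2L, CRZ = 2L, CNOT = 2L)
  nparam <- c(H = 0L, RX = 1L, RZ = 1L, RZZ = 1L, CRZ = 1L, CNOT = 0L)
  if (!gate %in% names(arity)) {
    abort_domain(sprintf("unknown gate `%s`.", gate))
  }
  qubits <- as.integer(qubits)
  if (length(qubits) != arity[[gate]] || anyNA(qubits) || any(qubits < 0) ||
      anyDuplicated(qubits)) {
    abort_domain(sprintf(
      "gate `%s` needs %d distinct nonnegative qubit indices.",
      gate, arity[[gate]]))
  }
  if (length(params) != nparam[[gate]]) {
    abort_domain(sprintf("gate `%s` needs %d parameter(s).",
                         gate, nparam[[gate]]))
  }
  check_finite(c(params, 0), "params")
  tibble::tibble(gate = gate, params = list(as.numeric(params)),
                 qubits = list(qubits))
}

#' @rdname gate_op
#' @param n_qubits Number of qubits.
#' @param gates A tibble of gate rows (rbind of [gate_op()] rows).
#' @param label Free-text label.
#' @export
circuit_spec <- function(n_qubits, gates, label = "") {
  n_qubits <- check_count(n_qubits, "n_qubits")
  gates <- dplyr::bind_rows(gates)
  if (nrow(gates) > 0) {
    maxq <- max(purrr::map_int(gates$qubits, max))
    if (maxq >= n_qubits) abort_domain("gate qubit index out of range.")
  }
  structure(list(n_qubits = n_qubits, gates = gates, label = label),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> '%s': %d qubits, %d gates\n",
              x$label, x$n_qubits, nrow(x$gates)))
  invisible(x)
}

#' Trotterized single-neuron circuit (plain-RZ form)
#'
#' The canonical low-depth neuron circuit: an initial Hadamard layer
#' (uniform superposition over voltage bins), then `n_steps` Trotter steps,
#' each a Hadamard layer (kinetic surrogate) followed by per-qubit phase
#' gates `RZ(angle_scale / 2^i)` on qubit `i` (potential surrogate). With
#' the defaults (3 qubits, 10 steps, `angle_scale = 0.1 * pi`) this is 63
#' gates with RZ angles 0.31416, 0.15708, 0.07854. Note this circuit
#' contains no entangling gate, so its exact outcome distribution always
#' factorises over bits (see [product_structure_test()]).
#'
#' @param n_steps Number of Trotter steps (>= 0).
#' @param angle_scale Base RZ angle; qubit `i` receives `angle_scale / 2^i`.
#' @param n_qubits Number of qubits.
#' @return A `circuit_spec`.
#' @examples
#' build_neuron_circuit() # 63 gates
#' @export
build_neuron_circuit <- function(n_steps = 10L, angle_scale = pi * 0.1,
                                 n_qubits = 3L) {
  n_steps <- check_count(n_steps, "n_steps", min = 0L)
  n_qubits <- check_count(n_qubits, "n_qubits")
  check_scalar(angle_scale, "angle_scale")
  g <- list()
  h_layer <- lapply(0:(n_qubits - 1), function(q) gate_op("H", q))
  g <- c(g, h_layer)
  for (s in seq_len(n_steps)) {
    g <- c(g, h_layer)
    g <- c(g, lapply(0:(n_qubits - 1), function(q) {
      gate_op("RZ", q, angle_scale / 2^q)
    }))
  }
  circuit_spec(n_qubits, g, label = sprintf("trotter_neuron_%dsteps", n_steps))
}

#' Trotterized neuron circuit with controlled-RZ potential layers
#'
#' Variant of [build_neuron_circuit()] in which each potential layer is a
#' set of CRZ gates given by `control_pattern` instead of plain RZ gates.
#' The CRZ angle on pair `(control, target)` is `angle_scale / 2^target`,
#' mirroring the per-qubit scaling of the plain form. An empty pattern
#' reduces exactly to [build_neuron_circuit()]. Any nonempty pattern makes
#' the circuit entangling, so its outcome distribution need not factorise
#' over bits.
#'
#' @inheritParams build_neuron_circuit
#' @param control_pattern List of `c(control, target)` integer pairs applied
#'   (in order) in every Trotter step.
#' @return A `circuit_spec`.
#' @examples
#' build_crz_variant(control_pattern = list(c(0, 1), c(1, 2)))
#' @export
build_crz_variant <- function(n_steps = 10L, angle_scale = pi * 0.1,
                              control_pattern = list(), n_qubits = 3L) {
  n_steps <- check_count(n_steps, "n_steps", min = 0L)
  n_qubits <- check_count(n_qubits, "n_qubits")
  for (p in control_pattern) {
    if (length(p) != 2 || p[1] == p[2]) {
      abort_domain("`control_pattern` entries must be distinct (control, target) pairs.")
    }
  }
  if (length(control_pattern) == 0) {
    out <- build_neuron_circuit(n_steps, angle_scale, n_qubits)
    out$label <- sprintf("crz_neuron_%dsteps", n_steps)
    return(out)
  }
  g <- list()
  h_layer <- lapply(0:(n_qubits - 1), function(q) gate_op("H", q))
  g <- c(g, h_layer)
  for (s in seq_len(n_steps)) {
    g <- c(g, h_layer)
    g <- c(g, lapply(control_pattern, function(p) {
      gate_op("CRZ", p, angle_scale / 2^p[2])
    }))
  }
  circuit_spec(n_qubits, g, label = sprintf("crz_neuron_%dsteps", n_steps))
}

#' Variational single-neuron circuit skeleton
#'
#' Fixed-parameter three-qubit skeleton with registers
#' (q0 = membrane potential, q1 = recovery, q2 = noise ancilla):
#' `H(q0)`, `RX(theta1, q1)`, `RZZ(theta2, q0, q1)`, `RX(noise_amp, q2)`,
#' `CRZ(control_phi, q2 -> q0)`. Exactly these five gates, in order;
#' measurement is handled by [measurement_probabilities()], not by a gate.
#' No optimisation loop is attached: the parameters are fixed inputs.
#'
#' @param theta1 Recovery-register rotation (radians).
#' @param theta2 Voltage-recovery ZZ coupling angle.
#' @param noise_amp Noise-ancilla rotation.
#' @param control_phi Conditional phase from the ancilla onto the voltage
#'   register.
#' @return A `circuit_spec` on 3 qubits.
#' @export
build_variational_neuron <- function(theta1, theta2, noise_amp, control_phi) {
  check_scalar(theta1, "theta1")
  check_scalar(theta2, "theta2")
  check_scalar(noise_amp, "noise_amp")
  check_scalar(control_phi, "control_phi")
  circuit_spec(3L, list(
    gate_op("H", 0L),
    gate_op("RX", 1L, theta1),
    gate_op("RZZ", c(0L, 1L), theta2),
    gate_op("RX", 2L, noise_amp),
    gate_op("CRZ", c(2L, 0L), control_phi)
  ), label = "variational_neuron")
}

#' Two-neuron network with an entangling synaptic coupling
#'
#' Places circuit `neuron_a` on qubits `0..nA-1` and `neuron_b` on qubits
#' `nA..nA+nB-1`, then applies a single `CRZ(coupling_angle)` from A's
#' designated output qubit to B's designated input qubit — the minimal
#' coherent stand-in for a synapse (influence without measurement). With
#' `coupling_angle = 0` the final state is exactly the tensor product of the
#' two single-neuron states.
#'
#' @param neuron_a,neuron_b `circuit_spec`s for the two neurons.
#' @param coupling_angle CRZ angle of the synaptic link (radians).
#' @param output_qubit 0-based qubit of `neuron_a` acting as its output.
#' @param input_qubit 0-based qubit of `neuron_b` receiving the coupling.
#' @return A `circuit_spec` on `nA + nB` qubits (6 for two default neurons).
#' @examples
#' net <- build_coupled_network(build_neuron_circuit(), build_neuron_circuit(),
#'                              coupling_angle = pi / 2)
#' net$n_qubits # 6
#' @export
build_coupled_network <- function(neuron_a, neuron_b, coupling_angle,
                                  output_qubit = 0L, input_qubit = 0L) {
  stopifnot(inherits(neuron_a, "circuit_spec"),
            inherits(neuron_b, "circuit_spec"))
  check_scalar(coupling_angle, "coupling_angle")
  output_qubit <- check_count(output_qubit, "output_qubit", min = 0L)
  input_qubit <- check_count(input_qubit, "input_qubit", min = 0L)
  if (output_qubit >= neuron_a$n_qubits || input_qubit >= neuron_b$n_qubits) {
    abort_domain("designated output/input qubit outside its register.")
  }
  shift <- function(gates, by) {
    gates$qubits <- lapply(gates$qubits, function(q) q + by)
    gates
  }
  gates <- dplyr::bind_rows(
    neuron_a$gates,
    shift(neuron_b$gates, neuron_a$n_qubits),
    gate_op("CRZ", c(output_qubit, neuron_a$n_qubits + input_qubit),
            coupling_angle)
  )
  circuit_spec(neuron_a$n_qubits + neuron_b$n_qubits, gates,
               label = "coupled_network")
}

#' Serialise circuits to JSON and OpenQASM 2.0
#'
#' `circuit_to_json()` / `circuit_from_json()` round-trip a `circuit_spec`
#' bit-exactly (angles written at full precision). `export_qasm()` writes
#' OpenQASM 2.0 using the qelib1 gates `h`, `rx`, `rz`, `rzz`, `crz`, `cx`.
#'
#' @param spec A `circuit_spec`.
#' @param path Optional file path; if `NULL` the text is returned.
#' @return JSON / QASM text (invisibly when written to `path`).
#' @export
circuit_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  obj <- list(
    n_qubits = spec$n_qubits,
    label = spec$label,
    gates = purrr::pmap(spec$gates, function(gate, params, qubits) {
      list(gate = gate, params = as.list(params), qubits = as.list(qubits))
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname circuit_to_json
#' @param json JSON text or a file path containing it.
#' @export
circuit_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyVector = FALSE)
  gates <- lapply(obj$gates, function(g) {
    gate_op(g$gate, unlist(g$qubits), as.numeric(unlist(g$params)))
  })
  if (length(gates) == 0) gates <- list()
  circuit_spec(obj$n_qubits, gates, label = obj$label %||% "")
}

#' @rdname circuit_to_json
#' @export
export_qasm <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c("OPENQASM 2.0;", "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", spec$n_qubits))
  body <- purrr::pmap_chr(spec$gates, function(gate, params, qubits) {
    switch(gate,
      H = sprintf("h q[%d];", qubits[1]),
      RX = sprintf("rx(%s) q[%d];", fmt(params[1]), qubits[1]),
      RZ = sprintf("rz(%s) q[%d];", fmt(params[1]), qubits[1]),
      RZZ = sprintf("rzz(%s) q[%d],q[%d];", fmt(params[1]), qubits[1], qubits[2]),
      CRZ = sprintf("crz(%s) q[%d],q[%d];", fmt(params[1]), qubits[1], qubits[2]),
      CNOT = sprintf("cx q[%d],q[%d];", qubits[1], qubits[2])
    )
  })
  txt <- c(lines, body)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
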