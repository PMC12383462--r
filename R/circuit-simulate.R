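#' Dense statevector simulation of a circuit
#'
#' Applies the gate list of a `circuit_spec` sequentially to the
#' computational basis state \eqn{|0\ldots0\rangle}, keeping the full
#' \eqn{2^n} complex amplitude vector. Qubit 0 is the least significant bit
#' of the basis index (little-endian). Capacity is capped at 12 qubits.
#'
#' @param spec A `circuit_spec`.
#' @return A `statevector`: complex vector of length `2^n` with attributes
#'   `n_qubits` and `bit_order = "little"`.
#' @examples
#' sv <- simulate_statevector(build_neuron_circuit())
#' sum(Mod(sv)^2)
#' @export
simulate_statevector <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  n <- spec$n_qubits
  if (n > 12L) abort_domain("dense simulation is capped at 12 qubits.")
  dim <- 2L^n
  psi <- complex(dim)
  psi[1] <- 1 + 0i
  idx <- 0:(dim - 1L)

  bit <- function(q) bitwAnd(bitwShiftR(idx, q), 1L)

  for (r in seq_len(nrow(spec$gates))) {
    gate <- spec$gates$gate[[r]]
    th <- spec$gates$params[[r]]
    qs <- spec$gates$qubits[[r]]
    if (gate %in% c("H", "RX")) {
      u <- if (gate == "H") {
        matrix(c(1, 1, 1, -1), 2) / sqrt(2)
      } else {
        matrix(c(cos(th / 2), -1i * sin(th / 2),
                 -1i * sin(th / 2), cos(th / 2)), 2)
      }
      q <- qs[1]
      lo <- which(bit(q) == 0L)
      hi <- lo + 2L^q
      a0 <- psi[lo]
      a1 <- psi[hi]
      psi[lo] <- u[1, 1] * a0 + u[1, 2] * a1
      psi[hi] <- u[2, 1] * a0 + u[2, 2] * a1
    } else if (gate == "RZ") {
      b <- bit(qs[1])
      psi <- psi * exp(1i * th / 2 * (2 * b - 1))
    } else if (gate == "RZZ") {
      z <- (1 - 2 * bit(qs[1])) * (1 - 2 * bit(qs[2])) # +1 if bits equal
      psi <- psi * exp(-1i * th / 2 * z)
    } else if (gate == "CRZ") {
      ctrl <- bit(qs[1])
      b <- bit(qs[2])
      psi <- psi * exp(1i * th / 2 * (2 * b - 1) * ctrl)
    } else if (gate == "CNOT") {
      ctrl <- bit(qs[1])
      flipped <- ifelse(ctrl == 1L, bitwXor(idx, 2L^qs[2]), idx)
      psi <- psi[flipped + 1L]
    }
  }
  structure(psi, n_qubits = n, bit_order = "little", class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("<statevector> %d qubits (%s-endian), norm = %.10f\n",
              attr(x, "n_qubits"), attr(x, "bit_order"),
              sum(Mod(x)^2)))
  invisible(x)
}

basis_labels <- function(n_qubits, order = c("little", "big")) {
  order <- match.arg(order)
  idx <- 0:(2L^n_qubits - 1L)
  chars <- vapply(idx, function(i) {
    bits <- bitwAnd(bitwShiftR(i, (n_qubits - 1L):0L), 1L)
    paste(bits, collapse = "")
  }, character(1))
  # little-endian labels: rightmost character is qubit 0 (the usual binary
  # expansion of the index). big-endian reverses each string.
  if (order == "big") chars <- vapply(strsplit(chars, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
  chars
}

#' Measurement probabilities of a statevector
#'
#' Exact Born probabilities \eqn{|a_i|^2} per basis label. Label conventions
#' are explicit: `"little"` (default) writes the basis index in binary with
#' qubit 0 as the rightmost character; `"big"` reverses the strings.
#' Switching convention permutes labels without changing any value.
#'
#' @param state A `statevector`.
#' @param label_order `"little"` or `"big"`.
#' @return A `prob_table`: tibble (`state`, `probability`) with attributes
#'   `n_qubits`, `bit_order`.
#' @examples
#' measurement_probabilities(simulate_statevector(build_neuron_circuit()))
#' @export
measurement_probabilities <- function(state, label_order = c("little", "big")) {
  stopifnot(inherits(state, "statevector"))
  label_order <- match.arg(label_order)
  p <- Mod(unclass(state))^2
  if (abs(sum(p) - 1) > 1e-9) {
    abort_domain("statevector is not normalised to within 1e-9.")
  }
  new_prob_table(basis_labels(attr(state, "n_qubits"), label_order), p,
                 attr(state, "n_qubits"), label_order)
}

new_prob_table <- function(labels, p, n_qubits, bit_order) {
  out <- tibble::tibble(state = labels, probability = p)
  class(out) <- c("prob_table", class(out))
  attr(out, "n_qubits") <- n_qubits
  attr(out, "bit_order") <- bit_order
  out
}

#' Build a probability table from printed values
#'
#' Convenience constructor for entering a published outcome table (e.g. to
#' run [product_structure_test()] on it). Probabilities are validated to be
#' nonnegative and to sum to 1 within `tol` (renormalised exactly).
#'
#' @param states Character bitstring labels covering all `2^n` outcomes.
#' @param probabilities Nonnegative values summing to ~1 (percent accepted:
#'   values summing to ~100 are divided by 100).
#' @param bit_order Label convention tag.
#' @param tol Tolerance on the sum.
#' @return A `prob_table`.
#' @examples
#' prob_table(c("00", "01", "10", "11"), c(0.25, 0.25, 0.25, 0.25))
#' @export
prob_table <- function(states, probabilities, bit_order = "little",
                       tol = 0.02) {
  if (length(states) != length(probabilities)) {
    abort_domain("`states` and `probabilities` lengths differ.")
  }
  n_qubits <- nchar(states[1])
  if (length(states) != 2^n_qubits || anyDuplicated(states)) {
    abort_domain("`states` must enumerate all 2^n distinct outcomes.")
  }
  check_finite(probabilities, "probabilities")
  if (any(probabilities < 0)) abort_domain("probabilities must be >= 0.")
  s <- sum(probabilities)
  if (abs(s - 100) < 100 * tol) probabilities <- probabilities / 100
  s <- sum(probabilities)
  if (abs(s - 1) > tol) {
    abort_domain(sprintf("probabilities sum to %.4f, not 1.", s))
  }
  ord <- order(strtoi(states, base = 2L))
  new_prob_table(states[ord], (probabilities / s)[ord],
                 as.integer(n_qubits), bit_order)
}

#' Sample measurement shots from a probability table
#'
#' Seeded multinomial sampling emulating a finite-shot histogram workflow.
#'
#' @param probs A `prob_table` (or a `statevector`, converted internally).
#' @param shots Number of shots.
#' @param seed Integer seed.
#' @return A tibble (`state`, `count`, `frequency`).
#' @export
sample_measurements <- function(probs, shots, seed) {
  if (inherits(probs, "statevector")) {
    probs <- measurement_probabilities(probs)
  }
  stopifnot(inherits(probs, "prob_table"))
  shots <- check_count(shots, "shots")
  set.seed(check_count(seed, "seed", min = 0L))
  counts <- as.vector(stats::rmultinom(1, shots, probs$probability))
  tibble::tibble(state = probs$state, count = counts,
                 frequency = counts / shots)
}

#' Test a full outcome distribution for bitwise product structure
#'
#' A circuit with no entangling gate produces outcome probabilities that
#' factorise over bits exactly. This diagnostic checks every conditional
#' 2x2 odds ratio implied by such factorisation: for each qubit pair
#' `(i, j)` and each assignment `c` of the remaining bits,
#' \deqn{OR = \frac{P(0_i 0_j, c)\,P(1_i 1_j, c)}{P(0_i 1_j, c)\,P(1_i 0_j, c)}}
#' must equal 1. For strictly positive tables, all such ratios being 1 is
#' equivalent to full factorisation. Contexts where all four probabilities
#' are below `zero_tol` are skipped as uninformative; a context with a zero
#' denominator but nonzero numerator (or vice versa) is degenerate and
#' flagged as non-product.
#'
#' @param probs A `prob_table` covering all `2^n` outcomes.
#' @param tol Tolerance on `|OR - 1|` for the product verdict.
#' @param zero_tol Probabilities below this are treated as structural zeros.
#' @return A list: `is_product_over_bits` (flag), `worst_odds_ratio`
#'   (largest of `max(OR, 1/OR)` over all testable contexts; `Inf` when
#'   degenerate), `n_ratios` tested.
#' @examples
#' pt <- measurement_probabilities(simulate_statevector(build_neuron_circuit()))
#' product_structure_test(pt)
#' @export
product_structure_test <- function(probs, tol = 1e-10, zero_tol = 1e-14) {
  stopifnot(inherits(probs, "prob_table"))
  n <- attr(probs, "n_qubits")
  if (nrow(probs) != 2^n) abort_domain("incomplete probability table.")
  # work on basis-index order regardless of label convention
  ord <- order(strtoi(probs$state, base = 2L))
  p <- probs$probability[ord]
  if (attr(probs, "bit_order") == "big") {
    # reorder so index bit q equals qubit q
    idx <- strtoi(vapply(strsplit(probs$state[ord], ""), function(s) {
      paste(rev(s), collapse = "")
    }, character(1)), base = 2L)
    p[idx + 1L] <- p
  }
  idx <- 0:(2^n - 1L)
  worst <- 1
  degenerate <- FALSE
  n_ratios <- 0L
  for (i in 0:(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      base <- idx[bitwAnd(idx, 2L^i) == 0L & bitwAnd(idx, 2L^j) == 0L]
      p00 <- p[base + 1L]
      p01 <- p[base + 2L^i + 1L] # bit i set
      p10 <- p[base + 2L^j + 1L] # bit j set
      p11 <- p[base + 2L^i + 2L^j + 1L]
      for (k in seq_along(base)) {
        four <- c(p00[k], p01[k], p10[k], p11[k])
        if (all(four < zero_tol)) next # uninformative context
        if (any(four < zero_tol)) {
          degenerate <- TRUE
          next
        }
        or <- (p00[k] * p11[k]) / (p01[k] * p10[k])
        worst <- max(worst, or, 1 / or)
        n_ratios <- n_ratios + 1L
      }
    }
  }
  if (degenerate) worst <- Inf
  list(
    is_product_over_bits = !degenerate && (worst - 1) <= tol,
    worst_odds_ratio = worst,
    n_ratios = n_ratios
  )
}

#' Quantum mutual information between two qubit registers
#'
#' For a pure state over the union of the two registers, computes
#' \eqn{I(A{:}B) = S(\rho_A) + S(\rho_B) - S(\rho_{AB})} (von Neumann
#' entropies, in bits), where \eqn{\rho_A} is the reduced density matrix of
#' register A. For a pure global state \eqn{S(\rho_{AB}) = 0}, so
#' \eqn{I = 2 S(\rho_A)}: it is strictly positive exactly when the registers
#' are entangled. Note a diagonal coupling such as CRZ changes no
#' computational-basis probability, so entanglement generated this way is
#' invisible to classical mutual information of measured bitstrings; the
#' quantum quantity is the meaningful register diagnostic here.
#'
#' @param state A `statevector`.
#' @param qubits_a,qubits_b Disjoint 0-based index sets that together cover
#'   all qubits.
#' @return Mutual information in bits (numeric scalar).
#' @examples
#' net <- build_coupled_network(build_variational_neuron(0.3, 0.7, 0.2, 0.5),
#'                              build_variational_neuron(0.4, 0.6, 0.1, 0.3),
#'                              coupling_angle = pi / 2)
#' register_mutual_information(simulate_statevector(net), 0:2, 3:5)
#' @export
register_mutual_information <- function(state, qubits_a, qubits_b) {
  stopifnot(inherits(state, "statevector"))
  n <- attr(state, "n_qubits")
  qubits_a <- sort(as.integer(qubits_a))
  qubits_b <- sort(as.integer(qubits_b))
  if (length(intersect(qubits_a, qubits_b)) > 0 ||
      !setequal(c(qubits_a, qubits_b), 0:(n - 1L))) {
    abort_domain("registers must be disjoint and cover all qubits.")
  }
  psi <- unclass(state)
  idx <- 0:(2^n - 1L)
  sub_index <- function(qubits) {
    out <- integer(length(idx))
    for (pos in seq_along(qubits)) {
      out <- out + bitwAnd(bitwShiftR(idx, qubits[pos]), 1L) * 2L^(pos - 1L)
    }
    out
  }
  ia <- sub_index(qubits_a)
  ib <- sub_index(qubits_b)
  m <- matrix(0+0i, 2^length(qubits_a), 2^length(qubits_b))
  m[cbind(ia + 1L, ib + 1L)] <- psi
  sv <- svd(m, nu = 0, nv = 0)$d
  lam <- sv^2
  lam <- lam[lam > 1e-15]
  s_a <- -sum(lam * log2(lam)) # = S(rho_B) for a pure state
  2 * s_a
}
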