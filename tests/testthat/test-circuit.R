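test_that("the Trotterized neuron circuit has the documented layout", {
  spec <- build_neuron_circuit()
  expect_equal(spec$n_qubits, 3L)
  expect_equal(nrow(spec$gates), 63L) # 3 + 10 * (3 + 3)
  rz <- spec$gates[spec$gates$gate == "RZ", ]
  expect_equal(nrow(rz), 30L)
  first_layer <- rz[1:3, ]
  expect_equal(unlist(first_layer$qubits), 0:2)
  expect_equal(unlist(first_layer$params), pi * 0.1 / c(1, 2, 4),
               tolerance = 1e-12) # 0.31416, 0.15708, 0.07854
  expect_equal(nrow(build_neuron_circuit(n_steps = 0)$gates), 3L)
})

test_that("circuit JSON serialisation round-trips bit-exactly", {
  spec <- build_variational_neuron(0.1234567890123, -0.5, pi / 7, 2.1)
  spec2 <- circuit_from_json(circuit_to_json(spec))
  expect_identical(spec2$n_qubits, spec$n_qubits)
  expect_identical(spec2$label, spec$label)
  expect_equal(spec2$gates$gate, spec$gates$gate)
  expect_identical(spec2$gates$params, spec$gates$params)
  expect_identical(spec2$gates$qubits, spec$gates$qubits)

  path <- withr::local_tempfile(fileext = ".json")
  circuit_to_json(spec, path)
  expect_identical(circuit_from_json(path)$gates$params, spec$gates$params)
})

test_that("OpenQASM export names the qelib1 gates", {
  spec <- circuit_spec(3L, list(
    gate_op("H", 0L), gate_op("RX", 1L, 0.5), gate_op("RZ", 0L, pi * 0.1),
    gate_op("RZZ", c(0L, 1L), 0.25), gate_op("CRZ", c(2L, 0L), 0.75),
    gate_op("CNOT", c(0L, 2L))
  ))
  qasm <- export_qasm(spec)
  expect_identical(qasm[1], "OPENQASM 2.0;")
  expect_true(any(grepl("^h q\\[0\\];$", qasm)))
  expect_true(any(grepl("^rz\\(0.31415926535897931\\) q\\[0\\];$", qasm)))
  expect_true(any(grepl("^rzz\\(0.25\\) q\\[0\\],q\\[1\\];$", qasm)))
  expect_true(any(grepl("^crz\\(0.75\\) q\\[2\\],q\\[0\\];$", qasm)))
  expect_true(any(grepl("^cx q\\[0\\],q\\[2\\];$", qasm)))
})

test_that("statevector simulation matches the dense matrix-product oracle", {
  specs <- list(
    trotter = build_neuron_circuit(),
    variational = build_variational_neuron(0.3, 0.7, 0.2, 0.5),
    crz_chain = build_crz_variant(n_steps = 3,
                                  control_pattern = list(c(0, 1), c(1, 2))),
    mixed_4q = circuit_spec(4L, list(
      gate_op("H", 0L), gate_op("H", 2L), gate_op("RX", 1L, 0.9),
      gate_op("CNOT", c(0L, 3L)), gate_op("RZZ", c(1L, 3L), 0.4),
      gate_op("CRZ", c(3L, 0L), 1.1), gate_op("RZ", 2L, 0.6),
      gate_op("CNOT", c(2L, 1L)), gate_op("H", 3L)
    ))
  )
  for (nm in names(specs)) {
    sv <- simulate_statevector(specs[[nm]])
    expect_lt(max(Mod(unclass(sv) - oracle_statevector(specs[[nm]]))), 1e-12)
    expect_lt(abs(sum(Mod(sv)^2) - 1), 1e-12)
  }
})

test_that("elementary states come out as expected", {
  h1 <- simulate_statevector(circuit_spec(1L, list(gate_op("H", 0L))))
  expect_equal(unclass(h1), c(1, 1) / sqrt(2) + 0i, tolerance = 1e-12,
               ignore_attr = TRUE)

  h3 <- simulate_statevector(build_neuron_circuit(n_steps = 0))
  expect_equal(Mod(unclass(h3)), rep(1 / sqrt(8), 8), tolerance = 1e-12,
               ignore_attr = TRUE)

  empty <- simulate_statevector(circuit_spec(2L, list()))
  pt <- measurement_probabilities(empty)
  expect_equal(pt$probability[pt$state == "00"], 1)
})

test_that("zero-angle entangling gates are exact identities", {
  base <- build_neuron_circuit(n_steps = 2)
  with_id <- circuit_spec(3L, dplyr::bind_rows(
    base$gates, gate_op("CRZ", c(0L, 1L), 0), gate_op("RZZ", c(1L, 2L), 0)))
  expect_identical(unclass(simulate_statevector(with_id)),
                   unclass(simulate_statevector(base)))
})

test_that("variational circuit limiting cases behave as specified", {
  # all angles zero: only H on q0 acts
  pt <- measurement_probabilities(
    simulate_statevector(build_variational_neuron(0, 0, 0, 0)))
  expect_equal(pt$probability[pt$state == "000"], 0.5)
  expect_equal(pt$probability[pt$state == "001"], 0.5) # q0 = 1
  expect_equal(sum(pt$probability), 1, tolerance = 1e-12)

  # no entangling action: product over bits
  res <- product_structure_test(measurement_probabilities(
    simulate_statevector(build_variational_neuron(0.4, 0, 0.8, 0))))
  expect_true(res$is_product_over_bits)
})

test_that("label conventions permute outcomes without changing values", {
  sv <- simulate_statevector(build_variational_neuron(0.3, 0.7, 0.2, 0.5))
  little <- measurement_probabilities(sv, "little")
  big <- measurement_probabilities(sv, "big")
  expect_equal(sort(little$probability), sort(big$probability))
  # "011" little-endian (q0 = 1, q1 = 1, q2 = 0) is "110" big-endian
  expect_equal(big$probability[big$state == "110"],
               little$probability[little$state == "011"])
  expect_equal(sum(little$probability), 1, tolerance = 1e-12)

  bad <- structure(c(1 + 0i, 1 + 0i), n_qubits = 1L, bit_order = "little",
                   class = "statevector")
  expect_error(measurement_probabilities(bad),
               class = "quantneuron_domain_error")
})

test_that("product-structure test separates product from entangled tables", {
  # any product distribution passes with all odds ratios 1
  pa <- c(0.3, 0.7); pb <- c(0.6, 0.4); pc <- c(0.55, 0.45)
  joint <- as.vector(outer(as.vector(outer(pa, pb)), pc))
  labels <- vapply(0:7, function(i)
    paste(rev(as.integer(intToBits(i))[1:3]), collapse = ""), character(1))
  res <- product_structure_test(prob_table(labels, joint))
  expect_true(res$is_product_over_bits)
  expect_lt(res$worst_odds_ratio - 1, 1e-10)

  # Bell pair: degenerate odds ratio, flagged not-product
  bell <- product_structure_test(
    prob_table(c("00", "01", "10", "11"), c(0.5, 0, 0, 0.5)))
  expect_false(bell$is_product_over_bits)

  # the plain-RZ neuron circuit always yields a product distribution
  trotter_res <- product_structure_test(measurement_probabilities(
    simulate_statevector(build_neuron_circuit())))
  expect_true(trotter_res$is_product_over_bits)
  expect_lt(trotter_res$worst_odds_ratio - 1, 1e-10)

  # an entangling CRZ chain generically does not
  chained <- product_structure_test(measurement_probabilities(
    simulate_statevector(build_crz_variant(
      n_steps = 10, control_pattern = list(c(0, 1), c(1, 2))))))
  expect_false(chained$is_product_over_bits)
})

test_that("the published outcome table is not bitwise-product", {
  # printed percentages of the reported 3-qubit run
  published <- prob_table(
    c("000", "001", "010", "011", "100", "101", "110", "111"),
    c(27.7, 11.3, 13.6, 5.9, 24.5, 7.1, 5.4, 4.5))
  res <- product_structure_test(published)
  expect_false(res$is_product_over_bits)
  # worst conditional odds ratio: P(100) P(111) / (P(101) P(110))
  expect_equal(res$worst_odds_ratio, 24.5 * 4.5 / (7.1 * 5.4),
               tolerance = 1e-9) # 2.8756
})

test_that("coupled networks factorise exactly iff the coupling is off", {
  a <- build_neuron_circuit()
  b <- build_neuron_circuit(n_steps = 5)
  net0 <- build_coupled_network(a, b, coupling_angle = 0)
  expect_equal(net0$n_qubits, 6L)
  sv0 <- simulate_statevector(net0)
  kron_state <- as.vector(kronecker(unclass(simulate_statevector(b)),
                                    unclass(simulate_statevector(a))))
  expect_lt(max(Mod(unclass(sv0) - kron_state)), 1e-12)
  expect_lt(register_mutual_information(sv0, 0:2, 3:5), 1e-10)

  svq <- simulate_statevector(
    build_coupled_network(a, b, coupling_angle = pi / 2))
  expect_gt(register_mutual_information(svq, 0:2, 3:5), 1e-6)

  expect_error(build_coupled_network(a, b, 0.1, output_qubit = 7),
               class = "quantneuron_domain_error")
  expect_error(register_mutual_information(sv0, 0:2, 2:5),
               class = "quantneuron_domain_error")
})

test_that("shot sampling is seeded and consistent", {
  probs <- measurement_probabilities(
    simulate_statevector(build_neuron_circuit()))
  s1 <- sample_measurements(probs, 4096, seed = 9)
  s2 <- sample_measurements(probs, 4096, seed = 9)
  expect_identical(s1, s2)
  expect_equal(sum(s1$count), 4096)
  expect_lt(max(abs(s1$frequency - probs$probability)), 0.05)
})

test_that("gate and builder validation rejects malformed input", {
  expect_error(gate_op("H", c(0, 1)), class = "quantneuron_domain_error")
  expect_error(gate_op("CRZ", c(1, 1), 0.3), class = "quantneuron_domain_error")
  expect_error(gate_op("RZ", 0L), class = "quantneuron_domain_error")
  expect_error(gate_op("FOO", 0L), class = "quantneuron_domain_error")
  expect_error(circuit_spec(2L, list(gate_op("H", 5L))),
               class = "quantneuron_domain_error")
  expect_error(build_crz_variant(control_pattern = list(c(1, 1))),
               class = "quantneuron_domain_error")
  expect_error(simulate_statevector(circuit_spec(13L, list(gate_op("H", 0L)))),
               class = "quantneuron_domain_error")
  # empty control pattern reduces to the plain builder
  expect_equal(build_crz_variant(n_steps = 4)$gates,
               build_neuron_circuit(n_steps = 4)$gates)
})
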