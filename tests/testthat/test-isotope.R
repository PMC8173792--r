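test_that("delta to atom percent matches direct evaluation at natural abundance", {
  # AP = 100 R / (1 + R) at delta = 0
  expect_equal(delta_to_atom_percent(0, "C"), 1.11123, tolerance = 1e-5)
  expect_equal(delta_to_atom_percent(0, "N"), 0.36630, tolerance = 1e-5)
  expect_equal(atom_percent_to_delta(delta_to_atom_percent(0, "C"), "C"), 0,
               tolerance = 1e-9)
  # AP = 50% is the symmetry point R = 1
  r_pdb <- iso_standard("C")$reference_ratio
  expect_equal(atom_percent_to_delta(50, "C"), (1 / r_pdb - 1) * 1000)
})

test_that("delta/AP conversion is a strict bijection with tiny round-trip error", {
  deltas <- c(-30, 0, 500, -999.9, 1e5, runif(200, -900, 2000))
  for (el in c("C", "N")) {
    ap <- delta_to_atom_percent(deltas, el)
    expect_true(all(ap > 0 & ap < 100))
    expect_true(all(diff(delta_to_atom_percent(sort(deltas), el)) > 0))
    expect_lt(max(abs(atom_percent_to_delta(ap, el) - deltas)), 1e-9)
  }
  expect_error(delta_to_atom_percent(-1000), "-1000")
  expect_error(delta_to_atom_percent(NaN), "finite")
  expect_error(atom_percent_to_delta(0), "between")
  expect_error(atom_percent_to_delta(100), "between")
})

test_that("atom percent excess subtracts the control and flags negatives", {
  expect_equal(as.numeric(atom_percent_excess(1.081, 1.081)), 0)
  expect_equal(as.numeric(atom_percent_excess(2.27, 1.081)), 1.189)
  neg <- atom_percent_excess(1.0, 1.1)
  expect_true(attr(neg, "negative"))
  expect_equal(as.numeric(neg), -0.1, tolerance = 1e-12)
  # translation consistency
  a <- runif(20, 1, 5); b <- runif(20, 1, 5); k <- 0.37
  expect_equal(as.numeric(atom_percent_excess(a + k, b + k)),
               as.numeric(atom_percent_excess(a, b)))
})

test_that("relative enrichment is a scale-invariant percentage of host APE", {
  expect_equal(relative_enrichment(2, 2), 100)
  expect_equal(relative_enrichment(0.5, 2), 25)
  expect_equal(relative_enrichment(0.5 * 7, 2 * 7), 25)
  expect_error(relative_enrichment(1, 0), "zero")
})

test_that("spike mass-balance inversion round-trips the forward mixture", {
  # zero spike: identity
  expect_equal(invert_spike(3.2, 10, 0, 1.1, 0.5, 0.71), 3.2)
  # equal element masses and AP_std = AP_mix: sample must equal the mixture
  expect_equal(invert_spike(2.5, 4, 4, 2.5, 0.5, 0.5), 2.5)
  fwd <- function(ap_s, m_s, m_std, ap_std, f_s, f_std) {
    (ap_s * m_s * f_s + ap_std * m_std * f_std) / (m_s * f_s + m_std * f_std)
  }
  f_c <- acetanilide_fraction("C")
  mix <- fwd(5.0, 2.0, 3.0, delta_to_atom_percent(0, "C"), 0.45, f_c)
  expect_equal(invert_spike(mix, 2.0, 3.0, delta_to_atom_percent(0, "C"),
                            0.45, f_c), 5.0, tolerance = 1e-9)
  # property: forward/inverse identity over randomised draws
  set.seed(7)
  for (i in 1:1000) {
    ap_s <- runif(1, 0.3, 60); m_s <- runif(1, 0.1, 10)
    m_std <- runif(1, 0, 10); ap_std <- runif(1, 0.3, 5)
    f_s <- runif(1, 0.05, 1); f_std <- runif(1, 0.05, 1)
    mix <- fwd(ap_s, m_s, m_std, ap_std, f_s, f_std)
    expect_equal(invert_spike(mix, m_s, m_std, ap_std, f_s, f_std), ap_s,
                 tolerance = 1e-9)
  }
  expect_error(invert_spike(2, 0, 1, 1.1, 0.5, 0.5), "degenerate")
})

test_that("acetanilide element fractions follow C8H9NO", {
  expect_equal(acetanilide_fraction("C"), 0.7109, tolerance = 1e-4)
  expect_equal(acetanilide_fraction("N"), 0.1036, tolerance = 1e-3)
})

test_that("machine precision is the percent relative standard deviation", {
  expect_equal(machine_precision(c(3, 3, 3)), 0)
  expect_equal(machine_precision(c(9, 11)), 14.14, tolerance = 1e-3)
  expect_error(machine_precision(5), "two")
  expect_error(machine_precision(c(-1, 1)), "zero")
})

test_that("duplicate readings are averaged and singles pass through", {
  df <- data.frame(sample_id = c("a", "a", "b"), fraction = "host",
                   element = "C", treatment = "SymL", timepoint = "pulse",
                   value = c(2.0, 2.4, 1.5), replicate_index = c(1, 2, 1))
  out <- average_duplicates(df)
  expect_equal(out$value[out$sample_id == "a"], 2.2)
  expect_equal(out$value[out$sample_id == "b"], 1.5)
  expect_equal(out$n_replicates, c(2, 1))
  expect_warning(average_duplicates(rbind(df, df[1, ])), "more than two")
  expect_error(average_duplicates(df[0, ]), "no measurements")
  expect_error(average_duplicates(df[, setdiff(names(df), "value")]),
               "missing required")
})

test_that("APE table matches samples against pooled or state-matched T0 controls", {
  tab <- data.frame(
    sample_id = c("c1", "c2", "c3", "c4", "s1", "a1"),
    treatment = c("SymL", "SymL", "ApoL", "ApoL", "SymL", "ApoL"),
    fraction = "host", element = "C",
    timepoint = c("T0", "T0", "T0", "T0", "pulse", "pulse"),
    value = c(1.08, 1.10, 1.06, 1.08, 2.09, 1.57))
  pooled <- ape_table(tab, "pooled")
  expect_equal(pooled$ape, c(2.09, 1.57) - 1.08)
  per <- ape_table(tab, "per_state")
  expect_equal(per$ape[per$sample_id == "s1"], 2.09 - 1.09)
  expect_equal(per$ape[per$sample_id == "a1"], 1.57 - 1.07)
  expect_error(ape_table(tab[tab$timepoint != "T0", ]), "T0")
})
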