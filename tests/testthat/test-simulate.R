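test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(simulate_sia(cfg), simulate_sia(cfg))
  expect_identical(simulate_respirometry(cfg), simulate_respirometry(cfg))
  expect_identical(simulate_allometry(cfg), simulate_allometry(cfg))
  a <- simulate_asv_table(cfg)
  b <- simulate_asv_table(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  # and different seeds diverge
  expect_false(identical(simulate_sia(sim_config(seed = 100))$measurements$value,
                         simulate_sia(cfg)$measurements$value))
})

test_that("zero-noise isotope tables equal the configured trajectory means", {
  cfg <- sim_config(seed = 1, rsd_c = 0, rsd_n = 0)
  sia <- simulate_sia(cfg)
  m <- sia$measurements
  row <- m[m$treatment == "SymL" & m$fraction == "algal" &
             m$timepoint == "chase3h" & m$element == "C", ]
  expect_true(all(row$value == cfg$trajectories$C$SymL$algal[3]))
  # designated low-mass algal cells carry a single reading
  singles <- m[m$treatment == "SymD" & m$timepoint == "pulse" &
                 m$fraction == "algal" & m$element == "C", ]
  expect_equal(sum(singles$sample_id == "SymDpulse1"), 1)
  expect_equal(sum(singles$sample_id == "SymDpulse2"), 2)
})

test_that("respirometry generator inverts the chamber equation exactly at zero noise", {
  cfg <- sim_config(seed = 4, do_noise_sd = 0)
  sim <- simulate_respirometry(cfg)
  out <- process_respirometry(sim$records)
  expect_equal(out$rates$rate, sim$truth$true_rate, tolerance = 1e-12)
  # signed convention: respiration records recover positive R
  r_rows <- out$rates$kind == "R"
  expect_equal(out$rates$R[r_rows], -sim$truth$true_rate[r_rows],
               tolerance = 1e-12)
})

test_that("configured Pn = R yields a gross production ratio of two", {
  cfg <- sim_config(seed = 6, do_noise_sd = 0)
  cfg$respirometry$SymL$sd <- 0
  cfg$respirometry$SymD$sd <- 0
  cfg$respirometry$SymL$mean <- 0.028
  cfg$respirometry$SymD$mean <- 0.028
  out <- process_respirometry(simulate_respirometry(cfg)$records)
  expect_equal(out$rates$Pg_to_R[out$rates$kind == "Pn"], rep(2, 5),
               tolerance = 1e-9)
})

test_that("zero-noise allometry pairs reproduce the generating polynomials", {
  cfg <- sim_config(seed = 2)
  cfg$allometry$symbiotic$sigma <- 0
  cfg$allometry$aposymbiotic$sigma <- 0
  sim <- simulate_allometry(cfg)
  for (st in c("symbiotic", "aposymbiotic")) {
    d <- sim$pairs[sim$pairs$state == st, ]
    fit <- fit_ww_bd(d$bd_mm, d$ww_g)
    expect_equal(fit$coefficients, cfg$allometry[[st]]$coef,
                 tolerance = 1e-8)
  }
})

test_that("the ASV generator plants its membership and contamination truth", {
  sim <- simulate_asv_table(sim_config(seed = 7))
  expect_equal(sum(sim$table$sample_meta$is_control), 1)
  expect_equal(dim(sim$table$counts)[1], 16)
  filt <- filter_contaminants(sim$table)
  expect_setequal(filt$removed$asv_id, sim$truth$contaminants)
  expect_setequal(filt$removed$asv_id[filt$removed$control_only],
                  sim$truth$control_only)
  sets <- core_sets(filt$table)
  expect_setequal(sets$core, sim$truth$core)
  expect_setequal(sets$symbiome, sim$truth$symbiome)
  expect_setequal(sets$apobiome, sim$truth$apobiome)
  # the tree covers the full ASV pool
  expect_setequal(sim$tree$tip.label, colnames(sim$table$counts))
  # aposymbiotic samples are planted richer and more variable
  rich <- rowSums(filt$table$counts > 0)
  grp <- filt$table$sample_meta$treatment
  expect_gt(mean(rich[grp == "ApoL"]), mean(rich[grp != "ApoL"]))
})

test_that("labelled vs unlabelled algal carbon is detectable by design", {
  hits <- vapply(1:20, function(i) {
    sia <- simulate_sia(sim_config(seed = 500 + i))
    avg <- average_duplicates(sia$measurements)
    sel <- avg$fraction == "algal" & avg$element == "C" &
      avg$timepoint == "pulse"
    a <- avg$value[sel & avg$treatment == "SymL"]
    b <- avg$value[sel & avg$treatment == "ApoL"]
    welch_upper_t(a, b)$p_value < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("regression generator hits its target noise level", {
  sim <- simulate_enrichment_regression(1.24, 0.17, n = 15,
                                        x_range = c(1, 9),
                                        r2_target = 0.68, seed = 3)
  expect_equal(nrow(sim$data), 15)
  expect_equal(sim$truth$sigma,
               sqrt(0.17^2 * 64 / 12 * 0.32 / 0.68), tolerance = 1e-12)
})
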