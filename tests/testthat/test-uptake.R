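test_that("delta to atom percent follows the reference-ratio formulas", {
  # reference gas: delta = 0 corresponds to 0.3663 atom%
  expect_equal(delta_to_atom_percent(0), 0.3663, tolerance = 1e-4)
  # delta = 1000 doubles the isotope ratio (0.7299... to 4 figures)
  expect_equal(delta_to_atom_percent(1000), 0.7300, tolerance = 5e-4)
  # strictly increasing in delta
  d <- seq(-900, 5000, length.out = 50)
  expect_true(all(diff(delta_to_atom_percent(d)) > 0))
  expect_error(delta_to_atom_percent(-1000), "-1000")
})

test_that("atom percent and delta conversions are mutually inverse", {
  d <- c(-500, 0, 100, 2000, 20000)
  expect_equal(atom_percent_to_delta(delta_to_atom_percent(d)), d,
               tolerance = 1e-9)
  expect_error(atom_percent_to_delta(0), "0, 100")
})

test_that("the mixing model matches hand evaluation and its homogeneities", {
  # A_PN = 1.000%, A0 = 0.366%, A_src = 50%, PN = 10, dt = 0.6667 h
  delta <- atom_percent_to_delta(1.000)
  v <- absolute_uptake(delta, pon = 10, duration = 0.6667,
                       atom_pct_source = 50, atom_pct_baseline = 0.366)
  expect_equal(v, (1.000 - 0.366) / (50 - 0.366) * 10 / 0.6667,
               tolerance = 1e-9)
  expect_equal(v, 0.1916, tolerance = 1e-3)
  # no tracer incorporation: A_PN = A0 gives zero uptake
  d0 <- atom_percent_to_delta(0.3663)
  expect_equal(absolute_uptake(d0, 10, 1, 50), 0, tolerance = 1e-12)
  # linear in PN, inverse in duration
  expect_equal(absolute_uptake(delta, 20, 0.6667, 50, 0.366), 2 * v)
  expect_equal(absolute_uptake(delta, 10, 2 * 0.6667, 50, 0.366), v / 2)
  expect_error(absolute_uptake(delta, 10, 1, atom_pct_source = 0.3,
                               atom_pct_baseline = 0.366), "enrich")
})

test_that("cell normalization is a plain division with guarded input", {
  expect_equal(cell_normalize(0.2, 1e6), 2e-7)
  expect_equal(cell_normalize(0, 1e6), 0)
  expect_equal(cell_normalize(0.2, 2e6), cell_normalize(0.2, 1e6) / 2)
  expect_error(cell_normalize(0.2, 0), "positive")
})

test_that("source-pool enrichment follows the two label-mixing regimes", {
  # 1:1 labeled:unlabeled at low additions, 9:1 unlabeled:labeled above 2 uM
  lo <- source_atom_percent(2, residual = 0)
  hi <- source_atom_percent(10, residual = 0)
  expect_equal(lo, 0.5 * 98 + 0.5 * 0.3663, tolerance = 1e-9)
  expect_equal(hi, 0.1 * 98 + 0.9 * 0.3663, tolerance = 1e-9)
  # residual unlabeled nitrate dilutes the label, more so at low additions
  expect_lt(source_atom_percent(0.1, residual = 0.1),
            source_atom_percent(0.1, residual = 0))
  expect_lt(source_atom_percent(0.1, residual = 0) -
              source_atom_percent(0.1, residual = 0.1),
            source_atom_percent(2, residual = 0) * 0.5)
})

test_that("simulated assays invert exactly through the mixing model", {
  a <- simulate_uptake_assay(2e-7, 1.5, c(0.1, 0.4, 0.8, 2, 10, 50, 100),
                             noise_cv = 0)
  v <- cell_normalize(
    absolute_uptake(a$delta15n_particulate, a$pon, a$duration,
                    a$atom_pct_source, a$atom_pct_baseline),
    a$cells)
  truth <- 2e-7 * a$substrate / (1.5 + a$substrate)
  expect_lt(max(abs(v - truth) / truth), 1e-6)  # >= 6 significant digits
  # half-saturation: at S = K_s the recovered rate is V_max / 2
  ah <- simulate_uptake_assay(3e-7, 1, 1, noise_cv = 0)
  vh <- cell_normalize(
    absolute_uptake(ah$delta15n_particulate, ah$pon, ah$duration,
                    ah$atom_pct_source, ah$atom_pct_baseline),
    ah$cells)
  expect_equal(vh, 3e-7 / 2, tolerance = 1e-9)
})

test_that("Michaelis-Menten fitting recovers noiseless and noisy truth", {
  s <- c(0.1, 0.4, 0.8, 2, 10, 50, 100)
  v <- 2e-7 * s / (1.5 + s)
  f <- fit_michaelis_menten(s, v)
  expect_equal(f$v_max, 2e-7, tolerance = 1e-4)
  expect_equal(f$k_s, 1.5, tolerance = 1e-4)
  # fitted curve is monotone increasing in S and bounded above by v_max
  grid <- seq(0.01, 200, length.out = 400)
  pred <- f$v_max * grid / (f$k_s + grid)
  expect_true(all(diff(pred) > 0))
  expect_true(all(pred < f$v_max))
  expect_error(fit_michaelis_menten(s, -v), "nonpositive")
  expect_error(fit_michaelis_menten(c(1, 1, 2), c(1, 1, 2)), "3 distinct")
  # recovery under measurement noise across seeds
  ok <- vapply(1:10, function(i) {
    a <- simulate_uptake_assay(2e-7, 1.5, s, replicates = 4,
                               noise_cv = 0.02, seed = 100 + i)
    vv <- cell_normalize(
      absolute_uptake(a$delta15n_particulate, a$pon, a$duration,
                      a$atom_pct_source, a$atom_pct_baseline),
      a$cells)
    fi <- fit_michaelis_menten(a$substrate, vv)
    abs(fi$v_max - 2e-7) / 2e-7 <= 0.1 && abs(fi$k_s - 1.5) / 1.5 <= 0.25
  }, logical(1))
  expect_true(all(ok))
})

test_that("per-strain kinetics wrapper returns one row per strain with CIs", {
  s <- c(0.1, 0.4, 0.8, 2, 10, 50, 100)
  a1 <- simulate_uptake_assay(2e-7, 1.5, s, replicates = 2, noise_cv = 0.02,
                              seed = 1, strain_id = "A1")
  a2 <- simulate_uptake_assay(4e-7, 3, s, cells = 2e7, replicates = 2,
                              noise_cv = 0.02, seed = 2, strain_id = "T1")
  kin <- uptake_kinetics(rbind(a1, a2), n_boot = 50, seed = 3)
  expect_equal(sort(kin$strain_id), c("A1", "T1"))
  expect_true(all(kin$v_max_low <= kin$v_max & kin$v_max <= kin$v_max_high))
})
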