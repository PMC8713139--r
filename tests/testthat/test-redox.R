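test_that("the two-electron Nernst relation reproduces published potentials", {
  expect_equal(round(nernst_potential(18.08), 2), -93.69)
  expect_equal(round(nernst_potential(28.59), 2), -148.16)
  expect_equal(nernst_potential(0), 0)
})

test_that("nernst_potential is proportional in dG", {
  x <- withr::with_seed(5, runif(20, -60, 60))
  expect_equal(nernst_potential(2 * x), 2 * nernst_potential(x))
  expect_equal(nernst_potential(x, n_electrons = 1),
               2 * nernst_potential(x, n_electrons = 2))
})

test_that("linear calibration follows slope and intercept", {
  expect_equal(calibrate(-148.16, calibration_model(1.5, -43)), -265.24)
  expect_equal(calibrate(-148.16, calibration_model(1.5, -47)), -269.24)
  expect_equal(calibrate(0, calibration_model(1.5, -43)), -43)
  expect_error(calibration_model(slope = 0), "nonzero")
})

test_that("classification applies the inclusive functional window", {
  expect_equal(classify_role(-269), "functional")
  expect_equal(classify_role(-426), "structural")
  expect_equal(classify_role(c(-330, -89)), c("functional", "functional"))
  expect_equal(classify_role(c(-330.01, -88.99)),
               c("structural", "structural"))
  expect_true(flag_gray_zone(-400))
  expect_false(flag_gray_zone(-500))
  expect_false(flag_gray_zone(-200))
})

test_that("classification policies validate their window", {
  expect_error(classification_policy(functional_low = -50,
                                     functional_high = -89), "below")
  expect_error(classification_policy(structural_cut = -100), "below")
})

test_that("published corrected potentials split 7 functional / 10 structural", {
  tab <- loxl2_disulfides()
  expect_equal(nrow(tab), 17L)
  roles <- classify_role(tab$E_corr_mV)
  expect_equal(sum(roles == "functional"), 7L)
  expect_equal(sum(roles == "structural"), 10L)
  fun <- tab$E_corr_mV[roles == "functional"]
  expect_equal(min(fun), -298.15)
  expect_equal(max(fun), -181.94)
})

test_that("Nernst-consistent table rows reproduce their printed potential", {
  tab <- loxl2_disulfides()
  cons <- tab[tab$nernst_consistent, ]
  expect_equal(nrow(cons), 10L)
  expect_true(all(abs(nernst_potential(cons$work_kJ_mol) - cons$E_cal_mV)
                  <= 0.01))
  # and the flagged rows genuinely are inconsistent
  incons <- tab[!tab$nernst_consistent, ]
  expect_true(all(abs(nernst_potential(incons$work_kJ_mol) - incons$E_cal_mV)
                  > 0.01))
})

test_that("build_report chains estimate -> Nernst -> calibration -> role", {
  # dG values chosen so corrected potentials land near -100, -400, -500 mV
  model <- calibration_model(1.5, -43)
  dg_for <- function(E_corr) {
    -(E_corr - model$intercept) / model$slope * (2 * 96.485 / 1000)
  }
  bonds <- list(
    list(bond_id = "b1", domain = "d", dG = dg_for(-100)),
    list(bond_id = "b2", domain = "d", dG = dg_for(-400)),
    list(bond_id = "b3", domain = "d", dG = dg_for(-500)))
  rep <- build_report(bonds, model = model)
  expect_equal(rep$records$role, c("functional", "structural", "structural"))
  expect_equal(rep$records$E_corr, c(-100, -400, -500), tolerance = 1e-9)
  expect_equal(rep$summary$n_functional, 1L)
  expect_equal(rep$records$gray_zone, c(FALSE, TRUE, FALSE))
})

test_that("build_report rejects duplicates and handles the empty panel", {
  expect_error(build_report(list(list(bond_id = "x", dG = 1),
                                 list(bond_id = "x", dG = 2))),
               "duplicate bond_id")
  rep <- build_report(list())
  expect_equal(nrow(rep$records), 0L)
  expect_equal(rep$summary$n_functional, 0L)
  expect_equal(rep$summary$n_structural, 0L)
})

test_that("report summary counts are invariant to input order", {
  tab <- loxl2_disulfides()
  bonds <- lapply(seq_len(nrow(tab)), function(i) {
    list(bond_id = tab$bond_id[i], domain = tab$domain[i],
         dG = tab$work_kJ_mol[i])
  })
  r1 <- build_report(bonds)
  r2 <- build_report(rev(bonds))
  expect_equal(r1$summary, r2$summary)
  # every record gets exactly one role
  expect_true(all(r1$records$role %in% c("functional", "structural")))
})

test_that("estimates from work sets feed the report", {
  pan <- make_bond_panel(n_bonds = 2, dG_values = c(20, 45), sigma = 3,
                         n_per_direction = 150, seed = 31)
  rep <- build_report(pan$bonds, estimator = "bar")
  expect_equal(rep$records$role, pan$truth$role)
  expect_lt(max(abs(rep$records$dG - pan$truth$dG_true)), 1.5)
})

test_that("distance-potential rank correlation matches a brute-force oracle", {
  expect_equal(correlate_distance_potential(1:5, c(50, 40, 30, 20, 10)), -1)
  expect_error(correlate_distance_potential(1:2, 1:2), "at least 3")

  d_tied <- c(5, 8, 8, 12, 15)
  e <- c(-180, -250, -210, -300, -330)
  expect_equal(correlate_distance_potential(d_tied, e),
               brute_spearman(d_tied, e))

  withr::with_seed(13, {
    d <- runif(5, 5, 18)
    p <- sample(c(-182, -271, -187, -298, -386))
    expect_equal(correlate_distance_potential(d, p), brute_spearman(d, p))
  })
})
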