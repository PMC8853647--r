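# the traditional biomass-reaction counterpart of the comprehensive model

ref_state <- function() {
  if (is.null(.cache$ref_state)) {
    m <- cell_model()
    sw <- cell_sweep()
    ev <- egvs(m, rationalize(sw$mu_max - 5e-4))
    .cache$ref_state <- list(
      mu = ev$mu,
      x = as_rational(stats::setNames(ev$concentrations[1, ], m$species)))
  }
  .cache$ref_state
}

test_that("the biomass column is built from the composition with
           amino-acid folding and is mass-balanced after unscaling", {
  m <- cell_model()
  st <- ref_state()
  tm <- traditional_model(m, st)
  expect_equal(colnames(tm$stoich),
               c("r_IG", "r_IN", "r_EAA", "r_ELD", "r_EL", "biomass"))
  # x_AA_tot = n_I(x_IG + x_IN) + n_E(x_EAA + x_ELD + x_EL) + n_R x_R + x_AA
  x <- rat_num(st$x)
  expect_equal(rat_num(tm$x_aa_tot),
               646 * (x[["IG"]] + x[["IN"]]) +
                 325 * (x[["EAA"]] + x[["ELD"]] + x[["EL"]]) +
                 22608 * x[["R"]] + x[["AA"]])
  # unscaled column consumes exactly one gram of precursors per gram:
  # w_met^T column = -(w^T x) = -1
  wcol <- rat_num(egrowth:::rq_dot(tm$molar_masses,
                                   tm$biomass_col_unscaled))
  expect_equal(wcol, -1, tolerance = 1e-12)
})

test_that("the traditional model has exactly one EFM and, with frozen
           capacity constraints, one EFV", {
  m <- cell_model()
  tm <- traditional_model(m, ref_state())
  ta <- traditional_analysis(tm, m)
  expect_equal(ta$n_efm, 1)
  expect_equal(ta$n_efv, 1)
  # the single EFM runs all reactions: uptake feeds amino acids and lipids
  expect_true(all(rat_num(ta$efms) > 0))
})

test_that("a zero-growth reference state is rejected", {
  m <- cell_model()
  expect_error(traditional_model(m, list(mu = "0", x = ref_state()$x)),
               "positive growth rate")
})
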