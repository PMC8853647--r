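# autocatalysis (BC/CC/AC), kinetic consistency, MAC sets

test_that("the lipid-free mode is BC but not CC; blending in enzyme and
           ribosome production closes it", {
  m <- cell_model()
  raw <- cell_egms_raw()
  vprime <- rq_add(egm_by_product(raw, "IG"), egm_by_product(raw, "IN"))
  r <- classify_gm(m, vprime)
  expect_true(r$basically_catalytic)     # all reactions are catalytic
  expect_false(r$catalytically_closed)
  expect_setequal(r$violating_reactions, c("r_EAA", "s_IG", "s_IN"))
  expect_false(r$autocatalytic)
  vpp <- rq_add(vprime, rq_add(egm_by_product(raw, "EAA"),
                               egm_by_product(raw, "R")))
  r2 <- classify_gm(m, vpp)
  expect_true(r2$catalytically_closed)
  expect_true(r2$autocatalytic)          # AC = BC and CC
  expect_equal(r2$autocatalytic,
               r2$basically_catalytic && r2$catalytically_closed)
})

test_that("e^G is kinetically consistent; modes leaving involved species
           unproduced are not", {
  m <- cell_model()
  raw <- cell_egms_raw()
  rG <- classify_gm(m, egm_by_product(raw, "G"))
  expect_true(rG$kinetically_consistent)
  # e^IG consumes G, N, AA without producing them
  rIG <- classify_gm(m, egm_by_product(raw, "IG"))
  expect_false(rIG$kinetically_consistent)
  expect_setequal(rIG$unsupplied_species, c("G", "N", "AA"))
})

test_that("AC = BC and CC across random growth modes", {
  m <- cell_model()
  raw <- cell_egms_raw()
  set.seed(23)
  for (rep in 1:10) {
    co <- as.character(sample(0:2, 11, replace = TRUE))
    v <- rq_matmul(t(raw$flux), co)
    if (all(rat_num(v) == 0)) next
    r <- classify_gm(m, v)
    expect_equal(r$autocatalytic,
                 r$basically_catalytic && r$catalytically_closed)
    # kinetic consistency implies production of every involved species
    if (r$kinetically_consistent) {
      active <- m$reactions[rat_num(v) != 0]
      touched <- m$species[apply(
        rat_num(m$stoich[, active, drop = FALSE]) != 0, 1, any)]
      Nv <- rat_num(rq_matmul(m$stoich, as_rational(v)))
      expect_true(all(Nv[match(touched, m$species)] > 0))
    }
  }
})

test_that("the stoichiometry-only fixture has exactly one MAC set", {
  m <- cell_model()
  ms <- mac_sets(m, cell_egms_raw())
  expect_length(ms, 1)
  expect_setequal(ms[[1]],
                  c("r_IG", "r_IN", "r_EAA", "s_IG", "s_IN", "s_EAA", "s_R"))
  # removing any reaction destroys AC-support feasibility
  for (r in ms[[1]]) {
    expect_false(egrowth:::.ac_support_feasible(m, setdiff(ms[[1]], r)))
  }
})

test_that("the minimal model's MAC sets project to {w1, wR} and {w2, wR}", {
  mm <- minimal_growth_model()
  ms <- mac_sets(mm)
  proj <- unique(lapply(ms, intersect, c("w1", "w2", "wR")))
  expect_setequal(lapply(proj, sort), list(c("w1", "wR"), c("w2", "wR")))
})

test_that("the minimal model has 4 scaled-and-projected EGMs, each producing
           one species", {
  mm <- minimal_growth_model()
  es <- egms(mm)
  prod <- vapply(es$produced, paste, character(1), collapse = "+")
  expect_true(all(lengths(es$produced) == 1))  # one product per EGM
  # projection to the scaled synthesis fluxes (w1, w2, wR)/mu
  syn <- match(c("w1", "w2", "wR"), mm$reactions)
  projected <- unique(round(rat_num(es$flux[, syn, drop = FALSE]), 9))
  expect_equal(nrow(projected), 4)
  expect_setequal(unique(prod), c("AA", "E1", "E2", "R"))
})

test_that("under the capacity and membrane constraints every EGV is
           autocatalytic and none is kinetically consistent", {
  m <- cell_model()
  e5 <- cell_egvs("1/2")
  for (i in seq_len(nrow(e5$flux))) {
    r <- classify_gm(m, e5$flux[i, ])
    expect_true(r$autocatalytic)
    expect_false(r$kinetically_consistent)
  }
  # full support everywhere: the whole reaction set is the only AC support
  # realized by EGVs
  expect_true(all(rat_num(e5$flux) > 0))
})
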