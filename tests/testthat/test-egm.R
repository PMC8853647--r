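# elementary growth modes of the self-fabricating cell

test_that("the fixture has 11 EGMs, one per species, none with zero mu", {
  m <- cell_model()
  es <- cell_egms()
  expect_equal(nrow(es$flux), 11)
  expect_equal(sum(es$is_flux_mode), 0)  # no EFMs
  prod <- vapply(es$produced, paste, character(1), collapse = "+")
  expect_setequal(prod, m$species)       # bijection EGM -> produced species
  # N e^i = (mu / omega_i) u^i, with normalization mu = 1
  Nv <- rat_num(rq_matmul(m$stoich, t(es$flux)))
  for (i in seq_len(11)) {
    u <- numeric(11)
    u[match(prod[i], m$species)] <- 1 / rat_num(m$molar_masses[[prod[i]]])
    expect_equal(Nv[, i], u, ignore_attr = TRUE)
    expect_equal(rat_num(es$mu[i]), 1)
  }
})

test_that("EGM flux patterns match the closed forms", {
  m <- cell_model()
  es <- cell_egms()
  w <- m$molar_masses
  # e^G = mu/omega_G * (1,0,...,0); e^AA = mu/omega_AA * (1,1,1,0,...)
  expect_equal(rat_num(egm_by_product(es, "G")),
               c(1 / 180, rep(0, 10)), ignore_attr = TRUE)
  expect_equal(rat_num(egm_by_product(es, "AA")),
               c(1, 1, 1, rep(0, 8)) / 198, ignore_attr = TRUE)
  # e^IG = mu/omega_IG * (n_I, n_I, n_I, 0, 0; 1, 0, ...)
  expect_equal(rat_num(egm_by_product(es, "IG")),
               c(646, 646, 646, 0, 0, 1, rep(0, 5)) / (646 * 198),
               ignore_attr = TRUE)
  # e^L = mu/omega_L * (n_L, 0, 0, 1, 1; 0...)
  expect_equal(rat_num(egm_by_product(es, "L")),
               c(7, 0, 0, 1, 1, rep(0, 6)) / 1260, ignore_attr = TRUE)
  # associated concentrations: x(e^i) = u^i / omega_i
  xg <- es$concentrations[match("G", vapply(es$produced, paste,
                                            character(1))), ]
  expect_equal(xg[["G"]], 1 / 180)
  expect_equal(sum(xg != 0), 1)
})

test_that("only e^G and e^N are support-minimal", {
  es <- cell_egms()
  sm <- support_minimal(es)
  prod <- vapply(es$produced, paste, character(1), collapse = "+")
  expect_setequal(prod[sm], c("G", "N"))
})

test_that("every EGM is conformally non-decomposable in the growth cone", {
  es <- cell_egms()
  cone <- es$cone
  for (i in seq_len(nrow(es$flux)))
    expect_true(is_cnd(es$flux[i, ], cone))
})

test_that("the lipid-free growth mode decomposes over the expected EGMs", {
  m <- cell_model()
  raw <- cell_egms_raw()
  prod <- vapply(raw$produced, paste, character(1), collapse = "+")
  # v' = e^IG + e^IN (+ metabolite EGMs): support {r_IG, r_IN, r_EAA,
  # s_IG, s_IN}, no lipid synthesis
  vprime <- rq_add(
    rq_add(egm_by_product(raw, "IG"), egm_by_product(raw, "IN")),
    rq_mul(egm_by_product(raw, "G"), "1/2"))
  supp <- m$reactions[rat_num(vprime) != 0]
  expect_setequal(supp, c("r_IG", "r_IN", "r_EAA", "s_IG", "s_IN"))
  dec <- decompose_growth_mode(m, vprime, raw)
  expect_length(dec$E0, 0)
  used <- vapply(dec$Emu, function(t) {
    paste(m$species[rat_num(rq_matmul(m$stoich, t$ev)) != 0],
          collapse = "+")
  }, character(1))
  expect_true(all(used %in% c("G", "N", "AA", "IG", "IN")))
  expect_true(all(c("IG", "IN") %in% used))       # lambda_IG, lambda_IN > 0
  expect_equal(rat_num(dec$lambda_sum), 1)        # convex combination
  expect_true(all(rat_num(dec$residual) == 0))
  # every E_mu term carries the growth rate of the target
  for (t in dec$Emu)
    expect_equal(growth_rate(m, t$ev), growth_rate(m, vprime))
})

test_that("an EGM decomposes as itself and random convex combinations of
           normalized EGMs recover their coefficients exactly", {
  m <- cell_model()
  es <- cell_egms()     # normalized to mu = 1
  raw <- cell_egms_raw()
  dec <- decompose_growth_mode(m, raw$flux[5, ], raw)
  expect_length(dec$Emu, 1)
  expect_equal(rat_num(dec$Emu[[1]]$lambda), 1)
  set.seed(12)
  for (rep in 1:5) {
    lam <- as.character(sample(0:6, 11, replace = TRUE))
    s <- egrowth:::rq_sum(lam)
    lam <- egrowth:::rq_div(lam, s)   # convex weights
    v <- rq_matmul(t(es$flux), lam)
    dec <- decompose_growth_mode(m, v, raw)
    # the 11 normalized EGMs are linearly independent (N is invertible),
    # so the convex representation is unique and must be recovered
    got <- stats::setNames(rep(0, 11), m$species)
    for (t in dec$Emu) {
      sp <- m$species[rat_num(rq_matmul(m$stoich, t$ev)) != 0]
      got[sp] <- rat_num(t$lambda)
    }
    prod <- vapply(es$produced, paste, character(1), collapse = "+")
    expect_equal(got[prod], stats::setNames(rat_num(lam), prod),
                 tolerance = 1e-12)
    # concentration mixing identity x(v) = sum lambda x(e)
    xv <- associated_concentrations(m, v)
    xmix <- rowSums(vapply(dec$Emu, function(t)
      rat_num(t$lambda) * associated_concentrations(m, t$ev),
      numeric(11)))
    expect_equal(xv, xmix, tolerance = 1e-12)
  }
})

test_that("growth cone construction stacks labeled mass-balance and
           irreversibility rows and is pointed for the fixture", {
  m <- cell_model()
  cone <- growth_cone(m)
  expect_equal(nrow(cone$ineq), 22)
  expect_setequal(rownames(cone$ineq),
                  c(paste("mb", m$species), paste("irr", m$reactions)))
  spec <- egrowth:::.reduce_spec(egrowth:::.spec_of(cone))
  expect_equal(egrowth:::.lineality_dim(spec), 0)
})
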