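test_that("the self-fabricating cell fixture is built as specified", {
  m <- cell_model()
  expect_equal(dim(m$stoich), c(11, 11))  # square stoichiometric matrix
  expect_true(validate_model(m)$ok)
  expect_setequal(m$exchange, c("r_IG", "r_IN"))
  expect_setequal(names(m$catalysts), m$reactions)  # all reactions catalytic
  expect_setequal(m$irreversible, m$reactions)
})

test_that("masses are derived from mass balance of internal reactions", {
  m <- cell_model()
  w <- rat_num(m$molar_masses)
  expect_equal(w[["AA"]], 180 + 18)            # G + N -> AA
  expect_equal(w[["LD"]], 7 * 180)             # n_L G -> LD
  expect_equal(w[["L"]], 7 * 180)              # LD -> L
  expect_equal(w[["IG"]], 646 * 198)
  expect_equal(w[["EAA"]], 325 * 198)
  expect_equal(w[["R"]], 22608 * 198)
  # underdetermined system errors
  m2 <- growth_model(c("A", "B"), c(A = "1"),
                     matrix(c("1", "0"), 2, 1,
                            dimnames = list(NULL, c("imp"))),
                     irreversible = "imp", exchange = "imp")
  expect_error(derive_masses(m2), "underdetermined|no internal")
})

test_that("validation catches broken models", {
  # internal reaction G -> 2G violates mass conservation
  N <- matrix(c("1", "-1", "1"), 1, 3,
              dimnames = list("G", c("imp", "dup", "exp")))
  N[1, "dup"] <- "1"  # net +1 G from nothing
  m <- growth_model("G", c(G = "180"), N, irreversible = colnames(N),
                    exchange = c("imp", "exp"))
  v <- validate_model(m)
  expect_false(v$ok)
  expect_match(paste(v$failures, collapse = " "), "mass")
  # closed two-species system has the conservation law y = (1, 1)
  N2 <- matrix(c("-1", "1"), 2, 1, dimnames = list(c("A", "B"), "conv"))
  m2 <- growth_model(c("A", "B"), c(A = "1", B = "1"), N2,
                     irreversible = "conv", exchange = character(0))
  v2 <- validate_model(m2)
  expect_false(v2$ok)
  expect_match(paste(v2$failures, collapse = " "), "conservation law")
  # catalyst pointing at a non-species
  m3 <- cell_model()
  m3$catalysts[["r_IG"]] <- "NOPE"
  expect_false(validate_model(m3)$ok)
})

test_that("growth rate equals its exchange-only form and vanishes iff Nv=0", {
  m <- cell_model()
  es <- cell_egms()
  set.seed(31)
  for (rep in 1:25) {
    co <- as.character(sample(0:5, 11, replace = TRUE))
    v <- rq_matmul(t(es$flux), co)
    mu_all <- growth_rate(m, v)  # internally asserts the exchange-only form
    Nv <- rat_num(rq_matmul(m$stoich, as_rational(v)))
    expect_equal(mu_all == 0, all(Nv == 0))
  }
  expect_equal(growth_rate(m, rep(0, 11)), 0)
})

test_that("associated concentrations are scale-invariant, nonnegative, and
           mass fractions sum to one", {
  m <- cell_model()
  es <- cell_egms()
  set.seed(17)
  for (rep in 1:10) {
    co <- as.character(sample(1:5, 11, replace = TRUE))
    v <- rq_matmul(t(es$flux), co)
    x1 <- associated_concentrations(m, v, exact = TRUE)
    x2 <- associated_concentrations(m, rq_mul(v, "7/3"), exact = TRUE)
    expect_identical(x1, x2)
    expect_true(all(rq_sign(x1) >= 0))
    expect_equal(rat_num(egrowth:::rq_sum(
      rq_mul(m$molar_masses, x1))), 1)
  }
  expect_error(associated_concentrations(m, rep(0, 11)), "flux mode")
})

test_that("exchange reactions are the mass-imbalanced columns", {
  m <- cell_model()
  expect_setequal(egrowth:::.detect_exchange(m), m$exchange)
})
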