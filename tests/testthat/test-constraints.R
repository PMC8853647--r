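# capacity/membrane constraints, growth polyhedron, EGVs

test_that("capacity constraints assemble the expected rows and units", {
  m <- cell_model()
  cs <- capacity_constraints(m, capacity_params(), "1/2")
  expect_equal(sum(cs$relation == ">="), 7)  # 5 cap + cap R + memb L
  expect_equal(sum(cs$relation == "="), 1)   # membrane area
  expect_setequal(cs$labels,
                  c("cap IG", "cap IN", "cap EAA", "cap ELD", "cap EL",
                    "cap R", "memb area", "memb L"))
  # Table values in canonical units: kcat = 79/s, kel = 8 AA/s
  expect_equal(unname(rat_num(cs$conc["cap IG" == cs$labels, "IG"])),
               79 * 3600)
  expect_equal(unname(rat_num(cs$conc["cap R" == cs$labels, "R"])),
               8 * 3600)
  # ribosome row weights are the amino-acid costs n_i
  expect_equal(unname(rat_num(cs$flux["cap R" == cs$labels, "s_R"])),
               -22608)
  expect_equal(unname(rat_num(cs$flux["cap R" == cs$labels, "s_IG"])),
               -646)
  # the membrane equality has positive right-hand side: all-zero (x, v)
  # violates it
  expect_gt(rat_num(cs$rhs[cs$relation == "="]), 0)
  # r(mu) <= 0 outside the valid range
  expect_error(capacity_constraints(m, capacity_params(), "10/3"),
               "surface-to-volume")
})

test_that("the growth polyhedron is feasible in regime L, infeasible beyond
           mu_max, and fixes the growth rate exactly", {
  m <- cell_model()
  e5 <- cell_egvs("1/2")
  expect_true(e5$feasible)
  e15 <- egvs(m, "3/2")
  expect_false(e15$feasible)
  # w^T N v = mu on every member
  for (i in c(1, 7, 24))
    expect_equal(growth_rate(m, e5$flux[i, ], exact = TRUE), "1/2")
})

test_that("regime L has 24 EGVs, regime H has 10; full support; exactly two
           inactive essential constraints; at most one stored metabolite", {
  e5 <- cell_egvs("1/2")
  expect_equal(nrow(e5$flux), 24)
  expect_equal(nrow(e5$rays), 0)
  e125 <- cell_egvs("5/4")
  expect_equal(nrow(e125$flux), 10)
  expect_equal(length(e5$essential), 11)
  for (ev in list(e5, e125)) {
    expect_true(all(rat_num(ev$flux) > 0))        # full support
    expect_true(all(lengths(ev$signatures) == 2)) # two inactive constraints
    expect_equal(anyDuplicated(ev$signature_key), 0)  # injective signature
    # at most one nonzero metabolite concentration (exact, via signatures):
    # metabolite storage shows up as an inactive mass-balance row
    n_stored <- vapply(ev$signatures, function(s)
      sum(startsWith(s, "mb ")), integer(1))
    expect_true(all(n_stored <= 1))
  }
})

test_that("signatures are stable within a regime", {
  e_a <- cell_egvs("1/2")
  e_b <- egvs(cell_model(), "3/5")
  expect_setequal(e_a$signature_key, e_b$signature_key)
})

test_that("uptake fractions sum to one and the balanced value is
           omega_N / (omega_G + omega_N)", {
  e5 <- cell_egvs("1/2")
  expect_equal(rowSums(e5$gamma), rep(1, 24))
  expect_equal(18 / 198, 0.0909, tolerance = 1e-3)
  # balanced families sit near 0.091 already at mu = 0.5
  bal <- abs(e5$gamma[, "gamma_IN"] - 18 / 198) < 0.02
  expect_gte(sum(bal), 10)
})

test_that("growth vectors decompose convexly over EGVs with the exact
           concentration mixing identity", {
  m <- cell_model()
  e5 <- cell_egvs("1/2")
  # an EGV decomposes as itself
  d0 <- decompose_growth_vector(m, "1/2", e5$flux[3, ], egv_set = e5)
  expect_length(d0$point_terms, 1)
  expect_equal(rat_num(d0$point_terms[[1]]$coef), 1)
  # random convex combinations reconstruct exactly
  set.seed(8)
  for (rep in 1:3) {
    idx <- sample(24, 2)
    lam <- c("2/5", "3/5")
    v <- rq_add(rq_mul(e5$flux[idx[1], ], lam[1]),
                rq_mul(e5$flux[idx[2], ], lam[2]))
    d <- decompose_growth_vector(m, "1/2", v, egv_set = e5)
    expect_true(all(rat_num(d$residual) == 0))
    expect_true(d$convex)
  }
  # every GV is also a GM and decomposes over EGMs
  dgm <- decompose_growth_mode(m, e5$flux[1, ], cell_egms_raw())
  expect_true(all(rat_num(dgm$residual) == 0))
  expect_equal(rat_num(dgm$lambda_sum), 1)
})

test_that("membership violations are reported with row labels", {
  m <- cell_model()
  e5 <- cell_egvs("1/2")
  bad <- rq_mul(e5$flux[1, ], "2")   # doubles the growth rate: mass row off
  expect_error(decompose_growth_vector(m, "1/2", bad, egv_set = e5),
               "mass")
})

test_that("the growth-rate sweep finds both regimes, the transition, the
           feasibility boundary, and the persistence split", {
  sw <- cell_sweep()
  expect_equal(nrow(sw$families), 26)              # EGV families overall
  expect_equal(sort(unique(stats::na.omit(sw$counts))), c(10, 24))
  expect_length(sw$mu_crit, 1)
  expect_equal(sw$mu_crit, 1.21, tolerance = 0.01)
  expect_equal(sw$mu_max, 1.27, tolerance = 0.01)
  expect_equal(sw$count_changes[[1]]$from, 24)
  expect_equal(sw$count_changes[[1]]$to, 10)
  cl <- sw$classes
  expect_equal(sum(cl$persistent), 8)              # exist at all mu
  expect_equal(sum(!cl$persistent & cl$mu_hi < sw$mu_crit + 0.01), 16)
  expect_equal(sum(!cl$persistent & cl$mu_lo > sw$mu_crit - 0.01), 2)
})

test_that("regime-L families merge pairwise-by-eight into the two regime-H
           families", {
  sw <- cell_sweep()
  expect_length(sw$merges, 2)
  froms <- lapply(sw$merges, `[[`, "from")
  expect_equal(sort(lengths(froms)), c(8, 8))
  expect_equal(length(intersect(froms[[1]], froms[[2]])), 0)
})

test_that("uptake classes have the expected sizes and limits", {
  sw <- cell_sweep()
  cl <- sw$classes
  tab <- table(cl$uptake_class)
  expect_equal(tab[["1a"]], 2)
  expect_equal(tab[["2a"]], 1)
  expect_equal(tab[["3a"]], 5)
  expect_equal(tab[["1b"]], 4)
  expect_equal(tab[["2b"]], 2)
  expect_equal(tab[["3b"]], 12)
  # high-ammonium families approach gamma_IN ~ 0.87 at small mu,
  # low-ammonium families approach 0
  hi <- cl$gamma_IN_low[startsWith(cl$uptake_class, "2")]
  expect_true(all(hi > 0.8))
  lo <- cl$gamma_IN_low[cl$uptake_class %in% c("1a", "1b")]
  expect_true(all(lo < 0.15))
})

test_that("ribosome classes: constant-high, linear-through-origin, rest", {
  sw <- cell_sweep()
  cl <- sw$classes
  tab <- table(cl$ribosome_class)
  expect_equal(tab[["I"]], 12)
  expect_equal(tab[["II"]], 9)
  expect_equal(tab[["III"]], 5)
  expect_equal(mean(cl$ribo_mean[cl$ribosome_class == "III"]), 0.9,
               tolerance = 0.05)
})

test_that("per family, carbon storage is non-increasing in growth rate
           throughout regime L", {
  # near mu_max the membrane constraint forces extra lipid (importers crowd
  # the membrane and alpha caps their area share), so monotone decrease is a
  # regime-L statement
  sw <- cell_sweep()
  fam <- sw$family_data
  mc <- max(sw$mu_crit)
  for (k in sw$families$signature) {
    rec <- fam[[k]]
    keep <- rec$mu <= mc - 1e-3
    if (sum(keep) < 2) next
    ord <- order(rec$mu[keep])
    s <- rec$s_C[keep][ord]
    expect_lt(s[length(s)], s[1] + 1e-9)   # net decrease over regime L
    expect_lt(max(diff(s)), 1e-3)          # no appreciable local increase
  }
})

test_that("the EGVs existing in regime H converge onto one flux vector as
           mu approaches mu_max", {
  sw <- cell_sweep()
  m <- cell_model()
  spread_at <- function(delta) {
    ev <- egvs(m, rationalize(sw$mu_max - delta))
    flux <- rat_num(ev$flux)
    max(apply(flux, 2, function(col) diff(range(col)))) / max(flux)
  }
  s <- vapply(c(2e-2, 5e-3, 5e-4), spread_at, numeric(1))
  expect_true(all(diff(s) < 0))   # shrinking towards the merge point
  expect_lt(s[3] / s[1], 0.5)
})

test_that("a model without additional constraints has no finite mu_max:
           the cone scales with mu", {
  m <- cell_model()
  empty_cs <- function(model, mu) NULL
  ev1 <- egvs(m, "1", constraints = NULL,
              params = capacity_params())  # with constraints: bounded
  p2 <- growth_polyhedron(m, NULL, "5")    # no constraints: feasible at 5/h
  expect_silent(evs <- elementary_vectors(p2))
  expect_gt(nrow(evs$point_evs), 0)
})
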