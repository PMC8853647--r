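# elementary vectors of s-cones, general cones and polyhedra, checked
# against closed-form toy examples and brute-force oracles

test_that("toy flux cone (one branch point) has its two support-minimal EVs", {
  sc <- s_cone(matrix(c(1, -1, -1), 1), nonneg_indices = 1:3)
  evs <- elementary_vectors(sc)
  expect_equal(ray_key(rat_num(evs)),
               ray_key(rbind(c(1, 1, 0), c(1, 0, 1))))
  expect_false(any(attr(evs, "sign_ambiguous")))
})

test_that("one-dimensional and degenerate s-cones behave", {
  # half-line R^1 with x >= 0
  sc <- s_cone(matrix("0", 1, 1), nonneg_indices = 1)
  expect_equal(rat_num(elementary_vectors(sc)), matrix(1, 1, 1),
               ignore_attr = TRUE)
  # full line: one representative, flagged sign-ambiguous
  sc2 <- s_cone(matrix("0", 1, 1))
  ev2 <- elementary_vectors(sc2)
  expect_equal(nrow(ev2), 1)
  expect_true(attr(ev2, "sign_ambiguous"))
  expect_equal(rat_num(ev2)[1, 1], 1, ignore_attr = TRUE)
  # the zero cone {x = 0}
  sc3 <- s_cone(diag(2), nonneg_indices = 1:2)
  expect_equal(nrow(elementary_vectors(sc3)), 0)
})

test_that("toy growth cone has its three cND EVs, only one support-minimal", {
  N <- rbind(c(1, -1, -1), c(0, 1, 0), c(0, 0, 1))
  cone <- poly_cone(rbind(N, diag(3)))
  evs <- elementary_vectors(cone)
  expect_equal(ray_key(rat_num(evs)),
               ray_key(rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))))
  # all pass the independent cND test; a conic but non-elementary member fails
  for (i in seq_len(nrow(evs))) expect_true(is_cnd(evs[i, ], cone))
  expect_false(is_cnd(c(2, 1, 1), cone))  # = (1,1,0) + (1,0,1)
  expect_false(is_cnd(c(1, 1), poly_cone(diag(2))))  # quadrant interior
  expect_error(is_cnd(c(0, 0, 0), cone), "nonzero")
})

test_that("quadrant cone has the coordinate rays as EVs", {
  evs <- elementary_vectors(poly_cone(diag(2)))
  expect_equal(ray_key(rat_num(evs)), ray_key(diag(2)))
})

test_that("s-cone enumeration matches the support-pattern oracle", {
  set.seed(421)
  for (rep in 1:6) {
    E <- rand_int_matrix(4, 7)
    sc <- s_cone(E, nonneg_indices = 1:7)
    got <- rat_num(elementary_vectors(sc))
    want <- oracle_scone_evs(E, nonneg = 1:7)
    expect_equal(ray_key(got), ray_key(do.call(rbind, want)),
                 info = paste("rep", rep))
  }
  # with reversible coordinates
  for (rep in 1:4) {
    E <- rand_int_matrix(3, 5)
    nn <- sort(sample(5, 3))
    sc <- s_cone(E, nonneg_indices = nn)
    got <- elementary_vectors(sc)
    want <- oracle_scone_evs(E, nonneg = nn)
    # compare up to sign for the sign-ambiguous rays
    wm <- if (length(want)) do.call(rbind, want) else NULL
    gk <- ray_key(abs(rat_num(got)))
    wk <- if (is.null(wm)) character(0) else ray_key(abs(wm))
    expect_equal(gk, wk, info = paste("rev rep", rep))
  }
})

test_that("cone enumeration matches the per-orthant extreme-ray oracle", {
  set.seed(99)
  reps <- 0
  while (reps < 6) {
    n <- sample(3:4, 1)
    A <- rand_int_matrix(n + sample(1:2, 1), n)
    cone <- poly_cone(A)
    spec <- egrowth:::.spec_of(cone)
    if (egrowth:::.lineality_dim(egrowth:::.reduce_spec(spec)) > 0) next
    reps <- reps + 1
    got <- rat_num(elementary_vectors(cone))
    want <- oracle_cone_evs(A)
    expect_equal(ray_key(got), ray_key(want), info = paste("rep", reps))
    # every reported EV passes is_cnd; perturbed interior members fail it
    for (i in seq_len(nrow(got))) expect_true(is_cnd(got[i, ], cone))
    if (nrow(got) >= 2) {
      mix <- got[1, ] + got[2, ]
      memb <- egrowth:::.membership(spec, as_rational(mix))
      if (memb$ok && !all(mix == 0)) expect_false(is_cnd(mix, cone))
    }
  }
})

test_that("non-pointed cones raise a lineality diagnostic", {
  # a single inequality in R^2 leaves a lineality line
  expect_error(elementary_vectors(poly_cone(matrix(c(1, 0), 1, 2))),
               class = "egrowth_lineality")
})

test_that("polyhedron EVs: intervals, half-lines, infeasibility", {
  # [1, 2]: two ccND points, no rays
  p <- polyhedron(matrix(c(1, -1), 2, 1), c(1, -2),
                  row_labels = c("lo", "hi"))
  evs <- elementary_vectors(p)
  expect_equal(sort(rat_num(evs$point_evs)[, 1]), c(1, 2))
  expect_equal(nrow(evs$ray_evs), 0)
  expect_true(is_ccnd("1", p))
  expect_false(is_ccnd("3/2", p))
  # half-line [1, inf): one point, one ray
  p2 <- polyhedron(matrix(1, 1, 1), "1", row_labels = "lo")
  evs2 <- elementary_vectors(p2)
  expect_equal(rat_num(evs2$point_evs)[, 1], 1, ignore_attr = TRUE)
  expect_equal(rat_num(evs2$ray_evs)[, 1], 1, ignore_attr = TRUE)
  # infeasible: x >= 2 and -x >= -1
  p3 <- polyhedron(matrix(c(1, -1), 2, 1), c(2, -1))
  expect_error(elementary_vectors(p3), class = "egrowth_infeasible")
})

test_that("random polytopes: point EVs equal the vertex-enumeration oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 3
    # bounded polytope in the nonnegative orthant: x >= 0, random upper rows
    A <- rbind(diag(n), -rand_int_matrix(2, n, lo = 1, hi = 3))
    b <- c(rep(0, n), -sample(5:9, 2, replace = TRUE))
    p <- polyhedron(A, b)
    evs <- elementary_vectors(p)
    expect_equal(nrow(evs$ray_evs), 0)
    want <- oracle_polytope_vertices(A, b)
    expect_equal(ray_key(rat_num(evs$point_evs) + 1),  # +1: avoid 0-row norm
                 ray_key(want + 1), info = paste("rep", rep))
    for (i in seq_len(nrow(evs$point_evs)))
      expect_true(is_ccnd(evs$point_evs[i, ], p))
  }
})

test_that("homogenization is consistent: b = 0 gives the recession cone", {
  N <- rbind(c(1, -1, -1), c(0, 1, 0), c(0, 0, 1))
  A <- rbind(N, diag(3))
  p <- polyhedron(A, rep("0", 6))
  evs <- elementary_vectors(p)
  cone_evs <- elementary_vectors(poly_cone(A))
  expect_equal(ray_key(rat_num(evs$ray_evs)), ray_key(rat_num(cone_evs)))
  # 0 is the only ccND point of a cone-shaped polyhedron and is reported
  expect_equal(nrow(evs$point_evs), 1)
  expect_true(all(rat_num(evs$point_evs) == 0))
})

test_that("s-cone specialization: {Nv = 0, v >= 0} via both routes agrees", {
  set.seed(11)
  N <- rand_int_matrix(2, 4)
  sc <- s_cone(N, nonneg_indices = 1:4)
  pc <- poly_cone(rbind(N, -N, diag(4)))
  expect_equal(ray_key(rat_num(elementary_vectors(sc))),
               ray_key(rat_num(elementary_vectors(pc))))
})

test_that("conformal decomposition reconstructs exactly, in sign-compatible
           terms, within the cardinality bound", {
  N <- rbind(c(1, -1, -1), c(0, 1, 0), c(0, 0, 1))
  cone <- poly_cone(rbind(N, diag(3)))
  evs <- elementary_vectors(cone)
  # an EV decomposes as itself
  d0 <- conformal_decompose(evs[1, ], cone, evs)
  expect_length(d0$ray_terms, 1)
  expect_equal(rat_num(d0$ray_terms[[1]]$coef), 1)
  # the worked target (3,1,1) = (1,0,0) + (1,1,0) + (1,0,1)
  d1 <- conformal_decompose(c(3, 1, 1), cone, evs)
  expect_length(d1$ray_terms, 3)
  expect_equal(sort(vapply(d1$ray_terms, function(t) rat_num(t$coef),
                           numeric(1))), c(1, 1, 1))
  # random conic combinations: exact reconstruction, sign compatibility,
  # |terms| <= |supp(x)| + |supp(Ax)|
  set.seed(5)
  A <- rbind(N, diag(3))
  for (rep in 1:20) {
    co <- sample(0:4, nrow(evs), replace = TRUE)
    target <- rat_num(t(evs)) %*% co
    if (all(target == 0)) next
    d <- conformal_decompose(as.vector(target), cone, evs)
    expect_true(all(rat_num(d$residual) == 0))
    for (tm in d$ray_terms) {
      se <- sign(rat_num(tm$ev)); st <- sign(as.vector(target))
      expect_true(all(se == 0 | se == st))
    }
    bound <- sum(target != 0) + sum(abs(A %*% target) > 0)
    expect_lte(length(d$ray_terms), bound)
  }
  # membership failures name the violated rows
  expect_error(conformal_decompose(c(-1, 0, 0), cone, evs), "irr|mb|r[0-9]")
})

test_that("polyhedron decomposition is convex on point terms", {
  p <- polyhedron(rbind(diag(2), c(-1, -1)), c(0, 0, -4))
  evs <- elementary_vectors(p)
  set.seed(2)
  for (rep in 1:10) {
    w <- runif(nrow(evs$point_evs))
    w <- round(w / sum(w), 3)
    w[1] <- 1 - sum(w[-1])
    target <- as.vector(rat_num(t(evs$point_evs)) %*% w)
    d <- conformal_decompose(target, p, evs)
    expect_true(all(rat_num(d$residual) == 0))
    expect_true(d$convex)
  }
})

test_that("float-mode enumeration agrees with exact mode on a small cone", {
  N <- rbind(c(1, -1, -1), c(0, 1, 0), c(0, 0, 1))
  cone <- poly_cone(rbind(N, diag(3)))
  exact <- rat_num(elementary_vectors(cone))
  fl <- elementary_vectors(cone, arithmetic = "float")
  expect_equal(ray_key(fl), ray_key(exact))
})
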