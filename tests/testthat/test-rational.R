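test_that("rational conversion and arithmetic are exact", {
  expect_equal(as_rational(c(1, 0.5, -2.25)), c("1", "1/2", "-9/4"))
  expect_equal(as_rational("6/4"), "3/2")
  expect_equal(rat_num("22608/198"), 22608 / 198)
  expect_equal(rationalize(1.21), "121/100")
  expect_equal(rationalize(0.091), "91/1000")
  # exact arithmetic with large intermediate values
  x <- "1"
  for (i in 1:150) x <- egrowth:::rq_mul(x, "3")
  y <- x
  for (i in 1:150) y <- egrowth:::rq_div(y, "3")
  expect_equal(y, "1")
  expect_equal(egrowth:::rq_add("1/3", "1/6"), "1/2")
  expect_equal(egrowth:::rq_dot(c("1/2", "2"), c("4", "1/4")), "5/2")
})

test_that("rational matrices round-trip through TSV", {
  M <- matrix(c("1/3", "-2", "0", "22608/198"), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  f <- tempfile(fileext = ".tsv")
  write_rational_tsv(M, f)
  M2 <- read_rational_tsv(f)
  expect_equal(rat_num(M2), rat_num(M))
  expect_equal(M2["b", "c2"], "1256/11")  # canonicalized on read
})
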