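#' Exact rational scalars, vectors and matrices
#'
#' Throughout the package, exact rational values are carried as character
#' strings of the form \code{"p/q"} (or plain integers \code{"p"}).  All
#' arithmetic on them is performed in compiled code with arbitrary-precision
#' integers, so enumeration results, active-set signatures and counts are
#' exact.  These helpers convert between representations.
#'
#' \code{as_rational()} converts numeric input exactly: every double is a
#' dyadic rational \eqn{m \cdot 2^{-k}} and is converted without rounding.
#' Use \code{rationalize()} when a decimal-looking double (e.g. \code{1.21})
#' should be read as the nearby small-denominator fraction (121/100) instead
#' of its exact binary expansion.
#'
#' @param x numeric or character vector/matrix (character entries "p/q")
#' @return character vector/matrix of canonical rationals
#' @examples
#' as_rational(c(1, 0.5, -2.25))
#' rationalize(1.21)
#' rat_num("22608/198")
#' @export
as_rational <- function(x) {
  if (is.character(x)) {
    out <- cxx_rat_canon(x)
  } else if (is.numeric(x)) {
    out <- vapply(as.numeric(x), .dbl_to_rat, character(1))
  } else {
    stop("cannot convert to rational: ", class(x)[1])
  }
  if (is.matrix(x)) {
    out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  } else if (!is.null(names(x))) {
    names(out) <- names(x)
  }
  out
}

.dbl_to_rat <- function(v) {
  if (is.na(v) || !is.finite(v)) stop("non-finite value cannot be rational")
  if (v == 0) return("0")
  k <- 0L
  m <- v
  while (m != round(m)) {
    m <- m * 2
    k <- k + 1L
    if (k > 1100L) stop("value cannot be converted exactly")  # unreachable
  }
  if (abs(m) >= 2^53) stop("numeric value too large for exact conversion")
  num <- sprintf("%.0f", m)
  if (k == 0L) return(num)
  cxx_elementwise(num, .pow2_str(k), "/")
}

# 2^k as an exact decimal string (k may exceed the double exponent range)
.pow2_str <- function(k) {
  out <- "1"
  base <- "2"
  while (k > 0L) {
    if (k %% 2L == 1L) out <- cxx_elementwise(out, base, "*")
    base <- cxx_elementwise(base, base, "*")
    k <- k %/% 2L
  }
  out
}

#' @rdname as_rational
#' @param tol acceptable absolute error of the approximating fraction
#' @param maxden largest denominator tried
#' @export
rationalize <- function(x, tol = 1e-9, maxden = 1e7) {
  vapply(as.numeric(x), function(v) {
    if (v == round(v)) return(sprintf("%.0f", v))
    # continued-fraction convergents
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
    a <- v
    repeat {
      ai <- floor(a)
      p2 <- ai * p1 + p0
      q2 <- ai * q1 + q0
      if (q2 > maxden) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      if (abs(p1 / q1 - v) < tol) break
      if (a == ai) break
      a <- 1 / (a - ai)
    }
    if (abs(p1 / q1 - v) >= tol) return(.dbl_to_rat(v))
    sprintf("%.0f/%.0f", p1, q1)
  }, character(1))
}

#' @rdname as_rational
#' @export
rat_num <- function(x) {
  out <- cxx_rat_to_num(as.character(x))
  if (is.matrix(x)) {
    out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  } else if (!is.null(names(x))) {
    names(out) <- names(x)
  }
  out
}

# elementwise exact arithmetic with recycling, shape-preserving
.rq <- function(a, b, op) {
  shape <- if (is.matrix(a)) a else if (is.matrix(b)) b else a
  out <- cxx_elementwise(as.character(a), as.character(b), op)
  if (is.matrix(shape)) out <- matrix(out, nrow(shape), ncol(shape),
                                      dimnames = dimnames(shape))
  else names(out) <- names(shape)
  out
}
rq_add <- function(a, b) .rq(a, b, "+")
rq_sub <- function(a, b) .rq(a, b, "-")
rq_mul <- function(a, b) .rq(a, b, "*")
rq_div <- function(a, b) .rq(a, b, "/")

# exact matrix product; accepts vectors as single-column matrices
rq_matmul <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, nrow = 1)
  bvec <- !is.matrix(B)
  if (bvec) B <- matrix(B, ncol = 1)
  out <- cxx_matmul(A, B)
  rn <- rownames(A)
  cn <- colnames(B)
  dimnames(out) <- list(rn, cn)
  if (bvec) out <- stats::setNames(out[, 1], rn)
  out
}

# exact dot product
rq_dot <- function(a, b) rq_matmul(matrix(a, nrow = 1), matrix(b, ncol = 1))[1]

rq_sum <- function(a) {
  if (length(a) == 0) return("0")
  rq_matmul(matrix(rep("1", length(a)), nrow = 1), matrix(a, ncol = 1))[1]
}

rq_sign <- function(a) {
  n <- rat_num(a)
  sign(n)
}

#' Read and write matrices of exact rationals as TSV
#'
#' Entries use the \code{"p/q"} syntax (plain integers allowed).  Row and
#' column names are preserved (first column holds row names when present).
#'
#' @param file path
#' @param x character matrix of rationals
#' @export
read_rational_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (colnames(df)[1] %in% c("", "row", ".row")) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
  }
  matrix(cxx_rat_canon(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' @rdname read_rational_tsv
#' @export
write_rational_tsv <- function(x, file) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(rownames(x))) df <- cbind(.row = rownames(x), df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
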