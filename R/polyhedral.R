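#' Polyhedral cones, s-cones, polyhedra and their elementary vectors
#'
#' The generating sets used throughout this package are *conformal*
#' generators: decompositions without cancellation, i.e. every term `e`
#' satisfies `sign(e) <= sign(x)` componentwise.  For an s-cone
#' \eqn{C(S,I) = \{x \in S, x_I \ge 0\}} the elementary vectors (EVs) are the
#' support-minimal vectors; for a general polyhedral cone
#' \eqn{C = \{x : Ax \ge 0\}} they are the conformally non-decomposable (cND)
#' vectors; for a polyhedron \eqn{P = \{x : Ax \ge b\}} they are the
#' convex-conformally non-decomposable (ccND) points of \eqn{P} together with
#' the cND vectors of the recession cone \eqn{R = \{x : Ax \ge 0\}}.
#'
#' Enumeration runs over exact rational arithmetic.  General cones are lifted
#' to a fully nonnegative s-cone by splitting free coordinates
#' (\eqn{x = x^+ - x^-}) and adding one slack per inequality row; the
#' support-minimal vectors of the lift are enumerated by double description
#' and mapped back, discarding artifacts with \eqn{x^+ \circ x^- \ne 0}.
#' This is the standard correspondence between conformal non-decomposability
#' and support minimality exploited by elementary-flux-mode software.
#' Polyhedra are homogenized: EVs of the cone
#' \eqn{\{(x,t) : Ax - bt \ge 0, t \ge 0\}} are split by \eqn{t > 0}
#' (rescaled to \eqn{t = 1}: the ccND points) versus \eqn{t = 0} (the
#' recession-cone EVs).
#'
#' @name polyhedral
NULL

# ---------------------------------------------------------------------------
# internal cone specification
#
# list(n, vn = variable names, ineq = labeled chr matrix (rows: a x >= 0),
#      eq = chr matrix (rows: g x = 0), nonneg = coordinate indices with
#      x_j >= 0)
# ---------------------------------------------------------------------------

.conespec <- function(n, vn = paste0("x", seq_len(n)), ineq = NULL, eq = NULL,
                      nonneg = integer(0)) {
  if (!is.null(ineq)) ineq <- as_rational(ineq)
  if (!is.null(eq)) eq <- as_rational(eq)
  list(n = n, vn = vn, ineq = ineq, eq = eq, nonneg = sort(unique(nonneg)))
}

# merge inequality rows that are positive multiples of a coordinate axis into
# the nonneg set, and drop rows that are positive multiples of an earlier row
# (exact duplicate removal).  Returns the reduced spec plus bookkeeping.
.reduce_spec <- function(spec) {
  merged <- character(0)
  if (is.null(spec$ineq) || nrow(spec$ineq) == 0) {
    return(c(spec, list(merged_labels = merged)))
  }
  A <- spec$ineq
  keep <- rep(TRUE, nrow(A))
  num <- rat_num(A)
  keys <- character(nrow(A))
  for (i in seq_len(nrow(A))) {
    nz <- which(num[i, ] != 0)
    if (length(nz) == 0) { keep[i] <- FALSE; next }
    # canonical direction of the row for duplicate detection
    canon <- cxx_canon_rows(matrix(A[i, ], 1))
    keys[i] <- paste(canon, collapse = ",")
    if (length(nz) == 1 && num[i, nz] > 0) {
      spec$nonneg <- sort(unique(c(spec$nonneg, nz)))
      merged <- c(merged, rownames(A)[i])
      keep[i] <- FALSE
      next
    }
    if (i > 1 && keys[i] %in% keys[seq_len(i - 1)][keep[seq_len(i - 1)]]) {
      keep[i] <- FALSE
      merged <- c(merged, rownames(A)[i])
    }
  }
  spec$ineq <- A[keep, , drop = FALSE]
  c(spec, list(merged_labels = merged))
}

.lineality_dim <- function(spec) {
  rows <- NULL
  if (!is.null(spec$ineq) && nrow(spec$ineq)) rows <- rbind(rows, spec$ineq)
  if (!is.null(spec$eq) && nrow(spec$eq)) rows <- rbind(rows, spec$eq)
  if (length(spec$nonneg)) {
    un <- matrix("0", length(spec$nonneg), spec$n)
    un[cbind(seq_along(spec$nonneg), spec$nonneg)] <- "1"
    rows <- rbind(rows, un)
  }
  if (is.null(rows)) return(spec$n)
  spec$n - cxx_rank(rows)
}

# elementary vectors of the cone described by spec (rows of returned matrix,
# canonical coprime integers).  Requires a pointed cone.
.ev_cone <- function(spec, check_pointed = TRUE) {
  spec <- .reduce_spec(spec)
  if (check_pointed && .lineality_dim(spec) > 0) {
    stop(structure(class = c("egrowth_lineality", "error", "condition"),
                   list(message = paste0(
                     "cone has a nontrivial lineality space (dimension ",
                     .lineality_dim(spec), "); elementary vectors are only ",
                     "enumerated for pointed cones"),
                     call = sys.call(-1))))
  }
  n <- spec$n
  free <- setdiff(seq_len(n), spec$nonneg)
  mi <- if (is.null(spec$ineq)) 0L else nrow(spec$ineq)
  nz <- n + length(free) + mi
  # column map: coordinate j -> +column; free j additionally -> -column
  poscol <- seq_len(n)
  negcol <- integer(n)
  if (length(free)) negcol[free] <- n + seq_along(free)
  liftrow <- function(row) {
    out <- character(nz)
    out[] <- "0"
    out[poscol] <- row
    if (length(free)) out[negcol[free]] <- rq_mul(row[free], "-1")
    out
  }
  M <- NULL
  if (!is.null(spec$eq) && nrow(spec$eq)) {
    M <- t(apply(spec$eq, 1, liftrow))
  }
  if (mi > 0) {
    Mi <- t(apply(spec$ineq, 1, liftrow))
    for (i in seq_len(mi)) Mi[i, n + length(free) + i] <- "-1"
    M <- rbind(M, Mi)
  }
  if (is.null(M)) M <- matrix(character(0), 0, nz)
  zrays <- cxx_dd_rays(M, as.integer(nz))
  if (nrow(zrays) == 0) {
    out <- matrix(character(0), 0, n, dimnames = list(NULL, spec$vn))
    return(out)
  }
  # drop split artifacts (x+ and x- simultaneously nonzero)
  if (length(free)) {
    pos <- rat_num(zrays[, free, drop = FALSE]) != 0
    neg <- rat_num(zrays[, negcol[free], drop = FALSE]) != 0
    keep <- !apply(pos & neg, 1, any)
    zrays <- zrays[keep, , drop = FALSE]
  }
  X <- zrays[, seq_len(n), drop = FALSE]
  if (length(free)) {
    X[, free] <- rq_sub(X[, free, drop = FALSE],
                        zrays[, negcol[free], drop = FALSE])
  }
  # drop all-zero images and re-canonicalize over the retained coordinates
  nzero <- apply(rat_num(X) != 0, 1, any)
  X <- X[nzero, , drop = FALSE]
  if (nrow(X)) X <- cxx_canon_rows(X)
  X <- unique(X)
  colnames(X) <- spec$vn
  X
}

# stable ordering of EV rows (numeric lexicographic)
.order_rows <- function(X) {
  if (nrow(X) < 2) return(X)
  num <- rat_num(X)
  X[do.call(order, as.data.frame(num)), , drop = FALSE]
}

# membership of v: list(ok, violated = labels)
.membership <- function(spec, v) {
  v <- as_rational(v)
  bad <- character(0)
  if (!is.null(spec$ineq) && nrow(spec$ineq)) {
    s <- cxx_residual_signs(spec$ineq, rep("0", nrow(spec$ineq)),
                            matrix(v, ncol = 1))
    viol <- s[, 1] < 0
    bad <- c(bad, rownames(spec$ineq)[viol])
  }
  if (!is.null(spec$eq) && nrow(spec$eq)) {
    s <- cxx_residual_signs(spec$eq, rep("0", nrow(spec$eq)),
                            matrix(v, ncol = 1))
    viol <- s[, 1] != 0
    labs <- rownames(spec$eq)
    if (is.null(labs)) labs <- paste0("eq", seq_len(nrow(spec$eq)))
    bad <- c(bad, labs[viol])
  }
  if (length(spec$nonneg)) {
    viol <- rq_sign(v[spec$nonneg]) < 0
    bad <- c(bad, paste0("nonneg ", spec$vn[spec$nonneg][viol]))
  }
  list(ok = length(bad) == 0, violated = bad)
}

# ---------------------------------------------------------------------------
# exported types
# ---------------------------------------------------------------------------

#' S-cones: subspace plus nonnegativity constraints
#'
#' An s-cone is \eqn{C(S, I) = \{x : x \in S, x_I \ge 0\}} where
#' \eqn{S = \ker(E)} for the equality matrix \eqn{E}.  Its elementary vectors
#' are the support-minimal elements (classical elementary flux modes when
#' \eqn{E} is a stoichiometric matrix and \eqn{I} the irreversible reactions).
#'
#' @param equality_matrix matrix (numeric or rational character) whose kernel
#'   is the subspace \eqn{S}; needs \code{n} columns
#' @param nonneg_indices indices \eqn{I} of coordinates constrained
#'   nonnegative
#' @param varnames optional coordinate names
#' @return an object of class \code{s_cone}
#' @seealso [elementary_vectors()]
#' @export
s_cone <- function(equality_matrix, nonneg_indices = integer(0),
                   varnames = NULL) {
  E <- as_rational(equality_matrix)
  if (!is.matrix(E)) E <- matrix(E, nrow = 1)
  n <- ncol(E)
  if (length(nonneg_indices) && (min(nonneg_indices) < 1 ||
                                 max(nonneg_indices) > n))
    stop("nonneg_indices out of range")
  vn <- varnames %||% colnames(E) %||% paste0("x", seq_len(n))
  structure(list(eq = E, nonneg = sort(unique(as.integer(nonneg_indices))),
                 n = n, vn = vn),
            class = "s_cone")
}

#' General polyhedral cones
#'
#' A polyhedral cone \eqn{C = \{x : Ax \ge 0\}} (optionally with explicit
#' equality rows \eqn{Gx = 0}, which are kept as equalities rather than split
#' into inequality pairs).  Elementary vectors are the conformally
#' non-decomposable elements.
#'
#' @param ineq_matrix inequality rows \eqn{A} (each row \eqn{a^T x \ge 0});
#'   row names are used as constraint labels
#' @param eq_matrix optional equality rows
#' @param varnames optional coordinate names
#' @return an object of class \code{poly_cone}
#' @export
poly_cone <- function(ineq_matrix, eq_matrix = NULL, varnames = NULL) {
  A <- as_rational(ineq_matrix)
  if (!is.matrix(A)) A <- matrix(A, nrow = 1)
  if (is.null(rownames(A))) rownames(A) <- paste0("r", seq_len(nrow(A)))
  G <- if (!is.null(eq_matrix)) {
    G <- as_rational(eq_matrix)
    if (!is.matrix(G)) matrix(G, nrow = 1) else G
  }
  vn <- varnames %||% colnames(A) %||% paste0("x", seq_len(ncol(A)))
  structure(list(ineq = A, eq = G, n = ncol(A), vn = vn),
            class = "poly_cone")
}

#' Polyhedra
#'
#' \eqn{P = \{x : Ax \ge b\}}, with selected rows marked as equalities.
#'
#' @param ineq_matrix constraint rows \eqn{A}
#' @param rhs right-hand side \eqn{b}
#' @param row_labels labels per row (defaults to row names of
#'   \code{ineq_matrix})
#' @param eq_mask logical; \code{TRUE} rows hold with equality
#' @param varnames optional coordinate names
#' @return an object of class \code{polyhedron}
#' @export
polyhedron <- function(ineq_matrix, rhs, row_labels = NULL,
                       eq_mask = NULL, varnames = NULL) {
  A <- as_rational(ineq_matrix)
  if (!is.matrix(A)) A <- matrix(A, nrow = 1)
  b <- as_rational(rhs)
  if (length(b) != nrow(A)) stop("length(rhs) must equal nrow(ineq_matrix)")
  labs <- row_labels %||% rownames(A) %||% paste0("r", seq_len(nrow(A)))
  if (length(labs) != nrow(A)) stop("row_labels length mismatch")
  if (anyDuplicated(labs)) stop("row labels must be unique")
  eqm <- eq_mask %||% rep(FALSE, nrow(A))
  if (length(eqm) != nrow(A)) stop("eq_mask length mismatch")
  rownames(A) <- labs
  vn <- varnames %||% colnames(A) %||% paste0("x", seq_len(ncol(A)))
  colnames(A) <- vn
  structure(list(ineq = A, rhs = b, labels = labs, eq_mask = eqm,
                 n = ncol(A), vn = vn),
            class = "polyhedron")
}

.spec_of <- function(x) {
  if (inherits(x, "s_cone")) {
    .conespec(x$n, x$vn, eq = x$eq, nonneg = x$nonneg)
  } else if (inherits(x, "poly_cone")) {
    .conespec(x$n, x$vn, ineq = x$ineq, eq = x$eq)
  } else if (inherits(x, "polyhedron")) {
    # recession-cone spec (b -> 0), used for membership of homogeneous parts
    .conespec(x$n, x$vn, ineq = x$ineq[!x$eq_mask, , drop = FALSE],
              eq = x$ineq[x$eq_mask, , drop = FALSE])
  } else stop("unsupported geometry object")
}

# homogenization of a polyhedron to a cone spec in (x, t)
.homog_spec <- function(p) {
  A <- p$ineq
  b <- p$rhs
  Ah <- cbind(A, rq_mul(b, "-1"))
  colnames(Ah) <- c(p$vn, ".t")
  ineq <- Ah[!p$eq_mask, , drop = FALSE]
  eq <- Ah[p$eq_mask, , drop = FALSE]
  .conespec(p$n + 1L, c(p$vn, ".t"),
            ineq = if (nrow(ineq)) ineq,
            eq = if (nrow(eq)) eq,
            nonneg = p$n + 1L)
}

# ---------------------------------------------------------------------------
# elementary vectors
# ---------------------------------------------------------------------------

#' Enumerate elementary vectors
#'
#' For an \code{s_cone}: all support-minimal vectors, one canonical
#' representative per ray (coprime integer entries).  Rays whose support
#' avoids the nonnegative index set come in \eqn{\pm} pairs; these are
#' collapsed to the representative with positive first nonzero entry and
#' flagged in the \code{sign_ambiguous} attribute.
#'
#' For a \code{poly_cone}: the unique minimal set of conformal generators
#' (the cND vectors), canonically scaled.
#'
#' For a \code{polyhedron}: a list with \code{point_evs} (ccND points, scaled
#' to the polyhedron, i.e. \eqn{t = 1}) and \code{ray_evs} (cND generators of
#' the recession cone).  An infeasible polyhedron raises an error of class
#' \code{egrowth_infeasible} — distinct from a feasible polyhedron with few
#' generators.
#'
#' @param x an \code{s_cone}, \code{poly_cone} or \code{polyhedron}
#' @param ... unused
#' @return matrix of EVs (rows), or for polyhedra a list; see Details
#' @examples
#' # flux cone of a 3-reaction chain: 2 support-minimal EVs
#' sc <- s_cone(matrix(c(1, -1, -1), 1), nonneg_indices = 1:3)
#' elementary_vectors(sc)
#' @export
elementary_vectors <- function(x, ...) UseMethod("elementary_vectors")

#' @export
elementary_vectors.s_cone <- function(x, ...) {
  # the reversible part of an s-cone is a subspace: lineality is expected
  # and handled by +/- pair collapsing, so no pointedness check here
  evs <- .ev_cone(.spec_of(x), check_pointed = FALSE)
  if (nrow(evs) == 0) {
    attr(evs, "sign_ambiguous") <- logical(0)
    return(evs)
  }
  num <- rat_num(evs)
  revsupp <- apply(num[, x$nonneg, drop = FALSE] != 0, 1, any)
  ambiguous <- !revsupp
  # collapse +/- pairs: canonical representative has positive first nonzero
  flip <- ambiguous & apply(num, 1, function(r) r[which(r != 0)[1]] < 0)
  if (any(flip)) {
    evs[flip, ] <- matrix(rq_mul(evs[flip, , drop = FALSE], "-1"),
                          sum(flip))
  }
  key <- apply(evs, 1, paste, collapse = ",")
  keep <- !duplicated(key)
  evs <- evs[keep, , drop = FALSE]
  evs <- .order_rows(evs)
  attr(evs, "sign_ambiguous") <-
    !apply(rat_num(evs)[, x$nonneg, drop = FALSE] != 0, 1, any)
  evs
}

#' @param arithmetic \code{"rational"} (exact, the default) or
#'   \code{"float"}: double-precision double description with tolerance
#'   \code{tol}, for models where exact arithmetic is too slow.  Counts and
#'   signatures are only guaranteed in rational mode.
#' @param tol float-mode zero tolerance
#' @rdname elementary_vectors
#' @export
elementary_vectors.poly_cone <- function(x, arithmetic = c("rational",
                                                           "float"),
                                         tol = 1e-9, ...) {
  arithmetic <- match.arg(arithmetic)
  if (arithmetic == "float") return(.ev_cone_float(.spec_of(x), tol))
  .order_rows(.ev_cone(.spec_of(x)))
}

# double-precision variant of .ev_cone; returns a numeric matrix of rays
# scaled to unit maximum entry
.ev_cone_float <- function(spec, tol = 1e-9) {
  spec <- .reduce_spec(spec)
  n <- spec$n
  free <- setdiff(seq_len(n), spec$nonneg)
  mi <- if (is.null(spec$ineq)) 0L else nrow(spec$ineq)
  nz <- n + length(free) + mi
  negcol <- integer(n)
  if (length(free)) negcol[free] <- n + seq_along(free)
  liftrow <- function(row) {
    out <- numeric(nz)
    out[seq_len(n)] <- row
    if (length(free)) out[negcol[free]] <- -row[free]
    out
  }
  M <- NULL
  if (!is.null(spec$eq) && nrow(spec$eq))
    M <- t(apply(rat_num(spec$eq), 1, liftrow))
  if (mi > 0) {
    Mi <- t(apply(rat_num(spec$ineq), 1, liftrow))
    for (i in seq_len(mi)) Mi[i, n + length(free) + i] <- -1
    M <- rbind(M, Mi)
  }
  if (is.null(M)) M <- matrix(numeric(0), 0, nz)
  zrays <- cxx_dd_rays_float(M, as.integer(nz), tol)
  if (nrow(zrays) == 0)
    return(matrix(numeric(0), 0, n, dimnames = list(NULL, spec$vn)))
  if (length(free)) {
    artifact <- apply(abs(zrays[, free, drop = FALSE]) > tol &
                        abs(zrays[, negcol[free], drop = FALSE]) > tol,
                      1, any)
    zrays <- zrays[!artifact, , drop = FALSE]
  }
  X <- zrays[, seq_len(n), drop = FALSE]
  if (length(free))
    X[, free] <- X[, free, drop = FALSE] -
      zrays[, negcol[free], drop = FALSE]
  keep <- apply(abs(X) > tol, 1, any)
  X <- X[keep, , drop = FALSE]
  X <- t(apply(X, 1, function(r) r / max(abs(r))))
  X <- X[!duplicated(round(X, 6)), , drop = FALSE]
  colnames(X) <- spec$vn
  X
}

#' @export
elementary_vectors.polyhedron <- function(x, ...) {
  hs <- .homog_spec(x)
  evs <- .ev_cone(hs)
  tcol <- x$n + 1L
  tval <- rat_num(evs[, tcol])
  pts <- evs[tval > 0, , drop = FALSE]
  rys <- evs[tval == 0, seq_len(x$n), drop = FALSE]
  if (nrow(pts) == 0) {
    stop(structure(class = c("egrowth_infeasible", "error", "condition"),
                   list(message = "polyhedron is infeasible (empty)",
                        call = sys.call(-1))))
  }
  # rescale points to t = 1
  P <- matrix("0", nrow(pts), x$n, dimnames = list(NULL, x$vn))
  for (i in seq_len(nrow(pts))) {
    P[i, ] <- rq_div(pts[i, seq_len(x$n)], pts[i, tcol])
  }
  colnames(rys) <- x$vn
  list(point_evs = .order_rows(P), ray_evs = .order_rows(rys))
}

# ---------------------------------------------------------------------------
# conformal non-decomposability tests
# ---------------------------------------------------------------------------

#' Test conformal non-decomposability
#'
#' \code{is_cnd()} decides whether a nonzero member \eqn{v} of a polyhedral
#' cone is conformally non-decomposable: every decomposition
#' \eqn{v = x^1 + x^2} into sign-compatible cone members forces
#' \eqn{x^1 \propto x^2}.  Sign-compatible decompositions live on the minimal
#' face of the cone through \eqn{v} intersected with \eqn{v}'s closed
#' orthant, so \eqn{v} is cND exactly when the linear system
#' \eqn{\{A_{act} x = 0,\; x_j = 0 \; (v_j = 0)\}} has a one-dimensional
#' solution space.  \code{is_ccnd()} is the polyhedron analogue: \eqn{v} is
#' convex-conformally non-decomposable iff the affine system
#' \eqn{\{A_{act} x = b_{act},\; x_j = 0\; (v_j = 0)\}} pins \eqn{x} down
#' uniquely.
#'
#' @param v vector (numeric or rational character)
#' @param cone a \code{poly_cone}
#' @param poly a \code{polyhedron}
#' @return logical flag
#' @export
is_cnd <- function(v, cone) {
  v <- as_rational(v)
  if (all(rq_sign(v) == 0)) stop("cND is defined for nonzero vectors only")
  memb <- .membership(.spec_of(cone), v)
  if (!memb$ok) stop("vector is not a member of the cone; violated: ",
                     paste(memb$violated, collapse = ", "))
  rows <- NULL
  if (!is.null(cone$ineq) && nrow(cone$ineq)) {
    s <- cxx_residual_signs(cone$ineq, rep("0", nrow(cone$ineq)),
                            matrix(v, ncol = 1))
    rows <- rbind(rows, cone$ineq[s[, 1] == 0, , drop = FALSE])
  }
  if (!is.null(cone$eq) && nrow(cone$eq)) rows <- rbind(rows, cone$eq)
  zero <- which(rq_sign(v) == 0)
  if (length(zero)) {
    un <- matrix("0", length(zero), cone$n)
    un[cbind(seq_along(zero), zero)] <- "1"
    rows <- rbind(rows, un)
  }
  nullity <- if (is.null(rows)) cone$n else cone$n - cxx_rank(rows)
  nullity == 1
}

#' @rdname is_cnd
#' @export
is_ccnd <- function(v, poly) {
  v <- as_rational(v)
  s <- cxx_residual_signs(poly$ineq, poly$rhs, matrix(v, ncol = 1))[, 1]
  if (any(s < 0) || any(s[poly$eq_mask] != 0))
    stop("vector is not a member of the polyhedron; violated: ",
         paste(poly$labels[s < 0 | (poly$eq_mask & s != 0)], collapse = ", "))
  act <- s == 0
  rows <- poly$ineq[act, , drop = FALSE]
  zero <- which(rq_sign(v) == 0)
  if (length(zero)) {
    un <- matrix("0", length(zero), poly$n)
    un[cbind(seq_along(zero), zero)] <- "1"
    rows <- rbind(rows, un)
  }
  nullity <- if (nrow(rows) == 0) poly$n else poly$n - cxx_rank(rows)
  nullity == 0
}

# ---------------------------------------------------------------------------
# conformal decomposition
# ---------------------------------------------------------------------------

#' Conformal decomposition over elementary vectors
#'
#' Writes a member of a cone (polyhedron) as a nonnegative (convex)
#' combination of sign-compatible elementary vectors, without cancellations.
#' The greedy construction subtracts, at each step, the largest
#' sign-compatible multiple of an EV that keeps the remainder inside the
#' cone; each step zeroes a coordinate of the remainder or of its constraint
#' image, which bounds the number of terms by
#' \eqn{|supp(x)| + |supp(Ax)|} (plus one for polyhedra).
#'
#' @param target member vector
#' @param x a \code{poly_cone}, \code{s_cone} or \code{polyhedron}
#' @param evs optional precomputed EV set (as returned by
#'   [elementary_vectors()]); computed if missing
#' @return object of class \code{conformal_decomposition} with elements
#'   \code{ray_terms}, \code{point_terms} (lists of \code{list(ev, coef)}),
#'   \code{convex} flag and the reconstruction residual (exactly zero)
#' @export
conformal_decompose <- function(target, x, evs = NULL) {
  target <- as_rational(target)
  if (inherits(x, "polyhedron")) {
    s <- cxx_residual_signs(x$ineq, x$rhs, matrix(target, ncol = 1))[, 1]
    bad <- (s < 0 & !x$eq_mask) | (x$eq_mask & s != 0)
    if (any(bad))
      stop("target is not a member of the polyhedron; violated: ",
           paste(x$labels[bad], collapse = ", "))
    if (is.null(evs)) evs <- elementary_vectors(x)
    hs <- .homog_spec(x)
    E <- rbind(
      if (nrow(evs$point_evs)) cbind(evs$point_evs, "1"),
      if (nrow(evs$ray_evs)) cbind(evs$ray_evs, "0")
    )
    npts <- nrow(evs$point_evs)
    A <- rbind(if (!is.null(hs$ineq)) hs$ineq,
               {
                 un <- matrix("0", 1, hs$n)
                 un[1, hs$n] <- "1"
                 un
               })
    res <- cxx_decompose(A, E, c(target, "1"))
    if (!res$ok) stop("conformal decomposition failed (incomplete EV set?)")
    coef <- res$coef
    pt <- which(rq_sign(coef) > 0 & seq_along(coef) <= npts)
    ry <- which(rq_sign(coef) > 0 & seq_along(coef) > npts)
    point_terms <- lapply(pt, function(i)
      list(ev = evs$point_evs[i, ], coef = coef[i]))
    ray_terms <- lapply(ry, function(i)
      list(ev = evs$ray_evs[i - npts, ], coef = coef[i]))
    csum <- rq_sum(coef[pt])
    out <- list(point_terms = point_terms, ray_terms = ray_terms,
                convex = rat_num(csum) == 1, coef_sum = csum,
                target = target)
  } else {
    spec <- .spec_of(x)
    memb <- .membership(spec, target)
    if (!memb$ok)
      stop("target is not a member of the cone; violated: ",
           paste(memb$violated, collapse = ", "))
    if (is.null(evs)) evs <- elementary_vectors(x)
    E <- evs
    if (inherits(x, "s_cone")) {
      amb <- attr(evs, "sign_ambiguous") %||% rep(FALSE, nrow(evs))
      if (any(amb)) {
        E <- rbind(E, matrix(rq_mul(evs[amb, , drop = FALSE], "-1"),
                             sum(amb)))
      }
    }
    A <- spec$ineq %||% matrix(character(0), 0, spec$n)
    res <- cxx_decompose(A, E, target)
    if (!res$ok) stop("conformal decomposition failed (incomplete EV set?)")
    coef <- res$coef
    idx <- which(rq_sign(coef) > 0)
    ray_terms <- lapply(idx, function(i) list(ev = E[i, ], coef = coef[i]))
    out <- list(point_terms = list(), ray_terms = ray_terms, convex = NA,
                coef_sum = rq_sum(coef[idx]), target = target)
  }
  recon <- .decomp_reconstruct(out)
  out$residual <- rq_sub(target, recon)
  stopifnot(all(rq_sign(out$residual) == 0))
  class(out) <- "conformal_decomposition"
  out
}

.decomp_reconstruct <- function(d) {
  n <- length(d$target)
  acc <- rep("0", n)
  for (tm in c(d$point_terms, d$ray_terms)) {
    acc <- rq_add(acc, rq_mul(tm$ev, tm$coef))
  }
  acc
}

#' @export
print.conformal_decomposition <- function(x, ...) {
  np <- length(x$point_terms)
  nr <- length(x$ray_terms)
  cat("Conformal decomposition:", np, "point term(s),", nr, "ray term(s)\n")
  if (np) {
    cat("  point coefficients (sum ", x$coef_sum, "):\n", sep = "")
    for (tm in x$point_terms)
      cat("   ", format(rat_num(tm$coef), digits = 4), "x [",
          paste(format(rat_num(tm$ev), digits = 3), collapse = ", "), "]\n")
  }
  if (nr) {
    cat("  ray terms:\n")
    for (tm in x$ray_terms)
      cat("   ", format(rat_num(tm$coef), digits = 4), "x [",
          paste(format(rat_num(tm$ev), digits = 3), collapse = ", "), "]\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
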