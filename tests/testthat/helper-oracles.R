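# Independent brute-force oracles for the polyhedral enumeration routines.
# They work in double precision on small integer inputs (exactly
# representable), via rank computations and exhaustive subset enumeration —
# deliberately sharing no code with the package's enumeration path.

.rank_tol <- 1e-8

num_rank <- function(M) {
  if (nrow(M) == 0 || ncol(M) == 0) return(0L)
  qr(M, tol = .rank_tol)$rank
}

num_nullvec <- function(M) {
  # a basis vector of a one-dimensional kernel
  n <- ncol(M)
  s <- svd(rbind(M, matrix(0, max(0, n - nrow(M)), n)))
  v <- s$v[, n]
  v[abs(v) < .rank_tol] <- 0
  v
}

# support-minimal vectors of {x in ker(E), x_I >= 0} by support-pattern
# enumeration: a support S carries an SM vector iff ker(E_S) is
# one-dimensional, its basis vector has full support S, and some orientation
# satisfies the sign constraints.
oracle_scone_evs <- function(E, nonneg) {
  n <- ncol(E)
  cand <- list()
  for (size in 1:n) {
    for (S in utils::combn(n, size, simplify = FALSE)) {
      ES <- E[, S, drop = FALSE]
      if ((size - num_rank(ES)) != 1) next
      v <- num_nullvec(ES)
      if (any(v == 0)) next
      full <- numeric(n)
      full[S] <- v
      ok_pos <- all(full[nonneg] >= 0)
      ok_neg <- all(-full[nonneg] >= 0)
      if (!ok_pos && !ok_neg) next
      if (!ok_pos) full <- -full
      cand[[length(cand) + 1L]] <- list(S = S, v = full)
    }
  }
  # support-minimality filter
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && all(cand[[j]]$S %in% cand[[i]]$S) &&
        length(cand[[j]]$S) < length(cand[[i]]$S)
    }, logical(1)))
  }, logical(1))
  lapply(cand[keep], `[[`, "v")
}

# elementary vectors of {x : Ax >= 0}: union over closed orthants of the
# extreme rays of the cone intersected with the orthant (a pointed cone in
# each orthant), found by exhaustive active-set enumeration.
oracle_cone_evs <- function(A) {
  n <- ncol(A)
  found <- list()
  orthants <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  for (o in seq_len(nrow(orthants))) {
    rows <- rbind(A, diag(orthants[o, ], n))
    m <- nrow(rows)
    if (m < n - 1) next
    for (S in utils::combn(m, n - 1, simplify = FALSE)) {
      sub <- rows[S, , drop = FALSE]
      if (num_rank(sub) != n - 1) next
      d <- num_nullvec(sub)
      for (dir in list(d, -d)) {
        if (all(rows %*% dir >= -.rank_tol)) {
          act <- rows[abs(rows %*% dir) < .rank_tol, , drop = FALSE]
          if (num_rank(act) == n - 1) {
            found[[length(found) + 1L]] <- dir / max(abs(dir))
          }
          break
        }
      }
    }
  }
  if (!length(found)) return(matrix(numeric(0), 0, n))
  M <- do.call(rbind, found)
  unique(round(M, 6))
}

# vertices of {x : Ax >= b} by exhaustive basis enumeration
oracle_polytope_vertices <- function(A, b) {
  n <- ncol(A)
  m <- nrow(A)
  verts <- list()
  for (S in utils::combn(m, n, simplify = FALSE)) {
    sub <- A[S, , drop = FALSE]
    if (num_rank(sub) < n) next
    x <- tryCatch(solve(sub, b[S]), error = function(e) NULL)
    if (is.null(x)) next
    if (all(A %*% x >= b - .rank_tol)) {
      verts[[length(verts) + 1L]] <- x
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  unique(round(do.call(rbind, verts), 6))
}

# canonical numeric form of a ray matrix for set comparison
ray_key <- function(M, digits = 6) {
  if (is.null(M) || nrow(M) == 0) return(character(0))
  M <- t(apply(M, 1, function(r) r / max(abs(r))))
  sort(apply(round(M, digits), 1, paste, collapse = ","))
}

rand_int_matrix <- function(nr, nc, lo = -3, hi = 3) {
  matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc)
}
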