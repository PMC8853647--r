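#' Capacity and membrane parameters
#'
#' Parameters of the linear constraints for the self-fabricating cell, with
#' canonical units hours, mol, gram, metre: turnover number \code{kcat}
#' (1/h, default 79/s), ribosome elongation rate \code{kel} (AA/h, default
#' 8 AA/s), lipid and importer cross-section areas (m^2, defaults 0.5 and 48
#' nm^2), cell density \code{rho} (g/m^3, default 290 g/L), minimum lipid
#' area fraction \code{alpha}, Avogadro constant, and the growth-rate
#' dependent surface-to-volume ratio \eqn{r(\mu) = (9.3 - 2.8\,\mu\,h)\,
#' \mu m^{-1}} stored via \code{s2v_intercept} and \code{s2v_slope} (1/m).
#' All values are exact rationals.
#'
#' @param kcat,kel,area_L,area_I,rho,alpha,avogadro,s2v_intercept,s2v_slope
#'   exact rational strings or numerics; see Details for units
#' @param ribosome,aa_species,membrane_lipid,importers species/roles used to
#'   assemble the constraint rows
#' @return a list of class \code{capacity_params}
#' @export
capacity_params <- function(kcat = "284400",
                            kel = "28800",
                            area_L = "1/2000000000000000000",
                            area_I = "48/1000000000000000000",
                            rho = "290000",
                            alpha = "1/2",
                            avogadro = "602214076000000000000000",
                            s2v_intercept = "9300000",
                            s2v_slope = "2800000",
                            ribosome = "R",
                            aa_species = "AA",
                            membrane_lipid = "L",
                            importers = c("IG", "IN")) {
  p <- list(kcat = as_rational(kcat), kel = as_rational(kel),
            area_L = as_rational(area_L), area_I = as_rational(area_I),
            rho = as_rational(rho), alpha = as_rational(alpha),
            avogadro = as_rational(avogadro),
            s2v_intercept = as_rational(s2v_intercept),
            s2v_slope = as_rational(s2v_slope),
            ribosome = ribosome, aa_species = aa_species,
            membrane_lipid = membrane_lipid, importers = importers)
  stopifnot(rat_num(p$kcat) > 0, rat_num(p$kel) > 0,
            rat_num(p$alpha) > 0, rat_num(p$alpha) < 1)
  class(p) <- "capacity_params"
  p
}

#' Linear constraint sets A x + B v >= b
#'
#' Rows couple concentrations \eqn{x} and fluxes \eqn{v}:
#' \eqn{A x + B v \; \{\ge,=\} \; b}, with a human-readable label per row.
#'
#' @param conc rows x species matrix \eqn{A}
#' @param flux rows x reactions matrix \eqn{B}
#' @param rhs right-hand side
#' @param relation character vector of \code{">="} / \code{"="} per row
#' @param labels unique row labels
#' @return object of class \code{constraint_set}
#' @export
constraint_set <- function(conc, flux, rhs, relation, labels) {
  conc <- as_rational(conc); flux <- as_rational(flux)
  if (!is.matrix(conc)) conc <- matrix(conc, nrow = 1)
  if (!is.matrix(flux)) flux <- matrix(flux, nrow = 1)
  rhs <- as_rational(rhs)
  m <- nrow(conc)
  stopifnot(nrow(flux) == m, length(rhs) == m, length(relation) == m,
            length(labels) == m, !anyDuplicated(labels),
            all(relation %in% c(">=", "=")))
  structure(list(conc = conc, flux = flux, rhs = rhs, relation = relation,
                 labels = labels),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Constraint set:", length(x$labels), "rows (",
      sum(x$relation == "="), "equalities )\n")
  cat("  ", paste(paste0(x$labels, " [", x$relation, "]"), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
rbind.constraint_set <- function(...) {
  parts <- list(...)
  constraint_set(do.call(rbind, lapply(parts, `[[`, "conc")),
                 do.call(rbind, lapply(parts, `[[`, "flux")),
                 unlist(lapply(parts, `[[`, "rhs")),
                 unlist(lapply(parts, `[[`, "relation")),
                 unlist(lapply(parts, `[[`, "labels")))
}

#' Capacity and membrane constraints at a given growth rate
#'
#' Assembles, for a growth model with explicit catalysts:
#' \itemize{
#'   \item one catalytic capacity row per single-reaction catalyst \eqn{c}:
#'     \eqn{k_{cat} x_c - v_r \ge 0} (label \code{"cap <c>"});
#'   \item one ribosome capacity row: \eqn{k_{el} x_R \ge \sum_r n_r w_r},
#'     where \eqn{n_r} is the amino-acid consumption of synthesis reaction
#'     \eqn{r} (label \code{"cap <ribosome>"});
#'   \item the membrane area equality
#'     \eqn{A_L N_A x_L + A_I N_A (x_{IG}+x_{IN}) = r(\mu)/\rho}
#'     (label \code{"memb area"}); both sides are scaled by the Avogadro
#'     constant, which keeps the rational entries small without changing the
#'     constraint;
#'   \item the minimum lipid fraction
#'     \eqn{(1-\alpha) A_L x_L \ge \alpha A_I (x_{IG}+x_{IN})}
#'     (label \code{"memb L"}).
#' }
#' Membrane rows are omitted when the model lacks the membrane species.
#'
#' @param model a validated [growth_model()]
#' @param params [capacity_params()]
#' @param mu growth rate (1/h); numeric values are converted to nearby exact
#'   rationals via [rationalize()]
#' @return a [constraint_set()]
#' @export
capacity_constraints <- function(model, params = capacity_params(), mu) {
  mu <- .mu_rat(mu)
  sp <- model$species; rx <- model$reactions
  nsp <- length(sp); nrx <- length(rx)
  conc <- NULL; flux <- NULL; rhs <- character(0)
  rel <- character(0); labs <- character(0)
  cats <- model$catalysts
  ribo <- params$ribosome
  # single-reaction catalysts: kcat * x_c - v_r >= 0
  for (r in names(cats)) {
    c_sp <- cats[[r]]
    if (identical(c_sp, ribo)) next
    a <- rep("0", nsp); b <- rep("0", nrx)
    a[match(c_sp, sp)] <- params$kcat
    b[match(r, rx)] <- "-1"
    conc <- rbind(conc, a); flux <- rbind(flux, b)
    rhs <- c(rhs, "0"); rel <- c(rel, ">=")
    labs <- c(labs, paste("cap", c_sp))
  }
  # ribosome: kel * x_R - sum_r n_r w_r >= 0, n_r = AA consumed by r
  ribo_rxns <- names(cats)[cats == ribo]
  if (length(ribo_rxns) && ribo %in% sp) {
    a <- rep("0", nsp); b <- rep("0", nrx)
    a[match(ribo, sp)] <- params$kel
    for (r in ribo_rxns) {
      b[match(r, rx)] <- model$stoich[params$aa_species, r]  # negative
    }
    conc <- rbind(conc, a); flux <- rbind(flux, b)
    rhs <- c(rhs, "0"); rel <- c(rel, ">=")
    labs <- c(labs, paste("cap", ribo))
  }
  # membrane constraints
  memb_sp <- c(params$membrane_lipid, params$importers)
  if (all(memb_sp %in% sp)) {
    rmu <- rq_sub(params$s2v_intercept, rq_mul(params$s2v_slope, mu))
    if (rat_num(rmu) <= 0)
      stop("surface-to-volume ratio r(mu) is nonpositive at mu = ",
           rat_num(mu), "; outside the parameterized range")
    aL <- rq_mul(params$area_L, params$avogadro)
    aI <- rq_mul(params$area_I, params$avogadro)
    a <- rep("0", nsp)
    a[match(params$membrane_lipid, sp)] <- aL
    a[match(params$importers, sp)] <- aI
    conc <- rbind(conc, a); flux <- rbind(flux, rep("0", nrx))
    rhs <- c(rhs, rq_div(rmu, params$rho)); rel <- c(rel, "=")
    labs <- c(labs, "memb area")
    a <- rep("0", nsp)
    a[match(params$membrane_lipid, sp)] <-
      rq_mul(rq_sub("1", params$alpha), aL)
    a[match(params$importers, sp)] <-
      rq_mul(rq_mul(params$alpha, aI), "-1")
    conc <- rbind(conc, a); flux <- rbind(flux, rep("0", nrx))
    rhs <- c(rhs, "0"); rel <- c(rel, ">=")
    labs <- c(labs, "memb L")
  }
  colnames(conc) <- sp; colnames(flux) <- rx
  rownames(conc) <- rownames(flux) <- NULL
  constraint_set(conc, flux, rhs, rel, labs)
}

.mu_rat <- function(mu) {
  if (is.character(mu)) as_rational(mu) else rationalize(mu)
}

#' Growth polyhedron at fixed growth rate
#'
#' Eliminating \eqn{x = Nv/\mu} from the constraint-based growth model gives
#' a polyhedron in flux space:
#' \deqn{P_g(\mu) = \{v : Nv \ge 0,\; v_I \ge 0,\; \omega^T N v = \mu,\;
#'   (A N + \mu B) v \;\{\ge,=\}\; \mu b\}.}
#' Rows are labeled \code{"mb <species>"}, \code{"irr <reaction>"},
#' \code{"mass"} and the labels of the supplied [constraint_set()].
#'
#' @param model a validated [growth_model()]
#' @param constraints a [constraint_set()] (already at growth rate
#'   \code{mu} if its rows depend on it)
#' @param mu growth rate (> 0)
#' @return a [polyhedron()] in flux space
#' @export
growth_polyhedron <- function(model, constraints, mu) {
  mu <- .mu_rat(mu)
  if (rat_num(mu) <= 0) stop("growth polyhedron requires mu > 0")
  N <- model$stoich; rx <- model$reactions
  irr <- match(model$irreversible, rx)
  un <- matrix("0", length(irr), ncol(N))
  un[cbind(seq_along(irr), irr)] <- "1"
  wN <- rq_matmul(matrix(model$molar_masses, nrow = 1), N)
  rows <- rbind(N, un, wN)
  rhs <- c(rep("0", nrow(N) + length(irr)), mu)
  labs <- c(paste("mb", model$species), paste("irr", rx[irr]), "mass")
  eqm <- c(rep(FALSE, nrow(N) + length(irr)), TRUE)
  if (!is.null(constraints)) {
    AN <- rq_matmul(constraints$conc, N)
    muB <- rq_mul(constraints$flux, mu)
    rows <- rbind(rows, rq_add(AN, muB))
    rhs <- c(rhs, rq_mul(constraints$rhs, mu))
    labs <- c(labs, constraints$labels)
    eqm <- c(eqm, constraints$relation == "=")
  }
  polyhedron(rows, rhs, row_labels = labs, eq_mask = eqm, varnames = rx)
}

# labels of the "essential" inequality rows of a growth polyhedron: rows that
# are neither equalities nor positive multiples of a single irreversible
# coordinate (those duplicate irreversibility bounds; e.g. the mass-balance
# row of a macromolecule produced by a single synthesis reaction).  Inactive
# signatures are reported over these rows.
.essential_rows <- function(poly) {
  ineq <- which(!poly$eq_mask)
  A <- poly$ineq[ineq, , drop = FALSE]
  b <- poly$rhs[ineq]
  num <- rat_num(A)
  keep <- logical(length(ineq))
  seen <- character(0)
  for (i in seq_len(nrow(A))) {
    nz <- which(num[i, ] != 0)
    if (length(nz) == 1 && num[i, nz] > 0 && rat_num(b[i]) == 0) next
    key <- paste(cxx_canon_rows(matrix(c(A[i, ], b[i]), 1)),
                 collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[i] <- TRUE
  }
  is_irr <- startsWith(poly$labels[ineq], "irr ")
  poly$labels[ineq][keep & !is_irr]
}

#' Enumerate elementary growth vectors
#'
#' Elementary growth vectors (EGVs) are the convex-conformally
#' non-decomposable elements of the growth polyhedron \eqn{P_g(\mu)}
#' together with the conformally non-decomposable elements of its recession
#' cone \eqn{\{v : Nv = 0, v_I \ge 0, Bv \ge 0\}}.  Unlike elementary flux
#' modes, EGVs are not determined by their supports but by their *inactive
#' constraint signatures*: the set of (essential) inequality rows satisfied
#' strictly.  An infeasible polyhedron is a first-class result, flagged via
#' \code{feasible = FALSE} — not an exception — since feasibility boundaries
#' in \eqn{\mu} are located by bisection on exactly this flag.
#'
#' @param model a validated [growth_model()]
#' @param mu growth rate (1/h, > 0)
#' @param constraints optional [constraint_set()]; by default built by
#'   [capacity_constraints()] at \code{mu}
#' @param params [capacity_params()] used when \code{constraints} is missing
#' @return object of class \code{egv_set}: point EGVs with fluxes,
#'   associated concentrations, mass fractions, inactive signatures, uptake
#'   fractions and storage, plus recession-cone EGVs
#' @export
egvs <- function(model, mu, constraints = NULL, params = capacity_params()) {
  mu <- .mu_rat(mu)
  cs <- constraints %||% capacity_constraints(model, params, mu)
  poly <- growth_polyhedron(model, cs, mu)
  evs <- tryCatch(elementary_vectors(poly),
                  egrowth_infeasible = function(e) NULL)
  out <- list(mu = mu, mu_num = rat_num(mu), feasible = !is.null(evs),
              polyhedron = poly, params = params, model = model,
              essential = .essential_rows(poly))
  class(out) <- "egv_set"
  if (is.null(evs)) return(out)
  P <- evs$point_evs
  n <- nrow(P)
  out$flux <- P
  out$rays <- evs$ray_evs
  # exact activity signatures over the essential rows
  ineq_idx <- match(out$essential, poly$labels)
  sig <- vector("list", n)
  if (n) {
    signs <- cxx_residual_signs(poly$ineq[ineq_idx, , drop = FALSE],
                                poly$rhs[ineq_idx], t(P))
    for (i in seq_len(n)) sig[[i]] <- out$essential[signs[, i] > 0]
  }
  out$signatures <- sig
  out$signature_key <- vapply(sig, paste, character(1), collapse = " | ")
  xs <- matrix(NA_real_, n, length(model$species),
               dimnames = list(NULL, model$species))
  for (i in seq_len(n)) xs[i, ] <- associated_concentrations(model, P[i, ])
  out$concentrations <- xs
  out$mass_fractions <- sweep(xs, 2, rat_num(model$molar_masses), `*`)
  out <- .egv_derived(out)
  out
}

# uptake fractions, carbon storage, ribosome mass fraction
.egv_derived <- function(out) {
  model <- out$model
  n <- if (is.null(out$flux)) 0L else nrow(out$flux)
  if (n == 0) return(out)
  exc <- model$exchange
  if (length(exc)) {
    g <- matrix(NA_real_, n, length(exc),
                dimnames = list(NULL, paste0("gamma_", sub("^r_", "",
                                                          exc))))
    for (j in seq_along(exc)) {
      col <- model$stoich[, exc[j], drop = FALSE]
      wcol <- rq_dot(model$molar_masses, col[, 1])
      for (i in seq_len(n)) {
        vr <- out$flux[i, match(exc[j], model$reactions)]
        g[i, j] <- rat_num(rq_div(rq_mul(wcol, vr), out$mu))
      }
    }
    out$gamma <- g
  }
  storage <- intersect(c("G", "LD", "L"), model$species)
  if (length(storage)) {
    out$s_C <- rowSums(out$mass_fractions[, storage, drop = FALSE])
  }
  if ("R" %in% model$species) {
    out$ribosome_mass_fraction <- out$mass_fractions[, "R"]
  }
  out
}

#' @export
print.egv_set <- function(x, ...) {
  cat("Elementary growth vectors at mu =", format(x$mu_num, digits = 6),
      "/h\n")
  if (!x$feasible) {
    cat("  growth polyhedron is INFEASIBLE at this growth rate\n")
    return(invisible(x))
  }
  n <- if (is.null(x$flux)) 0L else nrow(x$flux)
  cat(" ", n, "point EGV(s),", nrow(x$rays), "recession-cone EGV(s)\n")
  if (n) {
    df <- data.frame(signature = x$signature_key,
                     support = apply(rat_num(x$flux) != 0, 1, sum))
    if (!is.null(x$gamma)) df <- cbind(df, round(x$gamma, 4))
    if (!is.null(x$s_C)) df$s_C <- round(x$s_C, 4)
    if (!is.null(x$ribosome_mass_fraction))
      df$w_R.x_R <- round(x$ribosome_mass_fraction, 4)
    print(df)
  }
  invisible(x)
}

#' @export
as.data.frame.egv_set <- function(x, ...) {
  if (!x$feasible || is.null(x$flux) || nrow(x$flux) == 0)
    return(data.frame())
  flux <- rat_num(x$flux)
  colnames(flux) <- x$model$reactions
  df <- data.frame(mu = x$mu_num, egv = seq_len(nrow(flux)),
                   signature = x$signature_key,
                   support = apply(flux != 0, 1, sum),
                   flux, check.names = FALSE)
  xs <- x$concentrations
  colnames(xs) <- paste0("x_", x$model$species)
  mf <- x$mass_fractions
  colnames(mf) <- paste0("massfrac_", x$model$species)
  df <- cbind(df, xs, mf)
  if (!is.null(x$gamma)) df <- cbind(df, x$gamma)
  if (!is.null(x$s_C)) df$s_C <- x$s_C
  if (!is.null(x$ribosome_mass_fraction))
    df$ribosome_mass_fraction <- x$ribosome_mass_fraction
  df
}

#' Conformal decomposition of a growth vector into EGVs
#'
#' Writes a growth vector as a convex combination of sign-compatible point
#' EGVs plus nonnegative recession-cone terms, and verifies the exact
#' concentration mixing identity \eqn{x(v) = \sum \lambda_e x(e)}.
#'
#' @param model a validated [growth_model()]
#' @param mu growth rate
#' @param v a growth vector in \eqn{P_g(\mu)}
#' @param egv_set optional precomputed [egvs()] result at \code{mu}
#' @param ... passed to [egvs()] when \code{egv_set} is missing
#' @return a [conformal_decompose()] result, with the mixing identity
#'   checked
#' @export
decompose_growth_vector <- function(model, mu, v, egv_set = NULL, ...) {
  if (is.null(egv_set)) egv_set <- egvs(model, mu, ...)
  if (!egv_set$feasible) stop("growth polyhedron is infeasible at mu")
  dec <- conformal_decompose(as_rational(v), egv_set$polyhedron,
                             evs = list(point_evs = egv_set$flux,
                                        ray_evs = egv_set$rays))
  # concentration mixing identity x(v) = sum lambda_e x(e)
  xv <- associated_concentrations(model, v, exact = TRUE)
  mix <- rep("0", length(xv))
  for (tm in dec$point_terms) {
    xe <- associated_concentrations(model, tm$ev, exact = TRUE)
    mix <- rq_add(mix, rq_mul(xe, tm$coef))
  }
  stopifnot(all(rq_sign(rq_sub(xv, mix)) == 0))
  dec
}

# ---------------------------------------------------------------------------
# growth-rate sweep
# ---------------------------------------------------------------------------

#' Sweep EGVs across growth rates
#'
#' Enumerates EGVs on a growth-rate grid, tracks EGV *families* (identified
#' by their inactive-constraint signature) across \eqn{\mu}, and locates by
#' bisection (i) every growth rate at which the number of point EGVs
#' changes (\code{mu_crit}) and (ii) the feasibility boundary
#' (\code{mu_max}).  Monotone feasibility on the scanned range is checked,
#' not assumed.
#'
#' @param model a validated [growth_model()]
#' @param params [capacity_params()]
#' @param mu_min,mu_max_scan scanned growth-rate range (1/h)
#' @param step grid step (1/h)
#' @param tol bisection tolerance (1/h)
#' @param constraints_fn optional function \code{(model, mu) ->
#'   constraint_set}, overriding [capacity_constraints()]
#' @return object of class \code{mu_sweep}: per-\eqn{\mu} records, family
#'   table with validity intervals, \code{mu_crit}, \code{mu_max}, merge
#'   events and classifications (see [classify_egvs()])
#' @export
sweep_mu <- function(model, params = capacity_params(),
                     mu_min = 0.05, mu_max_scan = 1.5, step = 0.05,
                     tol = 1e-4, constraints_fn = NULL) {
  enum <- function(mu_chr) {
    cs <- if (is.null(constraints_fn)) {
      capacity_constraints(model, params, mu_chr)
    } else constraints_fn(model, mu_chr)
    egvs(model, mu_chr, constraints = cs, params = params)
  }
  mu_min <- .mu_rat(mu_min); step <- .mu_rat(step)
  grid <- list()
  mu <- mu_min
  while (rat_num(mu) <= rat_num(.mu_rat(mu_max_scan)) + 1e-12) {
    grid[[length(grid) + 1L]] <- mu
    mu <- rq_add(mu, step)
  }
  sets <- lapply(grid, enum)
  feas <- vapply(sets, `[[`, logical(1), "feasible")
  if (!any(feas)) stop("no feasible growth rate in the scanned range")
  # monotone feasibility check
  if (any(diff(feas) > 0) && which.max(feas) != 1L)
    warning("feasibility is not monotone on the scanned grid")
  counts <- vapply(sets, function(s)
    if (s$feasible) nrow(s$flux) else NA_integer_, integer(1))
  # family bookkeeping
  fam <- new.env(parent = emptyenv())
  note <- function(s) {
    if (!s$feasible) return()
    for (i in seq_along(s$signature_key)) {
      k <- s$signature_key[i]
      rec <- fam[[k]] %||% list(mu = numeric(0), gamma = NULL,
                                s_C = numeric(0), ribo = numeric(0),
                                signature = s$signatures[[i]])
      rec$mu <- c(rec$mu, s$mu_num)
      if (!is.null(s$gamma)) rec$gamma <- rbind(rec$gamma, s$gamma[i, ])
      if (!is.null(s$s_C)) rec$s_C <- c(rec$s_C, s$s_C[i])
      if (!is.null(s$ribosome_mass_fraction))
        rec$ribo <- c(rec$ribo, s$ribosome_mass_fraction[i])
      fam[[k]] <- rec
    }
  }
  for (s in sets) note(s)
  # bisection on EGV-count changes between feasible neighbours
  bisect <- function(lo, hi, f_lo, f_hi, what) {
    while (rat_num(rq_sub(hi, lo)) > tol) {
      mid <- rq_div(rq_add(lo, hi), "2")
      s <- enum(mid)
      note(s)
      key <- if (what == "count") {
        if (s$feasible) nrow(s$flux) else NA_integer_
      } else s$feasible
      if (identical(key, f_lo)) lo <- mid else hi <- mid
    }
    rat_num(rq_div(rq_add(lo, hi), "2"))
  }
  mu_crit <- numeric(0)
  count_change <- list()
  for (i in seq_len(length(sets) - 1)) {
    if (feas[i] && feas[i + 1] && counts[i] != counts[i + 1]) {
      mc <- bisect(grid[[i]], grid[[i + 1]], counts[i], counts[i + 1],
                   "count")
      mu_crit <- c(mu_crit, mc)
      count_change[[length(count_change) + 1L]] <-
        list(mu = mc, from = counts[i], to = counts[i + 1])
    }
  }
  mu_max <- NA_real_
  li <- max(which(feas))
  if (li < length(sets)) {
    mu_max <- bisect(grid[[li]], grid[[li + 1]], TRUE, FALSE, "feas")
  }
  # family table
  keys <- ls(fam)
  families <- data.frame(
    signature = keys,
    mu_lo = vapply(keys, function(k) min(fam[[k]]$mu), numeric(1)),
    mu_hi = vapply(keys, function(k) max(fam[[k]]$mu), numeric(1)),
    n_mu = vapply(keys, function(k) length(fam[[k]]$mu), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # merge events: families restricted to the low regime merge, at mu_crit,
  # into high-regime families that share an inactive row
  merges <- list()
  if (length(mu_crit)) {
    mc <- max(mu_crit)
    low_only <- families$signature[families$mu_hi < mc + tol * 2 &
                                     families$mu_lo < mc]
    high_only <- families$signature[families$mu_lo > mc - tol * 2]
    for (h in high_only) {
      hset <- fam[[h]]$signature
      partners <- low_only[vapply(low_only, function(l)
        length(intersect(fam[[l]]$signature, hset)) > 0, logical(1))]
      if (length(partners))
        merges[[length(merges) + 1L]] <- list(into = h, from = partners)
    }
  }
  out <- structure(list(grid = vapply(grid, rat_num, numeric(1)),
                        sets = sets, feasible = feas, counts = counts,
                        families = families, family_data = fam,
                        mu_crit = mu_crit, count_changes = count_change,
                        mu_max = mu_max, merges = merges,
                        model = model, params = params, tol = tol),
                   class = "mu_sweep")
  out$classes <- classify_egvs(out)
  out
}

#' @export
print.mu_sweep <- function(x, ...) {
  rng <- range(x$grid)
  cat("Growth-rate sweep on [", rng[1], ",", rng[2], "] /h\n")
  cat("  point-EGV counts over feasible grid:",
      paste(unique(stats::na.omit(x$counts)), collapse = " -> "), "\n")
  if (length(x$mu_crit))
    cat("  mu_crit (EGV count changes):",
        paste(round(x$mu_crit, 4), collapse = ", "), "/h\n")
  if (!is.na(x$mu_max))
    cat("  mu_max (feasibility boundary):", round(x$mu_max, 4), "/h\n")
  cat("  families (distinct inactive signatures):", nrow(x$families), "\n")
  invisible(x)
}

#' Classify EGV families by uptake/storage and ribosome content
#'
#' Uptake classes compare each family's ammonium uptake fraction
#' \eqn{\gamma_{IN}} at the low end of its validity interval with the
#' balanced value \eqn{\omega_N/(\omega_G + \omega_N)} (equal molar uptake):
#' class 1 = below (carbon storage), class 2 = above (nitrogen
#' accumulation), class 3 = balanced within \code{tol_balanced}.  Suffix
#' \code{a} marks families valid across the whole feasible range, \code{b}
#' families confined to one regime.  Ribosome classes are assigned in the
#' order: III = mass fraction \eqn{\omega_R x_R} constant across the
#' family's validity interval (total variation within \code{tol_const});
#' II = affine in \eqn{\mu} through the origin (maximum deviation from the
#' best through-origin line within \code{tol_linear}); I = the rest
#' (nonlinear, typically metabolite-storage families).  The descriptions are
#' qualitative in origin; the default tolerances sit inside the wide
#' numerical gap that separates the three behaviours in the self-fabricating
#' cell (linear deviations are either below 0.011 or above 0.40; total
#' variations either below 0.048 or above 0.87).
#'
#' @param sweep a [sweep_mu()] result
#' @param tol_balanced,tol_linear,tol_const classification tolerances
#' @return data frame with one row per family: uptake class, ribosome class,
#'   validity interval
#' @export
classify_egvs <- function(sweep, tol_balanced = 0.02, tol_linear = 0.02,
                          tol_const = 0.05) {
  model <- sweep$model
  fam <- sweep$family_data
  keys <- sweep$families$signature
  if (length(keys) == 0) return(data.frame())
  exc <- model$exchange
  wexc <- vapply(exc, function(r)
    rat_num(rq_dot(model$molar_masses, model$stoich[, r])), numeric(1))
  # balanced value for the nitrogen-like (lighter) exchange contribution
  j_n <- which.min(wexc)
  balanced <- wexc[j_n] / sum(wexc)
  lo_all <- min(sweep$families$mu_lo)
  hi_all <- max(sweep$families$mu_hi)
  span_tol <- max(diff(sweep$grid)) + sweep$tol
  res <- lapply(keys, function(k) {
    rec <- fam[[k]]
    ord <- order(rec$mu)
    mu <- rec$mu[ord]
    g_in <- rec$gamma[ord, j_n]
    g_low <- g_in[1]
    uptake_num <- if (abs(g_low - balanced) <= tol_balanced) 3L
                  else if (g_low < balanced) 1L else 2L
    persistent <- (min(mu) <= lo_all + span_tol) &&
      (max(mu) >= hi_all - span_tol)
    uptake <- paste0(uptake_num, if (persistent) "a" else "b")
    ribo <- rec$ribo[ord]
    slope <- sum(ribo * mu) / sum(mu * mu)
    lin_dev <- max(abs(ribo - slope * mu))
    const_dev <- diff(range(ribo))
    rclass <- if (const_dev <= tol_const) "III"
              else if (lin_dev <= tol_linear) "II" else "I"
    data.frame(signature = k, uptake_class = uptake,
               ribosome_class = rclass, persistent = persistent,
               mu_lo = min(mu), mu_hi = max(mu),
               gamma_IN_low = g_low,
               ribo_mean = mean(ribo), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
plot.mu_sweep <- function(x, what = c("gamma", "ribosome", "storage"), ...) {
  what <- match.arg(what)
  fam <- x$family_data
  keys <- x$families$signature
  ylab <- switch(what, gamma = expression(gamma[IN]),
                 ribosome = expression(omega[R] * x[R]),
                 storage = expression(s[C]))
  plot(NA, xlim = range(x$grid), ylim = c(0, 1), xlab = expression(mu),
       ylab = ylab, ...)
  j_n <- NULL
  for (i in seq_along(keys)) {
    rec <- fam[[keys[i]]]
    ord <- order(rec$mu)
    y <- switch(what,
                gamma = {
                  exc <- x$model$exchange
                  wexc <- vapply(exc, function(r)
                    rat_num(rq_dot(x$model$molar_masses,
                                   x$model$stoich[, r])), numeric(1))
                  rec$gamma[ord, which.min(wexc)]
                },
                ribosome = rec$ribo[ord],
                storage = rec$s_C[ord])
    graphics::lines(rec$mu[ord], y, col = i)
  }
  invisible(x)
}

#' Write EGV records / sweep results to CSV
#'
#' @param x an \code{egv_set} or \code{mu_sweep}
#' @param file output path
#' @export
write_egv_csv <- function(x, file) {
  df <- if (inherits(x, "mu_sweep")) {
    do.call(rbind, lapply(x$sets[x$feasible], as.data.frame))
  } else as.data.frame(x)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
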