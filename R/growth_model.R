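#' Growth models of self-fabricating cells
#'
#' A growth model describes a cell that synthesizes all of its own
#' macromolecules: a set of molecular species \code{Mol} with molar masses
#' \eqn{\omega > 0} (g/mol), a set of reactions \code{Rxn} with exact
#' stoichiometric matrix \eqn{N} (species x reactions), a subset of
#' irreversible reactions, a subset of exchange reactions (which move mass
#' across the cell boundary), and a partial map from catalytic reactions to
#' their catalyst species.  Concentrations \eqn{x} are in mol per gram dry
#' weight, so the dry-mass constraint reads \eqn{\omega^T x = 1}, fluxes are
#' in mol/g/h, and balanced exponential growth at rate \eqn{\mu} obeys
#' \eqn{N v = \mu x}.
#'
#' Two structural facts are enforced: internal reactions conserve mass
#' (\eqn{\omega^T N_{int} = 0}) and the network admits no semipositive
#' conservation law (\eqn{\ker N^T \cap R_{\ge0}^{Mol} = \{0\}}) — a
#' conserved nonnegative mass pool cannot grow exponentially.
#'
#' @param species character vector of species identifiers (ordered)
#' @param molar_masses named vector (numeric or rational character) of molar
#'   masses in g/mol; entries may be \code{NA} and later completed with
#'   [derive_masses()]
#' @param stoich species x reactions matrix (numeric or rational character)
#' @param irreversible character vector of irreversible reaction ids
#' @param exchange character vector of exchange reaction ids; if \code{NULL}
#'   and all masses are known, detected as the columns with
#'   \eqn{\omega^T N_{col} \ne 0}
#' @param catalysts named character vector mapping reaction id -> catalyst
#'   species id (partial)
#' @return an object of class \code{growth_model}
#' @seealso [validate_model()], [self_fabricating_cell()], [egms()]
#' @export
growth_model <- function(species, molar_masses, stoich, irreversible,
                         exchange = NULL, catalysts = character(0)) {
  stopifnot(is.character(species), !anyDuplicated(species))
  N <- as_rational(stoich)
  if (!is.matrix(N)) N <- matrix(N, nrow = length(species))
  if (nrow(N) != length(species)) stop("stoich must have one row per species")
  rxn <- colnames(N)
  if (is.null(rxn)) stop("stoich must have reaction ids as column names")
  rownames(N) <- species
  masses <- rep(NA_character_, length(species))
  names(masses) <- species
  known <- !is.na(molar_masses)
  if (any(known)) {
    mm <- molar_masses[known]
    if (is.null(names(mm)) || !all(names(mm) %in% species))
      stop("molar_masses must be named by species")
    masses[names(mm)] <- as_rational(mm)
  }
  if (!all(irreversible %in% rxn)) stop("unknown irreversible reaction id")
  if (length(catalysts)) {
    if (is.null(names(catalysts)) || !all(names(catalysts) %in% rxn))
      stop("catalysts must be named by reaction id")
  }
  m <- structure(list(species = species, molar_masses = masses,
                      reactions = rxn, stoich = N,
                      irreversible = irreversible,
                      exchange = exchange, catalysts = catalysts),
                 class = "growth_model")
  if (is.null(exchange) && !anyNA(masses)) {
    m$exchange <- .detect_exchange(m)
  }
  m
}

.detect_exchange <- function(model) {
  wN <- rq_matmul(matrix(model$molar_masses, nrow = 1), model$stoich)
  model$reactions[rat_num(wN) != 0]
}

.internal_rxns <- function(model) setdiff(model$reactions, model$exchange)

#' @export
print.growth_model <- function(x, ...) {
  cat("Growth model:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  irreversible:", length(x$irreversible),
      " exchange:", length(x$exchange),
      " catalytic:", length(x$catalysts), "\n")
  if (anyNA(x$molar_masses))
    cat("  molar masses incomplete (", sum(is.na(x$molar_masses)),
        "unknown ) - see derive_masses()\n")
  invisible(x)
}

#' @export
summary.growth_model <- function(object, ...) {
  print(object)
  cat("Species:", paste(object$species, collapse = ", "), "\n")
  cat("Reactions:", paste(object$reactions, collapse = ", "), "\n")
  v <- validate_model(object)
  cat(if (v$ok) "Model validates.\n" else "Model has validation failures.\n")
  invisible(object)
}

# ---------------------------------------------------------------------------
# validation
# ---------------------------------------------------------------------------

#' Validate the structural assumptions of a growth model
#'
#' Checks, exactly: (a) internal reactions conserve mass,
#' \eqn{\omega^T N_{int} = 0} column by column; (b) no semipositive
#' conservation law exists, i.e. the linear program
#' \eqn{\{y \ge 0, N^T y = 0, \sum y = 1\}} is infeasible; (c) every mapped
#' catalyst is a model species; (d) all molar masses are known and positive.
#'
#' @param model a [growth_model()]
#' @return object of class \code{model_validation}: list with \code{ok} and a
#'   character vector \code{failures} describing each violated assumption
#' @export
validate_model <- function(model) {
  fails <- character(0)
  if (anyNA(model$molar_masses)) {
    fails <- c(fails, paste("unknown molar mass for:",
                            paste(model$species[is.na(model$molar_masses)],
                                  collapse = ", ")))
  } else {
    if (any(rq_sign(model$molar_masses) <= 0))
      fails <- c(fails, "molar masses must be strictly positive")
    int <- .internal_rxns(model)
    if (length(int)) {
      wN <- rq_matmul(matrix(model$molar_masses, nrow = 1),
                      model$stoich[, int, drop = FALSE])
      bad <- int[rat_num(wN) != 0]
      if (length(bad))
        fails <- c(fails, paste("internal reaction(s) violate mass",
                                "conservation (w^T N != 0):",
                                paste(bad, collapse = ", ")))
    }
    # semipositive conservation law: y >= 0, N^T y = 0, sum(y) = 1 feasible?
    Nt <- t(model$stoich)
    M <- rbind(Nt, rep("1", nrow(model$stoich)))
    f <- c(rep("0", ncol(model$stoich)), "1")
    res <- cxx_simplex(M, f, rep("0", nrow(model$stoich)))
    if (res$status == 0) {
      y <- stats::setNames(rat_num(res$z), model$species)
      fails <- c(fails, paste("semipositive conservation law exists,",
                              "e.g. supported on:",
                              paste(names(y)[y > 0], collapse = ", ")))
    }
  }
  if (length(model$catalysts)) {
    bad <- model$catalysts[!(model$catalysts %in% model$species)]
    if (length(bad))
      fails <- c(fails, paste("catalyst is not a model species:",
                              paste(unique(bad), collapse = ", ")))
  }
  structure(list(ok = length(fails) == 0, failures = fails),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  if (x$ok) cat("Model validation: all checks passed\n")
  else {
    cat("Model validation FAILED:\n")
    for (f in x$failures) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Complete molar masses from mass conservation
#'
#' Unknown molar masses are solved from \eqn{\omega^T N_{int} = 0}: every
#' internal reaction gives one linear equation relating the masses of its
#' participants.  Errors if the system leaves a mass undetermined, is
#' inconsistent, or yields a nonpositive mass.
#'
#' @param model a [growth_model()] with \code{NA} masses
#' @return the model with all masses filled in (exact rationals)
#' @export
derive_masses <- function(model) {
  unknown <- which(is.na(model$molar_masses))
  if (length(unknown) == 0) return(model)
  int <- .internal_rxns(model)
  if (is.null(int) || length(int) == 0)
    stop("no internal reactions available to derive masses from")
  Ni <- model$stoich[, int, drop = FALSE]
  # columns: equations  sum_s w_s N_s,r = 0  ->  A w_unknown = -B w_known
  A <- t(Ni[unknown, , drop = FALSE])
  known <- setdiff(seq_along(model$species), unknown)
  b <- if (length(known)) {
    rq_mul(rq_matmul(matrix(model$molar_masses[known], nrow = 1),
                     Ni[known, , drop = FALSE]), "-1")
  } else rep("0", length(int))
  sol <- cxx_solve(A, b)
  if (sol$status == 2) stop("mass-conservation system is inconsistent")
  if (sol$status == 1) stop("masses are underdetermined by the internal ",
                            "reaction network")
  w <- sol$x
  if (any(rq_sign(w) <= 0))
    stop("derived molar mass is not positive for: ",
         paste(model$species[unknown][rq_sign(w) <= 0], collapse = ", "))
  model$molar_masses[unknown] <- w
  if (is.null(model$exchange)) model$exchange <- .detect_exchange(model)
  model
}

# ---------------------------------------------------------------------------
# growth rate and associated concentrations
# ---------------------------------------------------------------------------

#' Growth rate and associated concentrations of a flux vector
#'
#' The growth rate associated with a flux \eqn{v} is
#' \eqn{\mu(v) = \omega^T N v}; because internal reactions conserve mass this
#' equals \eqn{\omega^T N_{exc} v_{exc}} — growth is paid for entirely by
#' exchange with the environment, and the identity is asserted internally.
#' For \eqn{\mu(v) > 0}, the associated concentration vector is
#' \eqn{x(v) = Nv/\mu(v)}; it is invariant under positive scaling of
#' \eqn{v} and its mass fractions \eqn{\omega \circ x} sum to one.
#'
#' @param model a validated [growth_model()]
#' @param v flux vector (numeric, or rational character for exactness)
#' @param exact return exact rationals (character) instead of numeric
#' @return \code{growth_rate()}: the scalar \eqn{\mu(v)};
#'   \code{associated_concentrations()}: named concentration vector
#'   \eqn{x(v)} (mol/g)
#' @export
growth_rate <- function(model, v, exact = FALSE) {
  v <- as_rational(v)
  Nv <- rq_matmul(model$stoich, v)
  mu <- rq_dot(model$molar_masses, Nv)
  exc <- model$exchange
  if (length(exc)) {
    idx <- match(exc, model$reactions)
    Nve <- rq_matmul(model$stoich[, idx, drop = FALSE], v[idx])
    mu2 <- rq_dot(model$molar_masses, Nve)
    stopifnot(identical(mu, mu2))  # Eq. mu = w^T N_exc v_exc
  }
  if (exact) mu else rat_num(mu)
}

#' @rdname growth_rate
#' @export
associated_concentrations <- function(model, v, exact = FALSE) {
  v <- as_rational(v)
  Nv <- rq_matmul(model$stoich, v)
  mu <- rq_dot(model$molar_masses, Nv)
  if (rat_num(mu) <= 0)
    stop("flux has zero growth rate (a flux mode); ",
         "no associated concentrations exist")
  x <- stats::setNames(rq_div(Nv, mu), model$species)
  if (exact) x else rat_num(x)
}

#' @rdname growth_rate
#' @export
mass_fractions <- function(model, v, exact = FALSE) {
  x <- associated_concentrations(model, v, exact = TRUE)
  mf <- stats::setNames(rq_mul(model$molar_masses, x), model$species)
  if (exact) mf else rat_num(mf)
}

# ---------------------------------------------------------------------------
# fixture: the small self-fabricating cell
# ---------------------------------------------------------------------------

#' Built-in growth models
#'
#' \code{self_fabricating_cell()} builds the small self-fabricating cell:
#' glucose (G) and ammonium (N) import by dedicated importers (IG, IN),
#' amino-acid synthesis (G + N -> AA by enzyme EAA), lipid-droplet formation
#' (n_L G -> LD by ELD), lipid transfer to the membrane (LD -> L by EL), and
#' ribosomal synthesis of the five proteins and of the ribosome R itself
#' (n_i AA -> product).  11 species, 11 reactions, all irreversible, all
#' catalytic.  Default coefficients: n_L = 7, n_I = 646, n_E = 325,
#' n_R = 22608, molar masses 180 g/mol (glucose) and 18 g/mol (ammonium);
#' remaining masses follow from mass balance (e.g. amino acids 198 g/mol,
#' ribosome 22608 x 198 g/mol).
#'
#' \code{minimal_growth_model()} builds a 4-species toy with two alternative
#' amino-acid pathways: enzymes E1 and E2 each catalyze an (exchange) supply
#' reaction of AA, and the ribosome R synthesizes E1, E2 and itself from AA.
#' Substrates are implicit in the supply reactions; stoichiometric
#' coefficients are 1 and masses follow from mass balance with
#' \eqn{\omega_{AA} = 1}.
#'
#' @param n_L,n_I,n_E,n_R stoichiometric coefficients (glucose per lipid,
#'   amino acids per importer / enzyme / ribosome)
#' @param omega_G,omega_N molar masses of glucose and ammonium (g/mol)
#' @return a validated [growth_model()]
#' @export
self_fabricating_cell <- function(n_L = 7, n_I = 646, n_E = 325,
                                  n_R = 22608, omega_G = 180, omega_N = 18) {
  sp <- c("G", "N", "AA", "LD", "L", "IG", "IN", "EAA", "ELD", "EL", "R")
  rx <- c("r_IG", "r_IN", "r_EAA", "r_ELD", "r_EL",
          "s_IG", "s_IN", "s_EAA", "s_ELD", "s_EL", "s_R")
  N <- matrix("0", length(sp), length(rx), dimnames = list(sp, rx))
  nL <- as_rational(n_L); nI <- as_rational(n_I)
  nE <- as_rational(n_E); nR <- as_rational(n_R)
  N["G", "r_IG"] <- "1"
  N["N", "r_IN"] <- "1"
  N["G", "r_EAA"] <- "-1"; N["N", "r_EAA"] <- "-1"; N["AA", "r_EAA"] <- "1"
  N["G", "r_ELD"] <- rq_mul(nL, "-1"); N["LD", "r_ELD"] <- "1"
  N["LD", "r_EL"] <- "-1"; N["L", "r_EL"] <- "1"
  for (p in c("IG", "IN")) {
    N["AA", paste0("s_", p)] <- rq_mul(nI, "-1")
    N[p, paste0("s_", p)] <- "1"
  }
  for (p in c("EAA", "ELD", "EL")) {
    N["AA", paste0("s_", p)] <- rq_mul(nE, "-1")
    N[p, paste0("s_", p)] <- "1"
  }
  N["AA", "s_R"] <- rq_mul(nR, "-1"); N["R", "s_R"] <- "1"
  catal <- c(r_IG = "IG", r_IN = "IN", r_EAA = "EAA", r_ELD = "ELD",
             r_EL = "EL", s_IG = "R", s_IN = "R", s_EAA = "R",
             s_ELD = "R", s_R = "R", s_EL = "R")
  m <- growth_model(
    species = sp,
    molar_masses = c(G = as_rational(omega_G), N = as_rational(omega_N)),
    stoich = N, irreversible = rx,
    exchange = c("r_IG", "r_IN"),
    catalysts = catal[rx]
  )
  m <- derive_masses(m)
  m$coefficients <- list(n_L = as_rational(n_L), n_I = as_rational(n_I),
                         n_E = as_rational(n_E), n_R = as_rational(n_R))
  m
}

#' @rdname self_fabricating_cell
#' @export
minimal_growth_model <- function() {
  sp <- c("AA", "E1", "E2", "R")
  rx <- c("v1", "v2", "w1", "w2", "wR")
  N <- matrix("0", length(sp), length(rx), dimnames = list(sp, rx))
  N["AA", "v1"] <- "1"; N["AA", "v2"] <- "1"
  N["AA", c("w1", "w2", "wR")] <- "-1"
  N["E1", "w1"] <- "1"; N["E2", "w2"] <- "1"; N["R", "wR"] <- "1"
  growth_model(
    species = sp,
    molar_masses = c(AA = "1"),
    stoich = N, irreversible = rx,
    exchange = c("v1", "v2"),
    catalysts = c(v1 = "E1", v2 = "E2", w1 = "R", w2 = "R", wR = "R")
  ) |> derive_masses()
}

# ---------------------------------------------------------------------------
# traditional (biomass-reaction) comparison model
# ---------------------------------------------------------------------------

#' Build the traditional biomass-reaction counterpart of a comprehensive model
#'
#' Takes the metabolic part of the self-fabricating cell (metabolite rows,
#' enzymatic reactions) and appends a fixed biomass column that consumes the
#' precursor metabolites in proportion to a reference biomass composition
#' \eqn{x}.  Macromolecule concentrations are folded into their total
#' amino-acid content
#' \eqn{x_{AA}^{tot} = n_I(x_{IG}+x_{IN}) + n_E(x_{EAA}+x_{ELD}+x_{EL}) +
#' n_R x_R + x_{AA}}.  The column is scaled by the total precursor
#' concentration \eqn{\bar{x}} (the molar sum of the consumed precursors) so
#' its entries are dimensionless; one unit of biomass flux then consumes
#' \eqn{1/\bar{x}} grams of precursors per gram dry weight (the reference
#' state has \eqn{\omega^T x = 1}).
#'
#' @param model the comprehensive [self_fabricating_cell()] model
#' @param biomass_state list with exact rationals \code{mu} (> 0) and named
#'   concentration vector \code{x}, e.g. the composition of a maximum-growth
#'   elementary growth vector
#' @return list of class \code{traditional_model}: \code{stoich} (metabolite
#'   rows x \code{c(enzymatic reactions, "biomass")}), \code{x_aa_tot},
#'   \code{xbar}, \code{biomass_col_unscaled}, and the metabolite masses
#' @export
traditional_model <- function(model, biomass_state) {
  mu <- as_rational(biomass_state$mu)
  if (rat_num(mu) <= 0) stop("biomass state must have positive growth rate")
  x <- as_rational(biomass_state$x)
  mets <- c("G", "N", "AA", "LD", "L")
  rxns <- c("r_IG", "r_IN", "r_EAA", "r_ELD", "r_EL")
  stopifnot(all(mets %in% model$species), all(rxns %in% model$reactions))
  co <- model$coefficients
  x_aa_tot <- rq_add(
    rq_add(rq_mul(co$n_I, rq_add(x["IG"], x["IN"])),
           rq_mul(co$n_E, rq_sum(x[c("EAA", "ELD", "EL")]))),
    rq_add(rq_mul(co$n_R, x["R"]), x["AA"]))
  prec <- c(G = unname(x["G"]), N = unname(x["N"]), AA = unname(x_aa_tot),
            LD = unname(x["LD"]), L = unname(x["L"]))
  xbar <- rq_sum(prec)
  if (rat_num(xbar) <= 0) stop("reference state has no precursor content")
  Nm <- model$stoich[mets, rxns, drop = FALSE]
  bio_unscaled <- rq_mul(prec, "-1")
  bio <- rq_div(bio_unscaled, xbar)
  Nt <- cbind(Nm, biomass = bio)
  structure(list(stoich = Nt, metabolites = mets,
                 molar_masses = model$molar_masses[mets],
                 x_aa_tot = x_aa_tot, xbar = xbar,
                 biomass_col_unscaled = bio_unscaled,
                 reference = list(mu = mu, x = x)),
            class = "traditional_model")
}

#' Elementary flux modes and vectors of the traditional model
#'
#' The traditional flux cone is \eqn{\{v : N v = 0, v \ge 0\}} over the
#' metabolite rows; its elementary vectors are the classical EFMs.  With
#' enzyme capacity bounds \eqn{v_r \le k_{cat} x_r} frozen at the reference
#' enzyme concentrations, the flux polyhedron's elementary vectors are the
#' EFVs.  The zero flux vector (always feasible, and a ccND point of the
#' polyhedron) is not counted as a flux phenotype.
#'
#' @param tmodel a [traditional_model()]
#' @param model the comprehensive model (for enzyme concentrations/kcat)
#' @param params [capacity_params()]
#' @return list with \code{n_efm}, \code{n_efv}, \code{efms}, \code{efvs}
#' @export
traditional_analysis <- function(tmodel, model, params = capacity_params()) {
  Nt <- tmodel$stoich
  sc <- s_cone(Nt, nonneg_indices = seq_len(ncol(Nt)),
               varnames = colnames(Nt))
  efms <- elementary_vectors(sc)
  # capacity bounds at the reference composition: v_r <= kcat * x_E(r)
  xref <- tmodel$reference$x
  enz <- c(r_IG = "IG", r_IN = "IN", r_EAA = "EAA", r_ELD = "ELD",
           r_EL = "EL")
  nr <- ncol(Nt)
  rows <- NULL; rhs <- character(0); labs <- character(0); eqm <- logical(0)
  # steady state (equalities) and nonnegativity
  rows <- Nt
  rhs <- rep("0", nrow(Nt)); labs <- paste("ss", rownames(Nt))
  eqm <- rep(TRUE, nrow(Nt))
  un <- matrix("0", nr, nr); diag(un) <- "1"
  rows <- rbind(rows, un)
  rhs <- c(rhs, rep("0", nr)); labs <- c(labs, paste("irr", colnames(Nt)))
  eqm <- c(eqm, rep(FALSE, nr))
  for (r in names(enz)) {
    row <- rep("0", nr)
    row[match(r, colnames(Nt))] <- "-1"
    rows <- rbind(rows, row)
    rhs <- c(rhs, rq_mul(rq_mul(params$kcat, xref[enz[[r]]]), "-1"))
    labs <- c(labs, paste("cap", enz[[r]]))
    eqm <- c(eqm, FALSE)
  }
  poly <- polyhedron(rows, rhs, row_labels = labs, eq_mask = eqm,
                     varnames = colnames(Nt))
  evs <- elementary_vectors(poly)
  nonzero <- apply(rat_num(evs$point_evs) != 0, 1, any)
  list(n_efm = nrow(efms),
       n_efv = sum(nonzero) + nrow(evs$ray_evs),
       efms = efms,
       efvs = list(point_evs = evs$point_evs[nonzero, , drop = FALSE],
                   ray_evs = evs$ray_evs))
}
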