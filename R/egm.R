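#' Growth cone and elementary growth modes
#'
#' At balanced growth, \eqn{Nv = \mu x \ge 0}: a growth mode (GM) is any flux
#' vector with \eqn{Nv \ge 0} and \eqn{v_I \ge 0}.  The growth cone
#' \deqn{C_g = \{v : Nv \ge 0, v_I \ge 0\}}
#' is a general polyhedral cone (unlike the flux cone \eqn{\{Nv = 0\}} of
#' traditional models, which lies in a subspace).  Its elementary vectors —
#' the elementary growth modes (EGMs) — are the conformally non-decomposable
#' GMs; every nonzero GM is a conformal sum of EGMs.  GMs with
#' \eqn{\mu(v) = 0} are exactly the flux modes (\eqn{Nv = 0}).
#'
#' @param model a validated [growth_model()]
#' @return \code{growth_cone()}: a [poly_cone()] whose rows are labeled
#'   \code{"mb <species>"} (mass balance, \eqn{Nv \ge 0}) and
#'   \code{"irr <reaction>"} (irreversibility)
#' @seealso [egms()], [decompose_growth_mode()]
#' @export
growth_cone <- function(model) {
  N <- model$stoich
  irr <- match(model$irreversible, model$reactions)
  un <- matrix("0", length(irr), ncol(N))
  un[cbind(seq_along(irr), irr)] <- "1"
  A <- rbind(N, un)
  rownames(A) <- c(paste("mb", model$species),
                   paste("irr", model$reactions[irr]))
  poly_cone(A, varnames = model$reactions)
}

#' Enumerate elementary growth modes
#'
#' Enumerates all EGMs of the growth cone up to scaling (exact arithmetic).
#' EGMs with positive associated growth rate are rescaled so that
#' \eqn{\mu(e) =} \code{normalize_mu}; EGMs with \eqn{\mu(e) = 0} are
#' elementary flux modes of the comprehensive network and are reported in
#' canonical integer scaling.  Output rows are ordered by the first produced
#' species (model species order), then lexicographically by flux.
#'
#' @param model a validated [growth_model()]
#' @param normalize_mu growth rate used to scale EGMs with \eqn{\mu > 0}
#'   (default 1/h); \code{NULL} keeps canonical integer scaling
#' @return object of class \code{egm_set}: data frame-like list with the flux
#'   matrix (rows = EGMs), associated growth rates, associated concentration
#'   matrix, produced species, and flux-mode flags
#' @export
egms <- function(model, normalize_mu = 1) {
  cone <- growth_cone(model)
  rays <- elementary_vectors(cone)
  n <- nrow(rays)
  prodlist <- vector("list", n)
  mu <- character(n)
  if (n) {
    Nv <- rq_matmul(model$stoich, t(rays))  # species x EGMs
    for (i in seq_len(n)) {
      mu[i] <- rq_dot(model$molar_masses, Nv[, i])
      prodlist[[i]] <- model$species[rat_num(Nv[, i]) != 0]
    }
  }
  if (!is.null(normalize_mu) && n) {
    nm <- as_rational(normalize_mu)
    pos <- rat_num(mu) > 0
    for (i in which(pos)) {
      f <- rq_div(nm, mu[i])
      rays[i, ] <- rq_mul(rays[i, ], f)
      mu[i] <- nm
    }
  }
  # stable order: first produced species, then lexicographic flux
  first_prod <- vapply(prodlist, function(p)
    if (length(p)) min(match(p, model$species)) else Inf, numeric(1))
  num <- rat_num(rays)
  ord <- do.call(order, c(list(first_prod), as.data.frame(num)))
  rays <- rays[ord, , drop = FALSE]
  mu <- mu[ord]
  prodlist <- prodlist[ord]
  xs <- matrix(NA_real_, n, length(model$species),
               dimnames = list(NULL, model$species))
  for (i in seq_len(n)) {
    if (rat_num(mu[i]) > 0)
      xs[i, ] <- associated_concentrations(model, rays[i, ])
  }
  structure(list(flux = rays, mu = mu, concentrations = xs,
                 produced = prodlist,
                 is_flux_mode = rat_num(mu) == 0,
                 model = model, cone = cone),
            class = "egm_set")
}

#' @export
print.egm_set <- function(x, ...) {
  n <- nrow(x$flux)
  cat("Elementary growth modes:", n, "EGMs (",
      sum(x$is_flux_mode), "with zero growth rate )\n")
  if (n) {
    prod <- vapply(x$produced, paste, character(1), collapse = "+")
    supp <- apply(rat_num(x$flux) != 0, 1, sum)
    df <- data.frame(produced = prod, mu = rat_num(x$mu), support = supp)
    print(utils::head(df, 20))
    if (n > 20) cat("  ...", n - 20, "more\n")
  }
  invisible(x)
}

#' @export
as.data.frame.egm_set <- function(x, ...) {
  flux <- rat_num(x$flux)
  colnames(flux) <- x$model$reactions
  data.frame(
    egm = seq_len(nrow(flux)),
    produced = vapply(x$produced, paste, character(1), collapse = "+"),
    mu = rat_num(x$mu),
    support = apply(flux != 0, 1, sum),
    flux,
    check.names = FALSE
  )
}

#' Which EGMs are support-minimal?
#'
#' In a growth cone, elementary vectors are conformally non-decomposable but
#' not support-minimal in general.  This helper flags the EGMs whose support
#' contains no other EGM's support strictly.
#'
#' @param x an \code{egm_set}
#' @return logical vector along the EGMs
#' @export
support_minimal <- function(x) {
  supp <- lapply(seq_len(nrow(x$flux)),
                 function(i) which(rat_num(x$flux[i, ]) != 0))
  vapply(seq_along(supp), function(i) {
    !any(vapply(seq_along(supp), function(j) {
      j != i && all(supp[[j]] %in% supp[[i]]) &&
        length(supp[[j]]) < length(supp[[i]])
    }, logical(1)))
  }, logical(1))
}

#' Conformal decomposition of a growth mode into EGMs
#'
#' Writes a growth mode \eqn{v} as \eqn{v = \sum_{E_0} e + \sum_{E_\mu}
#' \lambda_e e}: the \eqn{E_0} terms are EGMs with zero growth rate (their
#' coefficients absorbed into the vectors), the \eqn{E_\mu} terms are EGMs
#' rescaled to \eqn{\mu(e) = \mu(v)} with convex coefficients
#' \eqn{\sum \lambda_e = 1}.  When \eqn{\mu(v) > 0} the associated
#' concentrations mix accordingly: \eqn{x(v) = \sum \lambda_e x(e)}.
#'
#' @param model a validated [growth_model()]
#' @param v a growth mode (membership is checked; violations are reported
#'   with their row labels)
#' @param egm_set optional precomputed [egms()] result
#' @return a \code{growth_decomposition}: list with \code{E0} (flux-mode
#'   terms), \code{Emu} (list of \code{list(ev, lambda)} with EGMs at
#'   \eqn{\mu(v)}), \code{mu}, and the exact reconstruction residual
#' @export
decompose_growth_mode <- function(model, v, egm_set = NULL) {
  v <- as_rational(v)
  if (is.null(egm_set)) egm_set <- egms(model, normalize_mu = NULL)
  cone <- egm_set$cone
  dec <- conformal_decompose(v, cone, evs = egm_set$flux)
  mu_v <- growth_rate(model, v, exact = TRUE)
  E0 <- list(); Emu <- list()
  for (tm in dec$ray_terms) {
    mu_e <- growth_rate(model, tm$ev, exact = TRUE)
    term_flux <- rq_mul(tm$ev, tm$coef)
    if (rat_num(mu_e) == 0) {
      E0[[length(E0) + 1L]] <- term_flux
    } else {
      lambda <- rq_div(rq_mul(mu_e, tm$coef), mu_v)
      ev_scaled <- rq_div(term_flux, lambda)
      Emu[[length(Emu) + 1L]] <- list(ev = ev_scaled, lambda = lambda)
    }
  }
  lam_sum <- rq_sum(vapply(Emu, function(t) t$lambda, character(1)))
  recon <- Reduce(rq_add, c(E0, lapply(Emu, function(t)
    rq_mul(t$ev, t$lambda))), rep("0", length(v)))
  structure(list(E0 = E0, Emu = Emu, mu = mu_v, lambda_sum = lam_sum,
                 residual = rq_sub(v, recon)),
            class = "growth_decomposition")
}

#' @export
print.growth_decomposition <- function(x, ...) {
  cat("Growth-mode decomposition: ", length(x$E0), " flux-mode term(s), ",
      length(x$Emu), " growth term(s) at mu = ",
      format(rat_num(x$mu), digits = 4), "\n", sep = "")
  if (length(x$Emu)) {
    lam <- vapply(x$Emu, function(t) rat_num(t$lambda), numeric(1))
    cat("  lambda:", paste(format(lam, digits = 4), collapse = ", "),
        "(sum", format(rat_num(x$lambda_sum), digits = 4), ")\n")
  }
  invisible(x)
}

#' Write an EGM set to CSV
#'
#' One row per EGM: reaction fluxes, associated growth rate, associated
#' concentrations, mass fractions, produced species and support size.
#'
#' @param x an \code{egm_set}
#' @param file output path
#' @export
write_egm_csv <- function(x, file) {
  df <- as.data.frame(x)
  xs <- x$concentrations
  colnames(xs) <- paste0("x_", colnames(xs))
  mf <- sweep(x$concentrations, 2, rat_num(x$model$molar_masses), `*`)
  colnames(mf) <- paste0("massfrac_", x$model$species)
  utils::write.csv(cbind(df, xs, mf), file, row.names = FALSE)
  invisible(file)
}
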