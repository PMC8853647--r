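#' Autocatalysis and kinetic consistency of growth modes
#'
#' In a coarse-grained model (catalysis attached to individual reactions), a
#' growth mode \eqn{v} is *basically catalytic* (BC) if some active reaction
#' is catalytic; *catalytically closed* (CC) if every catalyst of an active
#' catalytic reaction is produced, \eqn{(Nv)_s > 0}; and *autocatalytic*
#' (AC) if both.  It is *kinetically consistent* if every species with a
#' nonzero stoichiometric coefficient in an active reaction is produced —
#' flux through a reaction requires all of its participants to be present,
#' and at balanced growth presence means production (the associated
#' concentration is \eqn{x(v)_s = (Nv)_s/\mu}).  All conditions are decided
#' exactly on \eqn{Nv}.
#'
#' @param model a validated [growth_model()]
#' @param v a growth mode (membership in the growth cone is checked)
#' @return object of class \code{autocatalysis_report} with flags
#'   \code{basically_catalytic}, \code{catalytically_closed},
#'   \code{autocatalytic}, \code{kinetically_consistent}, the catalytic
#'   reactions whose catalyst is not produced
#'   (\code{violating_reactions}) and the involved-but-unproduced species
#'   (\code{unsupplied_species})
#' @export
classify_gm <- function(model, v) {
  v <- as_rational(v)
  cone <- growth_cone(model)
  memb <- .membership(.spec_of(cone), v)
  if (!memb$ok)
    stop("flux is not a growth mode; violated: ",
         paste(memb$violated, collapse = ", "))
  Nv <- rq_matmul(model$stoich, v)
  prod_sign <- stats::setNames(rq_sign(Nv), model$species)
  active <- model$reactions[rq_sign(v) != 0]
  cats <- model$catalysts
  active_cat <- intersect(active, names(cats))
  bc <- length(active_cat) > 0
  viol <- active_cat[prod_sign[cats[active_cat]] <= 0]
  cc <- length(viol) == 0
  # kinetic consistency: every species touched by an active reaction produced
  touched <- model$species[apply(
    rat_num(model$stoich[, active, drop = FALSE]) != 0, 1, any)]
  unsup <- touched[prod_sign[touched] <= 0]
  structure(list(basically_catalytic = bc,
                 catalytically_closed = cc,
                 autocatalytic = bc && cc,
                 violating_reactions = viol,
                 kinetically_consistent = length(unsup) == 0,
                 unsupplied_species = unsup),
            class = "autocatalysis_report")
}

#' @export
print.autocatalysis_report <- function(x, ...) {
  flag <- function(b) if (b) "yes" else "no"
  cat("Autocatalysis report\n")
  cat("  basically catalytic (BC):  ", flag(x$basically_catalytic), "\n")
  cat("  catalytically closed (CC): ", flag(x$catalytically_closed), "\n")
  if (length(x$violating_reactions))
    cat("    catalyst not produced for:",
        paste(x$violating_reactions, collapse = ", "), "\n")
  cat("  autocatalytic (AC):        ", flag(x$autocatalytic), "\n")
  cat("  kinetically consistent:    ", flag(x$kinetically_consistent), "\n")
  if (length(x$unsupplied_species))
    cat("    involved but not produced:",
        paste(x$unsupplied_species, collapse = ", "), "\n")
  invisible(x)
}

# does an AC growth mode with support exactly S exist?  Decided by an exact
# LP: maximize eps subject to v_S >= eps, Nv >= 0, (Nv)_cat >= eps for the
# catalysts of the active catalytic reactions, sum(v_S) = 1.  Strict
# positivity is LP-decidable thanks to the normalization row.
.ac_support_feasible <- function(model, S) {
  cats <- model$catalysts
  active_cat <- intersect(S, names(cats))
  if (length(active_cat) == 0) return(FALSE)  # not BC
  if (!all(S %in% model$irreversible))
    stop("MAC search requires the candidate support to be irreversible")
  needed <- unique(unname(cats[active_cat]))
  Ns <- model$stoich[, S, drop = FALSE]
  nS <- length(S)
  nsp <- length(model$species)
  # variables: v_S (nS) | eps (1) | slack_mb (nsp) | slack_v (nS) | slack_cat
  ncat <- length(needed)
  nvar <- nS + 1 + nsp + nS + ncat
  M <- matrix("0", nsp + nS + ncat + 1, nvar)
  f <- rep("0", nrow(M))
  # mass balance rows: N_S v - slack_mb = 0
  M[seq_len(nsp), seq_len(nS)] <- Ns
  for (i in seq_len(nsp)) M[i, nS + 1 + i] <- "-1"
  # support strictness: v_r - eps - slack_v = 0
  for (j in seq_len(nS)) {
    r <- nsp + j
    M[r, j] <- "1"; M[r, nS + 1] <- "-1"; M[r, nS + 1 + nsp + j] <- "-1"
  }
  # catalytic closure: (Nv)_c - eps - slack_cat = 0
  for (k in seq_len(ncat)) {
    r <- nsp + nS + k
    M[r, seq_len(nS)] <- model$stoich[needed[k], S]
    M[r, nS + 1] <- "-1"; M[r, nS + 1 + nsp + nS + k] <- "-1"
  }
  # normalization: sum v = 1
  M[nrow(M), seq_len(nS)] <- "1"
  f[nrow(M)] <- "1"
  cost <- rep("0", nvar); cost[nS + 1] <- "-1"  # maximize eps
  res <- cxx_simplex(M, f, cost)
  res$status == 0 && rat_num(res$obj) < 0
}

#' Enumerate minimal autocatalytic (MAC) reaction sets
#'
#' A reaction subset is autocatalytic (AC) if some AC growth mode has
#' exactly that support; MAC sets are the inclusion-minimal AC subsets.
#' Since every growth mode is a conformal sum of EGMs, every support is a
#' union of EGM supports; the search therefore walks the union lattice of
#' EGM supports in order of increasing size, decides AC-support existence
#' for each candidate by an exact strict-feasibility LP, and prunes
#' supersets of sets already found.
#'
#' @param model a validated [growth_model()] (all candidate reactions must
#'   be irreversible)
#' @param egm_set optional precomputed [egms()] result
#' @param max_candidates safety cap on the number of distinct support unions
#' @return list of character vectors (reaction ids), each a MAC set
#' @export
mac_sets <- function(model, egm_set = NULL, max_candidates = 100000) {
  if (is.null(egm_set)) egm_set <- egms(model, normalize_mu = NULL)
  supports <- lapply(seq_len(nrow(egm_set$flux)), function(i)
    model$reactions[rat_num(egm_set$flux[i, ]) != 0])
  k <- length(supports)
  if (2^k > max_candidates)
    stop("too many EGM-support unions; raise max_candidates")
  # all unions of EGM supports, deduplicated
  cand <- new.env(parent = emptyenv())
  for (bits in seq_len(2^k - 1)) {
    members <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) != 0)
    S <- sort(unique(unlist(supports[members])))
    cand[[paste(S, collapse = "|")]] <- S
  }
  sets <- mget(ls(cand), envir = cand)
  sizes <- lengths(sets)
  sets <- sets[order(sizes)]
  found <- list()
  for (S in sets) {
    if (any(vapply(found, function(Fm) all(Fm %in% S), logical(1)))) next
    if (.ac_support_feasible(model, S)) found[[length(found) + 1L]] <- S
  }
  found
}
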