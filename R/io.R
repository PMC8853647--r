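#' Read and write growth models as JSON
#'
#' Schema: \code{{"species": [{"id", "molar_mass"}],
#' "reactions": [{"id", "stoich": {species: coeff}, "irreversible",
#' "catalyst", "exchange"}]}}.  Coefficients and masses are exact rationals
#' serialized as \code{"p/q"} strings; unknown masses are \code{null} and can
#' be completed with [derive_masses()].  The round trip is the identity on
#' the schema fields.
#'
#' @param file path to a model JSON file
#' @param model a [growth_model()]
#' @return \code{read_growth_model()}: a [growth_model()]
#' @export
read_growth_model <- function(file) {
  j <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (is.null(j$species) || is.null(j$reactions))
    stop("model file must contain 'species' and 'reactions'")
  sp <- vapply(j$species, `[[`, character(1), "id")
  mm <- vapply(j$species, function(s)
    if (is.null(s$molar_mass)) NA_character_ else as.character(s$molar_mass),
    character(1))
  names(mm) <- sp
  rx <- vapply(j$reactions, `[[`, character(1), "id")
  N <- matrix("0", length(sp), length(rx), dimnames = list(sp, rx))
  for (r in j$reactions) {
    for (s in names(r$stoich)) {
      if (!s %in% sp) stop("stoichiometry references unknown species: ", s)
      N[s, r$id] <- as.character(r$stoich[[s]])
    }
  }
  irr <- rx[vapply(j$reactions, function(r)
    isTRUE(r$irreversible), logical(1))]
  has_exc <- any(vapply(j$reactions, function(r)
    !is.null(r$exchange), logical(1)))
  exc <- if (has_exc) {
    rx[vapply(j$reactions, function(r) isTRUE(r$exchange), logical(1))]
  } else NULL
  cats <- character(0)
  for (r in j$reactions) {
    if (!is.null(r$catalyst)) cats[r$id] <- r$catalyst
  }
  m <- growth_model(sp, mm[!is.na(mm)], N, irr, exchange = exc,
                    catalysts = cats)
  if (anyNA(m$molar_masses) && !is.null(exc)) m <- derive_masses(m)
  m
}

#' @rdname read_growth_model
#' @export
write_growth_model <- function(model, file) {
  sp <- lapply(model$species, function(s)
    list(id = s, molar_mass = if (is.na(model$molar_masses[[s]])) NULL
                              else model$molar_masses[[s]]))
  rx <- lapply(model$reactions, function(r) {
    col <- model$stoich[, r]
    nz <- col[rq_sign(col) != 0]
    out <- list(id = r, stoich = as.list(nz),
                irreversible = r %in% model$irreversible,
                exchange = r %in% model$exchange)
    if (r %in% names(model$catalysts))
      out$catalyst <- unname(model$catalysts[[r]])
    out
  })
  jsonlite::write_json(list(species = sp, reactions = rx), file,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(file)
}

#' Generate a random mass-consistent growth model
#'
#' Property-test input generator.  Builds a model that passes
#' [validate_model()] by construction: every metabolite gets an exchange
#' import reaction; internal metabolite reactions draw random participants
#' and integer coefficients with the last coefficient solved from mass
#' balance \eqn{\omega^T N_{col} = 0}; each macromolecule is synthesized
#' from a random metabolite precursor (mass set by mass balance) under a
#' randomly chosen macromolecule catalyst.  Models with a semipositive
#' conservation law (possible by unlucky draws) are rejected and resampled.
#' Deterministic for a given seed; the global RNG state is left untouched.
#'
#' @param n_metabolites,n_macromolecules,n_reactions sizes (each >= 1;
#'   \code{n_reactions} counts internal metabolite reactions)
#' @param seed integer seed
#' @return a validated [growth_model()]
#' @export
random_growth_model <- function(n_metabolites, n_macromolecules,
                                n_reactions, seed) {
  stopifnot(n_metabolites >= 1, n_macromolecules >= 1, n_reactions >= 0)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (attempt in 1:25) {
    m <- .random_model_once(n_metabolites, n_macromolecules, n_reactions)
    if (!is.null(m) && validate_model(m)$ok) return(m)
  }
  stop("could not generate a conservation-law-free model; ",
       "try different sizes")
}

.random_model_once <- function(n_met, n_macro, n_rxn) {
  mets <- paste0("M", seq_len(n_met))
  macros <- paste0("P", seq_len(n_macro))
  sp <- c(mets, macros)
  masses <- stats::setNames(as.character(sample(10:300, n_met, TRUE)), mets)
  rx <- character(0)
  cols <- list()
  exc <- character(0)
  cats <- character(0)
  for (mt in mets) {
    id <- paste0("imp_", mt)
    col <- stats::setNames(rep("0", length(sp)), sp)
    col[mt] <- "1"
    cols[[id]] <- col
    exc <- c(exc, id)
  }
  wm <- rat_num(as_rational(masses))
  for (k in seq_len(n_rxn)) {
    id <- paste0("rxn_", k)
    npart <- sample(2:min(3, n_met + 1), 1)
    if (npart > n_met) npart <- n_met
    if (npart < 2) break
    part <- sample(mets, npart)
    co <- sample(c(-2, -1, 1, 2), npart - 1, TRUE)
    rest <- -sum(wm[part[-npart]] * co) / wm[part[npart]]
    if (rest == 0) next
    col <- stats::setNames(rep("0", length(sp)), sp)
    col[part[-npart]] <- as.character(co)
    col[part[npart]] <- rationalize(rest, tol = 1e-12, maxden = 1e6)
    cols[[id]] <- col
  }
  for (i in seq_along(macros)) {
    id <- paste0("syn_", macros[i])
    prec <- sample(mets, 1)
    n <- sample(2:10, 1)
    col <- stats::setNames(rep("0", length(sp)), sp)
    col[prec] <- as.character(-n)
    col[macros[i]] <- "1"
    cols[[id]] <- col
    cats[id] <- macros[n_macro]  # ribosome-like last macromolecule
  }
  for (id in names(cols)) {
    if (!startsWith(id, "syn_") )
      cats[id] <- sample(macros, 1)
  }
  N <- do.call(cbind, cols)
  colnames(N) <- names(cols)
  rownames(N) <- sp
  m <- try(growth_model(sp, masses, N, irreversible = colnames(N),
                        exchange = exc, catalysts = cats), silent = TRUE)
  if (inherits(m, "try-error")) return(NULL)
  m <- try(derive_masses(m), silent = TRUE)
  if (inherits(m, "try-error")) return(NULL)
  m
}

#' Read a constraint configuration
#'
#' JSON with two optional blocks: \code{"capacity"}, overriding
#' [capacity_params()] fields keyed by symbol name (\code{k_cat},
#' \code{k_el}, \code{A_L}, \code{A_I}, \code{rho}, \code{alpha},
#' \code{r_intercept}, \code{r_slope}; exact rationals as strings), and
#' \code{"custom"}, a list of rows
#' \code{{label, relation, conc: {species: coeff}, flux: {reaction: coeff},
#' rhs}} appended to the generated constraint set.
#'
#' @param file path to the JSON configuration
#' @param model the [growth_model()] the custom rows refer to
#' @return list with \code{params} ([capacity_params()]) and
#'   \code{constraints_fn}, a function \code{(model, mu)} building the full
#'   [constraint_set()]
#' @export
read_constraints_config <- function(file, model) {
  j <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  cp <- j$capacity %||% list()
  map <- c(k_cat = "kcat", k_el = "kel", A_L = "area_L", A_I = "area_I",
           rho = "rho", alpha = "alpha", r_intercept = "s2v_intercept",
           r_slope = "s2v_slope")
  args <- list()
  for (sym in names(map)) {
    if (!is.null(cp[[sym]])) args[[map[[sym]]]] <- as.character(cp[[sym]])
  }
  params <- do.call(capacity_params, args)
  custom <- NULL
  if (length(j$custom)) {
    nsp <- length(model$species); nrx <- length(model$reactions)
    conc <- NULL; flux <- NULL; rhs <- character(0)
    rel <- character(0); labs <- character(0)
    for (row in j$custom) {
      a <- rep("0", nsp); b <- rep("0", nrx)
      for (s in names(row$conc)) a[match(s, model$species)] <-
          as.character(row$conc[[s]])
      for (r in names(row$flux)) b[match(r, model$reactions)] <-
          as.character(row$flux[[r]])
      conc <- rbind(conc, a); flux <- rbind(flux, b)
      rhs <- c(rhs, as.character(row$rhs %||% "0"))
      rel <- c(rel, row$relation %||% ">=")
      labs <- c(labs, row$label)
    }
    colnames(conc) <- model$species; colnames(flux) <- model$reactions
    custom <- constraint_set(conc, flux, rhs, rel, labs)
  }
  list(params = params,
       constraints_fn = function(model, mu) {
         base <- capacity_constraints(model, params, mu)
         if (is.null(custom)) base else rbind(base, custom)
       })
}

# ---------------------------------------------------------------------------
# command-line driver
# ---------------------------------------------------------------------------

#' Run a command-line style analysis
#'
#' Thin programmatic driver behind the \code{egrowth} command-line script
#' (\code{inst/cli/egrowth.R}).  Reads a model (and optional constraint
#' configuration), runs the requested analysis, writes CSV/JSON artifacts
#' and a run log into \code{output_dir}, and returns an exit status:
#' 0 success, 1 model-validation failure, 2 infeasible, 3 I/O error,
#' 4 configuration error.  Log messages go to \code{stderr}; results only to
#' files.
#'
#' @param config list with fields \code{mode} (one of \code{"validate"},
#'   \code{"egm"}, \code{"egv"}, \code{"sweep"}, \code{"decompose"},
#'   \code{"autocat"}, \code{"traditional"}), \code{model_path},
#'   \code{output_dir}, and mode-specific fields \code{mu},
#'   \code{mu_min}, \code{mu_max}, \code{step}, \code{flux_path},
#'   \code{seed}
#' @return integer exit status, invisibly
#' @export
run_cli <- function(config) {
  msg <- function(...) message("[egrowth] ", ...)
  modes <- c("validate", "egm", "egv", "sweep", "decompose", "autocat",
             "traditional")
  if (is.null(config$mode) || !config$mode %in% modes) {
    msg("unknown or missing mode")
    return(invisible(4L))
  }
  if (is.null(config$model_path) || !file.exists(config$model_path)) {
    msg("model file not found: ", config$model_path)
    return(invisible(3L))
  }
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- tryCatch(read_growth_model(config$model_path), error = function(e) {
    msg("failed to read model: ", conditionMessage(e)); NULL
  })
  .cli_constraints <- function(config, model) {
    if (is.null(config$constraints_path)) return(NULL)
    read_constraints_config(config$constraints_path, model)
  }
  if (is.null(model)) return(invisible(3L))
  val <- validate_model(model)
  if (!val$ok) {
    msg("model validation failed: ", paste(val$failures, collapse = "; "))
    if (config$mode != "validate") return(invisible(1L))
  }
  logf <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste("egrowth", as.character(utils::packageVersion("egrowth"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("time:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("mode:", config$mode),
    paste("model:", config$model_path),
    paste("mu:", config$mu %||% ""),
    paste("seed:", config$seed %||% ""),
    "arithmetic: exact rational"
  ), logf)
  status <- switch(config$mode,
    validate = {
      jsonlite::write_json(list(ok = val$ok, failures = val$failures),
                           file.path(out_dir, "validation.json"),
                           auto_unbox = TRUE)
      if (val$ok) 0L else 1L
    },
    egm = {
      write_egm_csv(egms(model), file.path(out_dir, "egms.csv"))
      0L
    },
    egv = {
      if (is.null(config$mu)) { msg("egv mode needs --mu > 0"); 4L }
      else {
        cc <- .cli_constraints(config, model)
        ev <- egvs(model, config$mu,
                   constraints = if (!is.null(cc))
                     cc$constraints_fn(model, .mu_rat(config$mu)),
                   params = if (!is.null(cc)) cc$params
                            else capacity_params())
        if (!ev$feasible) {
          msg("growth polyhedron infeasible at mu = ", config$mu)
          2L
        } else {
          write_egv_csv(ev, file.path(out_dir, "egvs.csv"))
          0L
        }
      }
    },
    sweep = {
      cc <- .cli_constraints(config, model)
      sw <- sweep_mu(model,
                     params = if (!is.null(cc)) cc$params
                              else capacity_params(),
                     constraints_fn = if (!is.null(cc)) cc$constraints_fn,
                     mu_min = config$mu_min %||% 0.05,
                     mu_max_scan = config$mu_max %||% 1.5,
                     step = config$step %||% 0.05)
      write_egv_csv(sw, file.path(out_dir, "sweep.csv"))
      utils::write.csv(sw$classes, file.path(out_dir, "families.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(mu_crit = sw$mu_crit, mu_max = sw$mu_max),
                           file.path(out_dir, "sweep_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      0L
    },
    decompose = {
      if (is.null(config$flux_path) || !file.exists(config$flux_path)) {
        msg("decompose mode needs --flux <tsv>"); 3L
      } else {
        v <- read_rational_tsv(config$flux_path)[, 1]
        dec <- if (is.null(config$mu)) decompose_growth_mode(model, v)
               else decompose_growth_vector(model, config$mu, v)
        nterms <- if (inherits(dec, "growth_decomposition")) {
          length(dec$E0) + length(dec$Emu)
        } else length(dec$point_terms) + length(dec$ray_terms)
        jsonlite::write_json(list(n_terms = nterms, exact = TRUE),
                             file.path(out_dir, "decomposition.json"),
                             auto_unbox = TRUE)
        0L
      }
    },
    autocat = {
      ms <- mac_sets(model)
      jsonlite::write_json(ms, file.path(out_dir, "mac_sets.json"))
      0L
    },
    traditional = {
      sw <- sweep_mu(model)
      if (is.na(sw$mu_max)) { msg("no maximum growth rate found"); 2L }
      else {
        ev <- egvs(model, rationalize(sw$mu_max - 1e-3))
        ref <- list(mu = ev$mu,
                    x = as_rational(stats::setNames(
                      ev$concentrations[1, ], model$species)))
        tm <- traditional_model(model, ref)
        ta <- traditional_analysis(tm, model)
        jsonlite::write_json(list(n_efm = ta$n_efm, n_efv = ta$n_efv),
                             file.path(out_dir, "traditional.json"),
                             auto_unbox = TRUE)
        0L
      }
    })
  msg("done (status ", status, "); artifacts in ", out_dir)
  invisible(status)
}
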