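#' Define a species in a reaction network
#'
#' @param id Short unique label used in concentration vectors and tables.
#' @param name Free-text name.
#' @param role One of `"substrate"`, `"nucleophile"`, `"product"`,
#'   `"byproduct"`. Species with an aromatic core (everything except the
#'   nucleophile here) enter the aromatic mass balance.
#' @return A one-row tibble.
#' @export
species <- function(id, name = id,
                    role = c("substrate", "nucleophile", "product", "byproduct")) {
  role <- match.arg(role)
  tibble::tibble(id = as.character(id), name = as.character(name), role = role)
}

#' Define an elementary reaction step
#'
#' A step has a rate law \eqn{r = k(T) \prod_i C_i^{n_i}} with Arrhenius
#' temperature dependence, and a signed stoichiometry giving the change in each
#' species per reaction event.
#'
#' @param label Step label.
#' @param orders Named numeric vector of reactant orders (species id ->
#'   exponent, non-negative; at least one must be positive).
#' @param stoich Named numeric vector of signed stoichiometric changes.
#' @param params An [arrhenius_params()] object.
#' @return An object of class `reaction_step`.
#' @export
reaction_step <- function(label, orders, stoich, params) {
  if (is.null(names(orders)) || is.null(names(stoich))) {
    abort_config("`orders` and `stoich` must be named by species id.")
  }
  if (any(orders < 0)) abort_config("Reaction orders must be non-negative.")
  if (!any(orders > 0)) {
    abort_config(sprintf("Step '%s' must have at least one reactant with positive order.", label))
  }
  if (!inherits(params, "arrhenius_params")) {
    params <- arrhenius_params(params$k_ref, params$Ea, params$T_ref)
  }
  structure(list(label = label, orders = orders, stoich = stoich, params = params),
    class = "reaction_step")
}

#' Assemble a kinetic scheme
#'
#' Bundles species and steps into a reaction network whose batch ODEs are
#' \eqn{dC/dt = S\, r(C, T)}. Validation enforces unique species ids, that
#' every species referenced by a step exists, and that each substitution step
#' conserves the aromatic core (the signed stoichiometry over aromatic species
#' sums to zero).
#'
#' @param species_tbl Tibble of species rows from [species()].
#' @param steps List of [reaction_step()] objects.
#' @param nucleophile_stoich_factor Nucleophile molecules consumed per
#'   substitution event (1 or 2); see [snar_scheme()].
#' @param id Scheme identifier stored in campaign metadata.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species_tbl, steps, nucleophile_stoich_factor = 1,
                           id = "custom") {
  if (anyDuplicated(species_tbl$id)) {
    abort_config("Species ids must be unique within a scheme.")
  }
  ids <- species_tbl$id
  aromatic <- ids[species_tbl$role != "nucleophile"]
  for (st in steps) {
    refd <- union(names(st$orders), names(st$stoich))
    missing <- setdiff(refd, ids)
    if (length(missing) > 0) {
      abort_config(sprintf("Step '%s' references unknown species: %s.",
        st$label, paste(missing, collapse = ", ")))
    }
    arom_change <- sum(st$stoich[intersect(names(st$stoich), aromatic)])
    if (abs(arom_change) > 1e-12) {
      abort_config(sprintf("Step '%s' does not conserve the aromatic core (net %g).",
        st$label, arom_change))
    }
  }
  # stoichiometry matrix, species x steps
  S <- matrix(0, nrow = length(ids), ncol = length(steps),
    dimnames = list(ids, vapply(steps, function(s) s$label, character(1))))
  for (j in seq_along(steps)) {
    S[names(steps[[j]]$stoich), j] <- steps[[j]]$stoich
  }
  structure(list(species = species_tbl, steps = steps, S = S,
    nu = nucleophile_stoich_factor, id = id),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme '%s'>: %d species, %d steps, nu = %g\n",
    x$id, nrow(x$species), length(x$steps), x$nu))
  for (st in x$steps) {
    cat(sprintf("  %-8s k_ref = %.4g, Ea = %.4g kJ/mol (T_ref = %.2f K)\n",
      st$label, st$params$k_ref, st$params$Ea / 1000, st$params$T_ref))
  }
  invisible(x)
}

#' The built-in SNAr scheme: 2,4-difluoronitrobenzene + pyrrolidine
#'
#' Four parallel/consecutive substitution steps in ethanol:
#' substrate -> ortho product (`k1`), substrate -> para product (`k2`),
#' ortho -> bis adduct (`k3`), para -> bis adduct (`k4`). In the default motif
#' every step is first order in the aromatic component and first order in
#' pyrrolidine (overall second order); rate constants are given at
#' `T_ref` = 90 degC. Defaults are the fitted estimates for this system:
#' k1 = 0.579, k2 = 0.0270, k3 = 0.00865, k4 = 0.0163 M^-1 s^-1 and
#' Ea = 33.3, 35.3, 38.9, 44.8 kJ mol^-1.
#'
#' @param k_ref Numeric length-4, rate constants at `T_ref` (M^-1 s^-1).
#' @param Ea Numeric length-4, activation energies (J mol^-1).
#' @param T_ref Reference temperature (K).
#' @param nucleophile_stoich_factor Pyrrolidine consumed per substitution
#'   event: 1 (free amine only) or 2 (a second equivalent scavenges HF as the
#'   pyrrolidinium salt).
#' @param aromatic_order,nucleophile_order Rate-law exponents applied to every
#'   step (integers 0-2); the default (1, 1) is the all-second-order motif.
#'   Alternative orders are used for rate-order discrimination.
#' @return A [kinetic_scheme()].
#' @examples
#' sc <- snar_scheme()
#' reaction_rates(sc, c(dfnb = 1, pyr = 1, ortho = 0, para = 0, bis = 0), T = 363.15)
#' @export
snar_scheme <- function(k_ref = c(0.579, 0.0270, 0.00865, 0.0163),
                        Ea = c(33300, 35300, 38900, 44800),
                        T_ref = 363.15,
                        nucleophile_stoich_factor = 1,
                        aromatic_order = 1, nucleophile_order = 1) {
  stopifnot(length(k_ref) == 4, length(Ea) == 4)
  if (!nucleophile_stoich_factor %in% c(1, 2)) {
    abort_config("`nucleophile_stoich_factor` must be 1 or 2.")
  }
  if (!aromatic_order %in% 0:2 || !nucleophile_order %in% 0:2) {
    abort_config("Rate-law orders must be integers in 0..2.")
  }
  if (aromatic_order == 0 && nucleophile_order == 0) {
    abort_config("At least one reactant must have a positive order.")
  }
  sp <- dplyr::bind_rows(
    species("dfnb", "2,4-difluoronitrobenzene", "substrate"),
    species("pyr", "pyrrolidine", "nucleophile"),
    species("ortho", "ortho-substituted product", "product"),
    species("para", "para-substituted product", "byproduct"),
    species("bis", "bis-adduct", "byproduct")
  )
  nu <- nucleophile_stoich_factor
  mk <- function(i, arom, prod) {
    orders <- c(aromatic_order, nucleophile_order)
    names(orders) <- c(arom, "pyr")
    orders <- orders[orders > 0]
    stoich <- stats::setNames(c(-1, 1, -nu), c(arom, prod, "pyr"))
    reaction_step(paste0("step", i), orders, stoich,
      arrhenius_params(k_ref[i], Ea[i], T_ref))
  }
  steps <- list(mk(1, "dfnb", "ortho"), mk(2, "dfnb", "para"),
    mk(3, "ortho", "bis"), mk(4, "para", "bis"))
  id <- sprintf("snar_a%dn%d_nu%d", aromatic_order, nucleophile_order, nu)
  kinetic_scheme(sp, steps, nucleophile_stoich_factor = nu, id = id)
}

#' Step rates at a given state
#'
#' Evaluates \eqn{r_j = k_j(T) \prod_i C_i^{n_{ij}}} for every step.
#'
#' @param scheme A [kinetic_scheme()].
#' @param conc Named numeric vector of concentrations (M) covering all scheme
#'   species.
#' @param T Temperature in K.
#' @return Named numeric vector of step rates (M s^-1).
#' @export
reaction_rates <- function(scheme, conc, T) {
  missing <- setdiff(scheme$species$id, names(conc))
  if (length(missing) > 0) {
    abort_data(sprintf("State is missing concentrations for: %s.",
      paste(missing, collapse = ", ")))
  }
  vapply(scheme$steps, function(st) {
    k <- arrhenius_k(st$params, T)
    cc <- pmax(conc[names(st$orders)], 0)
    k * prod(cc^st$orders)
  }, numeric(1))
}

#' Linear conservation invariants of a scheme
#'
#' For the SNAr network the aromatic core C_dfnb + C_ortho + C_para + C_bis and
#' the nucleophile combination C_pyr + nu (C_ortho + C_para + 2 C_bis) are
#' conserved along any trajectory. Returns both for each row of a trajectory.
#'
#' @param scheme A [kinetic_scheme()].
#' @param traj Tibble with one column per species id (e.g. from
#'   [simulate_profile()]).
#' @return Tibble with columns `aromatic_total`, `nucleophile_total`.
#' @export
conserved_totals <- function(scheme, traj) {
  ids <- scheme$species$id
  arom <- ids[scheme$species$role != "nucleophile"]
  w <- nucleophile_weights(scheme)
  mat <- as.matrix(traj[, ids, drop = FALSE])
  tibble::tibble(
    aromatic_total = rowSums(mat[, arom, drop = FALSE]),
    nucleophile_total = as.numeric(mat %*% w[ids])
  )
}

# Weight vector w with w'S = 0: nucleophile species weight 1, substrate weight
# 0, remaining weights = nucleophile units incorporated per molecule, solved
# from the stoichiometry matrix.
nucleophile_weights <- function(scheme) {
  ids <- scheme$species$id
  roles <- stats::setNames(scheme$species$role, ids)
  w <- stats::setNames(rep(NA_real_, length(ids)), ids)
  w[roles == "nucleophile"] <- 1
  w[roles == "substrate"] <- 0
  free <- ids[is.na(w)]
  St <- t(scheme$S) # steps x species
  if (length(free) > 0) {
    A <- St[, free, drop = FALSE]
    b <- -St[, !is.na(w[ids]), drop = FALSE] %*% w[ids][!is.na(w[ids])]
    sol <- stats::lsfit(A, b, intercept = FALSE)
    w[free] <- sol$coefficients
  }
  resid <- max(abs(St %*% w[ids]))
  if (resid > 1e-8) {
    rlang::warn("No exact nucleophile conservation law exists for this scheme; totals are approximate.")
  }
  w
}
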