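#' @include AllClasses.R
NULL

#' Hill-function coupling of Fj activity to phosphorylation
#'
#' Fraction of maximal phosphorylation rate driven by a given Fj kinase
#' activity: \code{fj^n / (K^n + fj^n)}. Monotonically increasing, equal to
#' 1/2 exactly at \code{fj = K}. With the default K = 250 and normalized
#' activities in [0, 1] the coupling operates in its near-linear regime.
#'
#' @param fjLevel non-negative Fj activity (scalar or vector).
#' @param hillN Hill coefficient, >= 1.
#' @param hillK half-saturation constant, > 0.
#' @return activity fraction in [0, 1), same length as \code{fjLevel}.
#' @examples
#' hillActivity(250, 1, 250)  # 0.5
#' hillActivity(750, 1, 250)  # 0.75
#' @export
hillActivity <- function(fjLevel, hillN, hillK) {
    if (any(!is.finite(fjLevel)) || any(fjLevel < 0))
        stop("'fjLevel' must be finite and non-negative")
    if (!is.finite(hillK) || hillK <= 0)
        stop("'hillK' must be positive")
    if (!is.finite(hillN) || hillN < 1)
        stop("'hillN' must be >= 1")
    fjLevel^hillN / (hillK^hillN + fjLevel^hillN)
}

.checkConservation <- function(state, profiles, where = "state") {
    if (nCells(state) != nCells(profiles))
        stop("state and profiles disagree on the number of cells")
    slack <- 1e-12
    if (any(state@ftP > profiles@ftTotal + slack) ||
        any(state@dsP > profiles@dsTotal + slack))
        stop(where, " violates conservation bounds: phosphorylated level ",
             "exceeds the cell's total")
    invisible(TRUE)
}

#' Unphosphorylated Ft and Ds by conservation
#'
#' The model stores only phosphorylated levels; unphosphorylated Ft and Ds
#' follow from conservation of each cell's total:
#' \code{ftU = ftTotal - ftP}, \code{dsU = dsTotal - dsP}.
#'
#' @param state a \linkS4class{PhosphoState} within conservation bounds.
#' @param profiles matching \linkS4class{ExpressionProfiles}.
#' @return list with numeric vectors \code{ftU} and \code{dsU}.
#' @examples
#' cfg <- defaultWildtypeConfig()
#' st <- steadyStatePhospho(cfg$profiles, cfg$params)
#' unphosphorylatedLevels(st, cfg$profiles)
#' @export
unphosphorylatedLevels <- function(state, profiles) {
    .checkConservation(state, profiles)
    list(ftU = pmax(profiles@ftTotal - state@ftP, 0),
         dsU = pmax(profiles@dsTotal - state@dsP, 0))
}

# per-cell effective phosphorylation rates a = alpha * H(fj)
.phosRates <- function(profiles, params) {
    h <- hillActivity(profiles@fj, params@hillN, params@hillK)
    list(aFt = params@alphaFt * h, aDs = params@alphaDs * h)
}

#' Right-hand sides of the phosphorylation ODEs
#'
#' Per-cell time derivatives of phosphorylated Ft and Ds. In each cell,
#' Fj-driven phosphorylation converts the unphosphorylated pool at rate
#' \code{alpha * H(fj)} and dephosphorylation returns the phosphorylated
#' pool at rate \code{beta}; cells are uncoupled in these equations:
#' \deqn{d Ft^p_i/dt = \alpha_{Ft} H(Fj_i) (Ft_T - Ft^p_i) -
#'   \beta_{Ft} Ft^p_i}
#' and analogously for Ds.
#'
#' @param state a \linkS4class{PhosphoState}.
#' @param profiles matching \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters}.
#' @return list with numeric vectors \code{dFtP} and \code{dDsP}.
#' @export
phosphoRates <- function(state, profiles, params) {
    .checkConservation(state, profiles)
    a <- .phosRates(profiles, params)
    list(dFtP = a$aFt * (profiles@ftTotal - state@ftP) -
              params@betaFt * state@ftP,
         dDsP = a$aDs * (profiles@dsTotal - state@dsP) -
              params@betaDs * state@dsP)
}

#' Closed-form steady state of the phosphorylation kinetics
#'
#' Each cell's linear kinetics has the unique fixed point
#' \code{x* = total * a / (a + beta)} with \code{a = alpha * H(fj)}; the
#' returned state has identically zero [phosphoRates()]. It is globally
#' attracting, which is why converged simulations are independent of their
#' random initial conditions.
#'
#' @param profiles \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters} with positive beta rates.
#' @return the steady \linkS4class{PhosphoState}.
#' @examples
#' cfg <- defaultWildtypeConfig()
#' ss <- steadyStatePhospho(cfg$profiles, cfg$params)
#' max(abs(phosphoRates(ss, cfg$profiles, cfg$params)$dFtP))  # ~0
#' @export
steadyStatePhospho <- function(profiles, params) {
    a <- .phosRates(profiles, params)
    phosphoState(
        ftP = profiles@ftTotal * a$aFt / (a$aFt + params@betaFt),
        dsP = profiles@dsTotal * a$aDs / (a$aDs + params@betaDs))
}

#' Exact time evolution of the phosphorylation kinetics
#'
#' The phosphorylation ODEs are linear per cell, so relaxation from any
#' initial condition is a single exponential:
#' \code{x(t) = x* + (x(0) - x*) exp(-(a + beta) t)}. This is the exact
#' solution used as the oracle for the forward-difference integrator.
#'
#' @param initial initial \linkS4class{PhosphoState}.
#' @param profiles \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters}.
#' @param t non-negative time (scalar).
#' @return the \linkS4class{PhosphoState} at time \code{t}.
#' @export
analyticRelaxation <- function(initial, profiles, params, t) {
    if (!is.finite(t) || t < 0) stop("'t' must be a non-negative number")
    .checkConservation(initial, profiles, "initial state")
    a <- .phosRates(profiles, params)
    ss <- steadyStatePhospho(profiles, params)
    phosphoState(
        ftP = ss@ftP + (initial@ftP - ss@ftP) *
            exp(-(a$aFt + params@betaFt) * t),
        dsP = ss@dsP + (initial@dsP - ss@dsP) *
            exp(-(a$aDs + params@betaDs) * t))
}
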