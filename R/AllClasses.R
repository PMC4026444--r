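#' @import methods
NULL

.checkScalar <- function(x, name, lower = 0, strict = FALSE) {
    if (length(x) != 1L || !is.finite(x))
        return(sprintf("'%s' must be a single finite number", name))
    if (strict && x <= lower)
        return(sprintf("'%s' must be > %g", name, lower))
    if (!strict && x < lower)
        return(sprintf("'%s' must be >= %g", name, lower))
    NULL
}

#' Kinetic parameters of the Ft-Ds-Fj model
#'
#' Holds every rate constant of the model: the Fj-driven phosphorylation
#' and background dephosphorylation rates of Ft and Ds, the Hill parameters
#' coupling Fj activity to phosphorylation, the heterodimer
#' association/dissociation rates, the weight factor \code{mu} on the
#' Ds-polarity term of the asymmetry decomposition, and the cell count.
#' Dephosphorylation and dissociation rates must be strictly positive so
#' that steady states exist.
#'
#' @slot nCells integer, number of cells in the row (>= 3).
#' @slot alphaFt,betaFt phosphorylation (by Fj) and dephosphorylation rates
#'   of Ft, per unit time.
#' @slot alphaDs,betaDs the same two rates for Ds.
#' @slot hillN Hill coefficient of the Fj activity coupling (>= 1).
#' @slot hillK Hill half-saturation constant, in Fj concentration units.
#' @slot kOn,kOff heterodimer association and dissociation rates.
#' @slot mu dimensionless weight on the Ds-polarity term.
#'
#' @seealso [modelParameters()] for the user-facing constructor.
#' @export
setClass("ModelParameters",
    representation(
        nCells = "integer",
        alphaFt = "numeric", betaFt = "numeric",
        alphaDs = "numeric", betaDs = "numeric",
        hillN = "numeric", hillK = "numeric",
        kOn = "numeric", kOff = "numeric",
        mu = "numeric"
    )
)

setValidity("ModelParameters", function(object) {
    msgs <- c(
        if (length(object@nCells) != 1L || is.na(object@nCells) ||
            object@nCells < 3L)
            "'nCells' must be a single integer >= 3 (at least one interior cell)",
        .checkScalar(object@alphaFt, "alphaFt"),
        .checkScalar(object@alphaDs, "alphaDs"),
        .checkScalar(object@betaFt, "betaFt", strict = TRUE),
        .checkScalar(object@betaDs, "betaDs", strict = TRUE),
        .checkScalar(object@hillN, "hillN", lower = 1),
        .checkScalar(object@hillK, "hillK", strict = TRUE),
        .checkScalar(object@kOn, "kOn"),
        .checkScalar(object@kOff, "kOff", strict = TRUE),
        .checkScalar(object@mu, "mu")
    )
    if (length(msgs)) msgs else TRUE
})

#' Construct model parameters
#'
#' Defaults are the wild-type parameter set: 20 cells, symmetric
#' phosphorylation kinetics for Ft and Ds (alpha = 2, beta = 0.1), a
#' near-linear Hill coupling (n = 1, K = 250 against Fj activities
#' normalized to at most 1), heterodimer rates kOn = 1, kOff = 0.1, and
#' equal weighting of the two polarity mechanisms (mu = 1).
#'
#' @param nCells number of cells in the row.
#' @param alphaFt,betaFt phosphorylation/dephosphorylation rates of Ft.
#' @param alphaDs,betaDs phosphorylation/dephosphorylation rates of Ds.
#' @param hillN,hillK Hill coefficient and half-saturation constant.
#' @param kOn,kOff heterodimer association/dissociation rates.
#' @param mu weight factor on the Ds-polarity term.
#' @return a validated \linkS4class{ModelParameters} object.
#' @examples
#' p <- modelParameters()
#' nCells(p)
#' @export
modelParameters <- function(nCells = 20L, alphaFt = 2, betaFt = 0.1,
                            alphaDs = 2, betaDs = 0.1,
                            hillN = 1, hillK = 250,
                            kOn = 1, kOff = 0.1, mu = 1) {
    new("ModelParameters", nCells = as.integer(nCells),
        alphaFt = as.numeric(alphaFt), betaFt = as.numeric(betaFt),
        alphaDs = as.numeric(alphaDs), betaDs = as.numeric(betaDs),
        hillN = as.numeric(hillN), hillK = as.numeric(hillK),
        kOn = as.numeric(kOn), kOff = as.numeric(kOff),
        mu = as.numeric(mu))
}

#' Per-cell expression profiles
#'
#' Per-cell Fj kinase activity, total Ds and total Ft along the
#' proximo-distal axis (cell 1 is the most proximal). Concentrations are in
#' the model's normalized units: total Ft is 1 in every cell, and Fj and
#' total Ds are scaled by their values in the most distal cell. Kinase
#' expression and kinase activity are treated as synonymous, so a single
#' \code{fj} vector serves for both.
#'
#' @slot fj numeric vector, Fj activity per cell.
#' @slot dsTotal numeric vector, total Ds per cell.
#' @slot ftTotal numeric vector, total Ft per cell.
#'
#' @seealso [expressionProfiles()], [wildtypeProfiles()]
#' @export
setClass("ExpressionProfiles",
    representation(fj = "numeric", dsTotal = "numeric", ftTotal = "numeric")
)

setValidity("ExpressionProfiles", function(object) {
    n <- length(object@fj)
    msgs <- c(
        if (n < 3L) "profiles must cover at least 3 cells",
        if (length(object@dsTotal) != n || length(object@ftTotal) != n)
            "'fj', 'dsTotal' and 'ftTotal' must have equal length",
        if (anyNA(object@fj) || anyNA(object@dsTotal) || anyNA(object@ftTotal))
            "profiles must not contain NA",
        if (any(object@fj < 0) || any(object@dsTotal < 0) ||
            any(object@ftTotal < 0))
            "profile entries must be non-negative"
    )
    if (length(msgs)) msgs else TRUE
})

#' Construct expression profiles
#'
#' @param fj,dsTotal,ftTotal numeric vectors of equal length (>= 3): per-cell
#'   Fj activity, total Ds and total Ft, ordered proximal to distal.
#' @return a validated \linkS4class{ExpressionProfiles} object.
#' @examples
#' expressionProfiles(fj = (1:5) / 5, dsTotal = seq(1.4, 1, length.out = 5),
#'                    ftTotal = rep(1, 5))
#' @export
expressionProfiles <- function(fj, dsTotal, ftTotal) {
    new("ExpressionProfiles", fj = as.numeric(fj),
        dsTotal = as.numeric(dsTotal), ftTotal = as.numeric(ftTotal))
}

#' Phosphorylation state of the cell row
#'
#' Per-cell concentrations of phosphorylated Ft and phosphorylated Ds, the
#' only dynamical variables of the cell-intrinsic kinetics. Unphosphorylated
#' levels are derived by conservation (total minus phosphorylated), never
#' stored. Conservation bounds (0 <= phosphorylated <= total) are checked
#' against a profile object by the operations that consume a state, since
#' the state alone does not know the totals.
#'
#' @slot ftP numeric vector, phosphorylated Ft per cell.
#' @slot dsP numeric vector, phosphorylated Ds per cell.
#'
#' @seealso [phosphoState()], [randomInitialState()], [steadyStatePhospho()]
#' @export
setClass("PhosphoState", representation(ftP = "numeric", dsP = "numeric"))

setValidity("PhosphoState", function(object) {
    msgs <- c(
        if (length(object@ftP) != length(object@dsP))
            "'ftP' and 'dsP' must have equal length",
        if (anyNA(object@ftP) || anyNA(object@dsP))
            "state must not contain NA",
        if (any(object@ftP < 0) || any(object@dsP < 0))
            "phosphorylated levels must be non-negative"
    )
    if (length(msgs)) msgs else TRUE
})

#' Construct a phosphorylation state
#' @param ftP,dsP numeric vectors of equal length: per-cell phosphorylated
#'   Ft and Ds.
#' @return a validated \linkS4class{PhosphoState}.
#' @export
phosphoState <- function(ftP, dsP) {
    new("PhosphoState", ftP = as.numeric(ftP), dsP = as.numeric(dsP))
}

#' Heterodimer concentrations at interior edges
#'
#' Steady-state Ft-Ds heterodimer concentration at each interior edge
#' (edge j joins cells j and j+1), resolved into the two binding
#' orientations possible at an edge: unphosphorylated Ds of the
#' proximal-side cell bound to phosphorylated Ft of the distal-side cell
#' (\code{cOrientDsDistal}), and phosphorylated Ft of the proximal-side
#' cell bound to unphosphorylated Ds of the distal-side cell
#' (\code{cOrientFtDistal}). The two components sum to the total.
#'
#' @slot cTotal numeric vector of length nCells - 1.
#' @slot cOrientDsDistal,cOrientFtDistal numeric vectors, the two
#'   orientation components.
#'
#' @seealso [edgeSteadyState()]
#' @export
setClass("EdgeState",
    representation(cTotal = "numeric", cOrientDsDistal = "numeric",
                   cOrientFtDistal = "numeric")
)

setValidity("EdgeState", function(object) {
    n <- length(object@cTotal)
    msgs <- c(
        if (length(object@cOrientDsDistal) != n ||
            length(object@cOrientFtDistal) != n)
            "orientation components must match 'cTotal' in length",
        if (any(object@cTotal < -1e-12) ||
            any(object@cOrientDsDistal < -1e-12) ||
            any(object@cOrientFtDistal < -1e-12))
            "edge concentrations must be non-negative",
        if (max(abs(object@cTotal - object@cOrientDsDistal -
                    object@cOrientFtDistal)) >
            1e-9 * max(1, max(abs(object@cTotal))))
            "'cTotal' must equal the sum of the two orientation components"
    )
    if (length(msgs)) msgs else TRUE
})

#' Steady-state polarity decomposition for interior cells
#'
#' For each interior cell i (2 .. nCells - 1), the asymmetry of heterodimer
#' concentration between its distal and proximal edges, deltaC, decomposed
#' into a phosphorylated-Ft polarity term and an unphosphorylated-Ds
#' polarity term: deltaC = (kOn/kOff) * (pFt + mu * pDs). Each cell is
#' classified distal (deltaC above tolerance), proximal (below minus
#' tolerance) or unpolarized.
#'
#' @slot cells integer vector of interior cell indices.
#' @slot pFt,pDs numeric vectors, the two polarity terms.
#' @slot deltaC numeric vector, the weighted asymmetry.
#' @slot labels character vector of classifications.
#' @slot mu weight factor used.
#' @slot tol classification tolerance used.
#'
#' @seealso [polarityTerms()], [weightedAsymmetry()], [classifyPolarity()]
#' @export
setClass("PolarityResult",
    representation(cells = "integer", pFt = "numeric", pDs = "numeric",
                   deltaC = "numeric", labels = "character",
                   mu = "numeric", tol = "numeric")
)

setValidity("PolarityResult", function(object) {
    n <- length(object@cells)
    msgs <- c(
        if (length(object@pFt) != n || length(object@pDs) != n ||
            length(object@deltaC) != n || length(object@labels) != n)
            "all per-cell slots must have equal length",
        if (!all(object@labels %in% c("distal", "proximal", "unpolarized")))
            "labels must be 'distal', 'proximal' or 'unpolarized'"
    )
    if (length(msgs)) msgs else TRUE
})

#' Simulated time course of the model
#'
#' Time points and stored states of a forward-difference integration.
#' Rows of the state matrices correspond to stored time points (storage is
#' thinned: every \code{thin}-th step is kept, plus the final state);
#' columns to cells (or interior edges for \code{edges}). The convergence
#' check always uses the unthinned current state during integration.
#'
#' @slot times numeric vector, strictly increasing, starting at 0.
#' @slot ftP,dsP numeric matrices (time x cell) of phosphorylated levels.
#' @slot edges numeric matrix (time x edge) of heterodimer concentrations;
#'   zero columns wide when edges were not tracked.
#' @slot converged logical, whether the steady-state criterion was met.
#' @slot convergenceTime numeric, time of first criterion satisfaction
#'   (NA if never).
#' @slot profiles the \linkS4class{ExpressionProfiles} used.
#' @slot params the \linkS4class{ModelParameters} used.
#'
#' @seealso [integratePhospho()], [integrateEdges()], [checkSteady()]
#' @export
setClass("Trajectory",
    representation(times = "numeric", ftP = "matrix", dsP = "matrix",
                   edges = "matrix", converged = "logical",
                   convergenceTime = "numeric",
                   profiles = "ExpressionProfiles",
                   params = "ModelParameters")
)

setValidity("Trajectory", function(object) {
    msgs <- c(
        if (length(object@times) == 0L)
            "trajectory must contain at least one time point",
        if (length(object@times) && object@times[1L] != 0)
            "trajectory must start at time 0",
        if (length(object@times) > 1L && any(diff(object@times) <= 0))
            "'times' must be strictly increasing",
        if (nrow(object@ftP) != length(object@times) ||
            nrow(object@dsP) != length(object@times))
            "state matrices must have one row per time point",
        if (any(object@ftP < 0) || any(object@dsP < 0))
            "stored states must be non-negative"
    )
    if (length(msgs)) msgs else TRUE
})

.PERTURBATION_KINDS <- c("wild_type", "flatten_fj", "flatten_ds",
                         "flatten_both", "fj_ft_dead", "fj_ds_dead")

#' In-silico perturbation specification
#'
#' Describes one of the model's genetic experiments: the unperturbed wild
#' type, uniform overexpression of Fj and/or Ds (gradient flattening), or
#' a kinase-dead Fj that has lost activity against one substrate
#' (\code{fj_ft_dead}: no phosphorylation of Ft; \code{fj_ds_dead}: no
#' phosphorylation of Ds).
#'
#' @slot kind one of \code{wild_type}, \code{flatten_fj}, \code{flatten_ds},
#'   \code{flatten_both}, \code{fj_ft_dead}, \code{fj_ds_dead}.
#' @slot flattenLevel uniform level used for overexpression; \code{NA}
#'   means "use the wild-type profile maximum".
#' @slot overrides named list of \linkS4class{ModelParameters} overrides
#'   (e.g. \code{list(mu = 10)}).
#'
#' @seealso [perturbationSpec()], [applyPerturbation()], [runExperiment()]
#' @export
setClass("PerturbationSpec",
    representation(kind = "character", flattenLevel = "numeric",
                   overrides = "list")
)

setValidity("PerturbationSpec", function(object) {
    msgs <- c(
        if (length(object@kind) != 1L ||
            !object@kind %in% .PERTURBATION_KINDS)
            paste0("'kind' must be one of: ",
                   paste(.PERTURBATION_KINDS, collapse = ", ")),
        if (length(object@flattenLevel) != 1L)
            "'flattenLevel' must be a single number (NA for profile maximum)",
        if (!is.na(object@flattenLevel) && object@flattenLevel < 0)
            "'flattenLevel' must be non-negative",
        if (length(object@overrides) &&
            (is.null(names(object@overrides)) ||
             any(!nzchar(names(object@overrides)))))
            "'overrides' must be a named list"
    )
    if (length(msgs)) msgs else TRUE
})

#' Construct a perturbation specification
#' @param kind perturbation kind; see \linkS4class{PerturbationSpec}.
#' @param flattenLevel uniform overexpression level for the flatten kinds;
#'   \code{NA} (default) uses the wild-type profile maximum.
#' @param overrides named list of parameter overrides.
#' @return a validated \linkS4class{PerturbationSpec}.
#' @examples
#' perturbationSpec("flatten_fj")
#' perturbationSpec("wild_type", overrides = list(mu = 10))
#' @export
perturbationSpec <- function(kind = "wild_type", flattenLevel = NA_real_,
                             overrides = list()) {
    new("PerturbationSpec", kind = kind,
        flattenLevel = as.numeric(flattenLevel), overrides = overrides)
}

#' Result of one in-silico experiment
#'
#' Bundles everything one perturbation run produces: the effective
#' parameters and profiles after perturbation, the converged
#' phosphorylation state, the steady-state edge heterodimer concentrations,
#' the polarity decomposition and classification, and the run's seed and
#' convergence summary.
#'
#' @slot spec the \linkS4class{PerturbationSpec} that was run.
#' @slot params,profiles effective parameters/profiles after perturbation.
#' @slot finalState converged \linkS4class{PhosphoState}.
#' @slot edges \linkS4class{EdgeState} at the final state.
#' @slot polarity \linkS4class{PolarityResult} at the final state.
#' @slot converged,convergenceTime convergence summary of the integration.
#' @slot seed integer seed used for the random initial state.
#'
#' @seealso [runExperiment()], [writeResults()]
#' @export
setClass("ExperimentResult",
    representation(spec = "PerturbationSpec", params = "ModelParameters",
                   profiles = "ExpressionProfiles",
                   finalState = "PhosphoState", edges = "EdgeState",
                   polarity = "PolarityResult", converged = "logical",
                   convergenceTime = "numeric", seed = "integer")
)

#' Full run configuration
#'
#' A flat, serializable description of one simulation run: model
#' parameters, profile endpoints, integration settings, the perturbation
#' to apply, the seed, and an output directory. Round-trips losslessly
#' through the YAML config format of [readRunConfig()] /
#' [writeRunConfig()].
#'
#' @slot params \linkS4class{ModelParameters}.
#' @slot fjProximal,fjDistal endpoints of the linear Fj activity profile.
#' @slot dsProximal,dsDistal endpoints of the linear total-Ds profile.
#' @slot ftLevel uniform total-Ft level.
#' @slot dt,tMax,tol forward-difference step, time horizon, and steady-state
#'   tolerance (max absolute rate).
#' @slot thin store every thin-th integration step.
#' @slot classifyTol tolerance for polarity classification.
#' @slot perturbation \linkS4class{PerturbationSpec}.
#' @slot seed integer seed for the random initial state.
#' @slot outdir output directory for [writeResults()].
#'
#' @seealso [runConfig()], [readRunConfig()]
#' @export
setClass("RunConfig",
    representation(params = "ModelParameters",
                   fjProximal = "numeric", fjDistal = "numeric",
                   dsProximal = "numeric", dsDistal = "numeric",
                   ftLevel = "numeric",
                   dt = "numeric", tMax = "numeric", tol = "numeric",
                   thin = "integer", classifyTol = "numeric",
                   perturbation = "PerturbationSpec",
                   seed = "integer", outdir = "character")
)

setValidity("RunConfig", function(object) {
    msgs <- c(
        .checkScalar(object@dt, "dt", strict = TRUE),
        .checkScalar(object@tMax, "tMax", strict = TRUE),
        .checkScalar(object@tol, "tol", strict = TRUE),
        .checkScalar(object@classifyTol, "classifyTol", strict = TRUE),
        if (length(object@thin) != 1L || object@thin < 1L)
            "'thin' must be a positive integer",
        .checkScalar(object@fjProximal, "fjProximal"),
        .checkScalar(object@fjDistal, "fjDistal"),
        .checkScalar(object@dsProximal, "dsProximal"),
        .checkScalar(object@dsDistal, "dsDistal"),
        .checkScalar(object@ftLevel, "ftLevel")
    )
    if (length(msgs)) msgs else TRUE
})
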