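#' @include AllClasses.R model-core.R
NULL

# mass-action rates for the N-1 interior edges given per-cell ftP and dsU
.edgeRates <- function(edges, ftP, dsU, params) {
    n <- length(ftP)
    params@kOn * (ftP[-n] * dsU[-1L] + dsU[-n] * ftP[-1L]) -
        params@kOff * edges
}

#' Explicit-Euler stability limit of the model's kinetics
#'
#' All ODEs of the model are linear with per-cell relaxation rates
#' \code{alpha * H(fj) + beta} (phosphorylation, both species) and
#' \code{kOff} (edge heterodimer). The forward-difference scheme is stable
#' for \code{dt < 2 / max(rate)}; [integratePhospho()] refuses larger
#' steps.
#'
#' @param profiles \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters}.
#' @return the maximal stable step size (scalar).
#' @export
stabilityBound <- function(profiles, params) {
    a <- .phosRates(profiles, params)
    2 / max(a$aFt + params@betaFt, a$aDs + params@betaDs, params@kOff)
}

#' Forward-difference integration of the phosphorylation kinetics
#'
#' Integrates the per-cell phosphorylation ODEs with the explicit Euler
#' update \code{x <- x + dt * rate(x)}, optionally carrying the edge
#' heterodimer concentrations along with the same scheme. Integration
#' stops early once the maximum absolute rate over all cells (and tracked
#' edges) drops below \code{tol}; otherwise it runs to \code{tMax} and the
#' returned trajectory is flagged unconverged. Every \code{thin}-th step is
#' stored (plus the final state); the convergence check uses the unthinned
#' current state.
#'
#' After the criterion first holds, integration continues for a settling
#' phase of \code{settle} further relaxation times of the slowest mode
#' (still capped by \code{tMax}), which parks the final state at the
#' floating-point fixed point of the kinetics. Downstream algebraic
#' identities — exact loss of asymmetry under doubly flattened gradients,
#' exactly unpolarized kinase-dead tissue — then hold at the final state
#' to near machine precision instead of being blurred by the stopping
#' residual.
#'
#' @param initial initial \linkS4class{PhosphoState}.
#' @param profiles \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters}.
#' @param dt time step; must be below [stabilityBound()].
#' @param tMax time horizon.
#' @param tol steady-state tolerance on the maximum absolute rate.
#' @param thin store every \code{thin}-th step.
#' @param trackEdges logical; also integrate the edge heterodimer ODEs.
#' @param initialEdges initial edge concentrations (length nCells - 1);
#'   defaults to the edge steady state of \code{initial}.
#' @param settle length of the post-convergence settling phase, in units
#'   of the slowest relaxation time; 0 disables it.
#' @return a \linkS4class{Trajectory}.
#' @examples
#' cfg <- defaultWildtypeConfig()
#' tr <- integratePhospho(randomInitialState(cfg$profiles, 1),
#'                        cfg$profiles, cfg$params)
#' isConverged(tr)
#' @export
integratePhospho <- function(initial, profiles, params, dt = 0.1,
                             tMax = 1000, tol = 1e-12, thin = 10L,
                             trackEdges = FALSE, initialEdges = NULL,
                             settle = 30) {
    .checkConservation(initial, profiles, "initial state")
    if (!is.finite(dt) || dt <= 0 || !is.finite(tMax) || tMax <= 0 ||
        !is.finite(tol) || tol <= 0)
        stop("'dt', 'tMax' and 'tol' must be positive")
    bound <- stabilityBound(profiles, params)
    if (dt >= bound)
        stop(sprintf(
            "stability violation: dt = %g >= explicit-Euler limit %g",
            dt, bound))
    thin <- max(1L, as.integer(thin))

    n <- nCells(profiles)
    ftP <- initial@ftP
    dsP <- initial@dsP
    edges <- NULL
    if (trackEdges) {
        edges <- if (is.null(initialEdges)) {
            edgeSteadyState(initial, profiles, params)@cTotal
        } else {
            if (length(initialEdges) != n - 1L)
                stop("'initialEdges' must have length nCells - 1")
            as.numeric(initialEdges)
        }
    }

    nSteps <- ceiling(tMax / dt)
    cap <- nSteps %/% thin + 4L
    times <- numeric(cap)
    ftStore <- matrix(0, cap, n)
    dsStore <- matrix(0, cap, n)
    edgeStore <- matrix(0, cap, if (trackEdges) n - 1L else 0L)
    nStored <- 0L
    store <- function(t) {
        nStored <<- nStored + 1L
        times[nStored] <<- t
        ftStore[nStored, ] <<- ftP
        dsStore[nStored, ] <<- dsP
        if (trackEdges) edgeStore[nStored, ] <<- edges
    }

    a <- .phosRates(profiles, params)
    lambdaMin <- min(a$aFt + params@betaFt, a$aDs + params@betaDs,
                     if (trackEdges) params@kOff else Inf)
    settleSteps <- if (settle > 0)
        as.integer(ceiling(settle / lambdaMin / dt)) else 0L
    converged <- FALSE
    convergenceTime <- NA_real_
    settleLeft <- -1L   # countdown once the criterion has triggered
    tCur <- 0
    store(0)
    for (k in seq_len(nSteps)) {
        dFt <- a$aFt * (profiles@ftTotal - ftP) - params@betaFt * ftP
        dDs <- a$aDs * (profiles@dsTotal - dsP) - params@betaDs * dsP
        if (trackEdges)
            dE <- .edgeRates(edges, ftP, profiles@dsTotal - dsP, params)
        if (!converged) {
            maxRate <- max(abs(dFt), abs(dDs))
            if (trackEdges) maxRate <- max(maxRate, abs(dE))
            if (maxRate < tol) {
                converged <- TRUE
                convergenceTime <- (k - 1L) * dt
                settleLeft <- settleSteps
                if (times[nStored] < convergenceTime)
                    store(convergenceTime)
            }
        }
        if (converged) {
            if (settleLeft <= 0L) break
            settleLeft <- settleLeft - 1L
        }
        ftP <- ftP + dt * dFt
        dsP <- dsP + dt * dDs
        if (trackEdges) edges <- edges + dt * dE
        if (any(!is.finite(ftP)) || any(!is.finite(dsP)) ||
            (trackEdges && any(!is.finite(edges))))
            stop("integration failure: non-finite state at t = ", k * dt)
        tCur <- k * dt
        if (k %% thin == 0L || k == nSteps) store(tCur)
    }
    if (times[nStored] < tCur) store(tCur)
    if (!converged) {
        dFt <- a$aFt * (profiles@ftTotal - ftP) - params@betaFt * ftP
        dDs <- a$aDs * (profiles@dsTotal - dsP) - params@betaDs * dsP
        maxRate <- max(abs(dFt), abs(dDs))
        if (trackEdges)
            maxRate <- max(maxRate, abs(
                .edgeRates(edges, ftP, profiles@dsTotal - dsP, params)))
        if (maxRate < tol) {
            converged <- TRUE
            convergenceTime <- nSteps * dt
        }
    }
    keep <- seq_len(nStored)
    new("Trajectory", times = times[keep],
        ftP = ftStore[keep, , drop = FALSE],
        dsP = dsStore[keep, , drop = FALSE],
        edges = edgeStore[keep, , drop = FALSE],
        converged = converged, convergenceTime = convergenceTime,
        profiles = profiles, params = params)
}

#' Forward-difference integration of the edge heterodimer kinetics
#'
#' Integrates \code{dC/dt = kOn (FtP_i DsU_{i+1} + DsU_i FtP_{i+1}) -
#' kOff C} for every interior edge along a stored phosphorylation
#' trajectory, holding the phosphorylation state piecewise constant at its
#' most recent stored value. When the phosphorylation state is at steady
#' state this relaxes exactly (up to Euler error) onto
#' [edgeSteadyState()] of that state.
#'
#' @param trajectory a \linkS4class{Trajectory} from [integratePhospho()].
#' @param params \linkS4class{ModelParameters}; defaults to the
#'   trajectory's own.
#' @param initialEdges numeric vector of length nCells - 1, edge
#'   concentrations at time 0.
#' @param dt Euler substep within each stored interval.
#' @return a copy of \code{trajectory} whose \code{edges} slot holds the
#'   edge concentrations at each stored time.
#' @export
integrateEdges <- function(trajectory, params = trajectory@params,
                           initialEdges, dt = 0.1) {
    profiles <- trajectory@profiles
    n <- nCells(profiles)
    if (length(initialEdges) != n - 1L)
        stop("'initialEdges' must have length nCells - 1")
    if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
    if (dt >= 2 / params@kOff)
        stop(sprintf(
            "stability violation: dt = %g >= explicit-Euler limit %g",
            dt, 2 / params@kOff))
    times <- trajectory@times
    edges <- as.numeric(initialEdges)
    out <- matrix(0, length(times), n - 1L)
    out[1L, ] <- edges
    for (j in seq_len(length(times) - 1L)) {
        ftP <- trajectory@ftP[j, ]
        dsU <- profiles@dsTotal - trajectory@dsP[j, ]
        span <- times[j + 1L] - times[j]
        m <- max(1L, round(span / dt))
        h <- span / m
        for (s in seq_len(m)) {
            dE <- .edgeRates(edges, ftP, dsU, params)
            edges <- edges + h * dE
            if (any(!is.finite(edges)))
                stop("integration failure: non-finite edge state")
        }
        out[j + 1L, ] <- edges
    }
    res <- trajectory
    res@edges <- out
    res
}

#' Locate the first stored steady state of a trajectory
#'
#' Applies the steady-state criterion (maximum absolute rate over all
#' cells, species, and tracked edges below \code{tol}) to every stored
#' state and reports the earliest time it holds.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param tol tolerance on the maximum absolute rate.
#' @return list with elements \code{steady} (logical), \code{index}
#'   (earliest stored index satisfying the criterion, NA if none) and
#'   \code{time} (the corresponding time, NA if none).
#' @export
checkSteady <- function(trajectory, tol = 1e-8) {
    if (!is.finite(tol) || tol <= 0) stop("'tol' must be positive")
    profiles <- trajectory@profiles
    params <- trajectory@params
    a <- .phosRates(profiles, params)
    hasEdges <- ncol(trajectory@edges) > 0L
    for (j in seq_along(trajectory@times)) {
        ftP <- trajectory@ftP[j, ]
        dsP <- trajectory@dsP[j, ]
        dFt <- a$aFt * (profiles@ftTotal - ftP) - params@betaFt * ftP
        dDs <- a$aDs * (profiles@dsTotal - dsP) - params@betaDs * dsP
        maxRate <- max(abs(dFt), abs(dDs))
        if (hasEdges)
            maxRate <- max(maxRate, abs(.edgeRates(
                trajectory@edges[j, ], ftP, profiles@dsTotal - dsP,
                params)))
        if (maxRate < tol)
            return(list(steady = TRUE, index = j,
                        time = trajectory@times[j]))
    }
    list(steady = FALSE, index = NA_integer_, time = NA_real_)
}
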