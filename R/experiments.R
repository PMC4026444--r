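#' @include AllClasses.R dynamics.R heterodimer.R synthetic-data.R
NULL

.overridableParams <- c("alphaFt", "betaFt", "alphaDs", "betaDs",
                        "hillN", "hillK", "kOn", "kOff", "mu")

#' Apply an in-silico perturbation to profiles and parameters
#'
#' Gradient flattening replaces the corresponding profile with a uniform
#' one at \code{flattenLevel} (defaulting to the wild-type profile
#' maximum, i.e. uniform overexpression at the gradient's peak); the
#' kinase-dead mutants set the phosphorylation rate of the respective
#' substrate to zero. Parameter overrides (e.g. \code{mu}) are applied
#' last. Inputs are never mutated.
#'
#' @param profiles wild-type \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters}.
#' @param spec a \linkS4class{PerturbationSpec}.
#' @return list with the perturbed \code{profiles} and \code{params}.
#' @examples
#' cfg <- defaultWildtypeConfig()
#' flat <- applyPerturbation(cfg$profiles, cfg$params,
#'                           perturbationSpec("flatten_fj"))
#' fjProfile(flat$profiles)  # uniform at the wild-type maximum, 1
#' @export
applyPerturbation <- function(profiles, params, spec) {
    validObject(spec)
    n <- nCells(profiles)
    kind <- spec@kind
    level <- function(profile) {
        if (is.na(spec@flattenLevel)) max(profile) else spec@flattenLevel
    }
    if (kind %in% c("flatten_fj", "flatten_both"))
        profiles@fj <- uniformProfile(n, level(profiles@fj))
    if (kind %in% c("flatten_ds", "flatten_both"))
        profiles@dsTotal <- uniformProfile(n, level(profiles@dsTotal))
    if (kind == "fj_ft_dead") params@alphaFt <- 0
    if (kind == "fj_ds_dead") params@alphaDs <- 0
    for (nm in names(spec@overrides)) {
        if (!nm %in% .overridableParams)
            stop("unknown parameter override: '", nm, "'")
        slot(params, nm) <- as.numeric(spec@overrides[[nm]])
    }
    validObject(params)
    validObject(profiles)
    list(profiles = profiles, params = params)
}

#' Run one in-silico experiment to steady state
#'
#' Builds the wild-type profiles from the configuration, applies the
#' perturbation, draws a seeded uniform-random initial phosphorylation
#' state, integrates the phosphorylation and edge heterodimer kinetics by
#' the forward-difference scheme until the steady-state criterion is met,
#' and computes the edge concentrations, the polarity decomposition and
#' the per-cell classification at the final state. Deterministic given
#' (config, spec, seed). A run that fails to converge within the time
#' horizon still reports its polarity, with a warning.
#'
#' @param spec a \linkS4class{PerturbationSpec} (or its kind as a string).
#' @param config a \linkS4class{RunConfig}; default [defaultRunConfig()].
#' @param seed integer seed for the random initial state; defaults to the
#'   config's seed.
#' @return an \linkS4class{ExperimentResult}.
#' @examples
#' res <- runExperiment("wild_type", seed = 1)
#' polarityLabels(res)
#' @export
runExperiment <- function(spec = perturbationSpec("wild_type"),
                          config = defaultRunConfig(),
                          seed = config@seed) {
    if (is.character(spec)) spec <- perturbationSpec(spec)
    validObject(config)
    wt <- expressionProfiles(
        fj = linearProfile(nCells(config), config@fjProximal,
                           config@fjDistal),
        dsTotal = linearProfile(nCells(config), config@dsProximal,
                                config@dsDistal),
        ftTotal = uniformProfile(nCells(config), config@ftLevel))
    pert <- applyPerturbation(wt, config@params, spec)
    initial <- randomInitialState(pert$profiles, seed)
    traj <- integratePhospho(initial, pert$profiles, pert$params,
                             dt = config@dt, tMax = config@tMax,
                             tol = config@tol, thin = config@thin,
                             trackEdges = TRUE)
    if (!traj@converged)
        warning("run did not reach the steady-state criterion by tMax = ",
                config@tMax, "; polarity reported at the final state")
    k <- length(traj@times)
    final <- phosphoState(traj@ftP[k, ], traj@dsP[k, ])
    new("ExperimentResult", spec = spec, params = pert$params,
        profiles = pert$profiles, finalState = final,
        edges = edgeSteadyState(final, pert$profiles, pert$params),
        polarity = polarityResult(final, pert$profiles, pert$params,
                                  tol = config@classifyTol),
        converged = traj@converged,
        convergenceTime = traj@convergenceTime,
        seed = as.integer(seed))
}

#' Sweep the weight factor mu over one steady state
#'
#' The phosphorylation dynamics do not involve mu, so a single wild-type
#' steady state is computed and the weighted asymmetry is re-evaluated for
#' each mu value. Rows are ordered by mu, then cell.
#'
#' @param muValues non-negative numeric vector of weight factors.
#' @param config a \linkS4class{RunConfig}.
#' @param seed integer seed for the underlying wild-type run.
#' @return data.frame with columns \code{mu}, \code{cell}, \code{delta_c}
#'   and \code{label}.
#' @examples
#' sw <- muSweep(c(0.1, 1, 10), seed = 1)
#' head(sw)
#' @export
muSweep <- function(muValues, config = defaultRunConfig(),
                    seed = config@seed) {
    if (any(!is.finite(muValues)) || any(muValues < 0))
        stop("'muValues' must be non-negative")
    base <- runExperiment(perturbationSpec("wild_type"), config, seed)
    muValues <- sort(muValues)
    rows <- lapply(muValues, function(m) {
        params <- base@params
        params@mu <- m
        dc <- weightedAsymmetry(base@finalState, base@profiles, params)
        data.frame(mu = m, cell = as.integer(names(dc)), delta_c = dc,
                   label = classifyPolarity(dc, config@classifyTol),
                   row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Parameter-sensitivity sweep of the wild-type classification
#'
#' Re-runs the wild-type experiment at each point of a parameter grid and
#' reports the fraction of interior cells classified distal. In
#' one-at-a-time mode (default) each listed parameter is varied alone with
#' all others at their configured values; in cartesian mode the full
#' product grid is run. An empty grid yields the single default point.
#'
#' Parameter changes rescale the magnitude of the asymmetry by orders of
#' magnitude (a Hill coefficient of 4 against activities far below K
#' crushes every concentration), while the robustness question is about
#' the direction of polarity. Sweep points are therefore classified
#' relative to the point's own asymmetry scale
#' (\code{classifyTol * max(abs(deltaC))}), with an absolute floor of
#' 1e-12 — two orders of magnitude above the noise that settled
#' integrations (see [integratePhospho()]) leave in \code{deltaC} — so
#' that a tissue whose asymmetry is pure numerical residue (for example
#' \code{alphaFt = 0}) is reported as fraction 0, not as noise-signed
#' labels.
#'
#' @param paramGrid named list mapping parameter names (see
#'   \linkS4class{ModelParameters} slots) to value vectors.
#' @param config a \linkS4class{RunConfig}.
#' @param seed integer seed shared by all runs.
#' @param mode \code{"oat"} (one-at-a-time) or \code{"cartesian"}.
#' @return data.frame, sorted by parameter then value: columns
#'   \code{parameter}, \code{value}, \code{fraction_distal} (oat mode) or
#'   one column per parameter plus \code{fraction_distal} (cartesian).
#' @examples
#' sensitivitySweep(list(hillN = c(1, 2, 4)), seed = 1)
#' @export
sensitivitySweep <- function(paramGrid = list(),
                             config = defaultRunConfig(),
                             seed = config@seed,
                             mode = c("oat", "cartesian")) {
    mode <- match.arg(mode)
    bad <- setdiff(names(paramGrid), .overridableParams)
    if (length(bad))
        stop("invalid parameter name(s): ", paste(bad, collapse = ", "))
    fracDistal <- function(overrides) {
        res <- runExperiment(
            perturbationSpec("wild_type", overrides = overrides),
            config, seed)
        dc <- res@polarity@deltaC
        tolPoint <- max(1e-12, config@classifyTol * max(abs(dc)))
        mean(classifyPolarity(dc, tolPoint) == "distal")
    }
    if (!length(paramGrid)) {
        return(data.frame(parameter = "(default)", value = NA_real_,
                          fraction_distal = fracDistal(list())))
    }
    if (mode == "oat") {
        rows <- lapply(sort(names(paramGrid)), function(nm) {
            vals <- sort(paramGrid[[nm]])
            data.frame(parameter = nm, value = vals,
                       fraction_distal = vapply(
                           vals,
                           function(v) fracDistal(stats::setNames(
                               list(v), nm)),
                           numeric(1)))
        })
        do.call(rbind, rows)
    } else {
        grid <- expand.grid(paramGrid[sort(names(paramGrid))],
                            KEEP.OUT.ATTRS = FALSE)
        grid <- grid[do.call(order, grid), , drop = FALSE]
        grid$fraction_distal <- vapply(
            seq_len(nrow(grid)),
            function(r) fracDistal(as.list(grid[r,
                setdiff(names(grid), "fraction_distal"), drop = FALSE])),
            numeric(1))
        rownames(grid) <- NULL
        grid
    }
}
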