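#' @include AllClasses.R
NULL

#' Linear per-cell profile
#'
#' Arithmetic sequence from a proximal value (cell 1) to a distal value
#' (cell \code{nCells}), inclusive of both endpoints. Graded tissue-level
#' expression along the proximo-distal axis is modelled this way.
#'
#' @param nCells number of cells (>= 3).
#' @param proximalValue,distalValue non-negative endpoint values.
#' @return numeric vector of length \code{nCells}.
#' @examples
#' linearProfile(3, 0, 1)  # 0, 0.5, 1
#' @export
linearProfile <- function(nCells, proximalValue, distalValue) {
    if (length(nCells) != 1L || is.na(nCells) || nCells < 3L)
        stop("'nCells' must be a single integer >= 3")
    if (proximalValue < 0 || distalValue < 0)
        stop("profile values must be non-negative")
    seq(proximalValue, distalValue, length.out = as.integer(nCells))
}

#' Uniform per-cell profile
#'
#' Constant vector; used for total Ft (the same in all cells) and for
#' uniform-overexpression perturbations.
#'
#' @param nCells number of cells (>= 3).
#' @param value non-negative level.
#' @return numeric vector of length \code{nCells}.
#' @export
uniformProfile <- function(nCells, value) {
    if (length(nCells) != 1L || is.na(nCells) || nCells < 3L)
        stop("'nCells' must be a single integer >= 3")
    if (length(value) != 1L || is.na(value) || value < 0)
        stop("'value' must be a single non-negative number")
    rep(as.numeric(value), as.integer(nCells))
}

#' Seeded random initial phosphorylation state
#'
#' Draws each cell's initial phosphorylated Ft uniformly from
#' (0, ftTotal[i]) and phosphorylated Ds from (0, dsTotal[i]), so any draw
#' satisfies the conservation bounds. The caller's RNG state is left
#' untouched; the same (profiles, seed) pair always yields the identical
#' state.
#'
#' @param profiles \linkS4class{ExpressionProfiles}.
#' @param seed integer seed.
#' @return a \linkS4class{PhosphoState}.
#' @examples
#' cfg <- defaultWildtypeConfig()
#' identical(randomInitialState(cfg$profiles, 7),
#'           randomInitialState(cfg$profiles, 7))
#' @export
randomInitialState <- function(profiles, seed) {
    n <- nCells(profiles)
    rng <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rng))
        assign(".Random.seed", rng, envir = globalenv()))
    set.seed(as.integer(seed))
    phosphoState(ftP = stats::runif(n) * profiles@ftTotal,
                 dsP = stats::runif(n) * profiles@dsTotal)
}

#' Default wild-type model configuration
#'
#' The reference parameter set and expression profiles: a row of 20 cells;
#' symmetric phosphorylation kinetics alpha = 2, beta = 0.1 for both Ft and
#' Ds; Hill coupling n = 1, K = 250; heterodimer rates kOn = 1, kOff = 0.1;
#' mu = 1. Profiles are in normalized units (values scaled to the most
#' distal cell): Fj activity rises linearly as i/N so the distal-most cell
#' sits at exactly 1 and every cell is strictly positive; total Ds falls
#' linearly from 1.475 proximally to 1 distally (slope 0.5 over the row);
#' total Ft is 1 everywhere.
#'
#' @param nCells number of cells (default 20).
#' @param dsSlope proximo-distal drop of the total-Ds profile over the row;
#'   the proximal endpoint is \code{1 + dsSlope * (nCells - 1) / nCells}.
#' @return list with elements \code{params} (\linkS4class{ModelParameters})
#'   and \code{profiles} (\linkS4class{ExpressionProfiles}).
#' @examples
#' cfg <- defaultWildtypeConfig()
#' fjProfile(cfg$profiles)[20]  # 1: normalized to the most distal cell
#' @export
defaultWildtypeConfig <- function(nCells = 20L, dsSlope = 0.5) {
    params <- modelParameters(nCells = nCells)
    list(params = params,
         profiles = wildtypeProfiles(params, dsSlope = dsSlope))
}

#' Wild-type expression profiles for a given parameter set
#'
#' @param params \linkS4class{ModelParameters} (only \code{nCells} is used).
#' @param fjProximal,fjDistal endpoints of the Fj activity gradient;
#'   defaults 1/nCells and 1 (the i/N convention).
#' @param dsProximal,dsDistal endpoints of the total-Ds gradient; defaults
#'   implement a slope of \code{dsSlope} over the row with the distal cell
#'   at 1.
#' @param ftLevel uniform total Ft (default 1).
#' @param dsSlope see [defaultWildtypeConfig()].
#' @return an \linkS4class{ExpressionProfiles} object.
#' @export
wildtypeProfiles <- function(params,
                             fjProximal = 1 / nCells(params),
                             fjDistal = 1,
                             dsProximal = 1 +
                                 dsSlope * (nCells(params) - 1) /
                                 nCells(params),
                             dsDistal = 1, ftLevel = 1, dsSlope = 0.5) {
    n <- nCells(params)
    expressionProfiles(
        fj = linearProfile(n, fjProximal, fjDistal),
        dsTotal = linearProfile(n, dsProximal, dsDistal),
        ftTotal = uniformProfile(n, ftLevel))
}
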