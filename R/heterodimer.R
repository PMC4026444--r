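#' @include AllClasses.R model-core.R
NULL

#' Steady-state heterodimer concentration at each interior edge
#'
#' The only heterodimer modelled is phosphorylated Ft bound to
#' unphosphorylated Ds of the adjacent cell (the dominant binding pair;
#' the three weaker pairs are neglected). At the edge joining cells i and
#' i+1 the mass-action steady state is
#' \deqn{C^* = (k_{on}/k_{off}) (Ft^p_i Ds^u_{i+1} + Ds^u_i Ft^p_{i+1})}
#' with the two addends reported separately as the edge's two binding
#' orientations. No heterodimer exists at the two tissue-boundary faces,
#' which have no neighbouring cell. Heterodimer formation does not feed
#' back on the monomer pools.
#'
#' @param state a \linkS4class{PhosphoState}.
#' @param profiles matching \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters}.
#' @return an \linkS4class{EdgeState} with nCells - 1 edges.
#' @examples
#' cfg <- defaultWildtypeConfig()
#' ss <- steadyStatePhospho(cfg$profiles, cfg$params)
#' edgeTotals(edgeSteadyState(ss, cfg$profiles, cfg$params))
#' @export
edgeSteadyState <- function(state, profiles, params) {
    n <- nCells(profiles)
    if (n < 2L) stop("at least 2 cells are needed to form an edge")
    .checkConservation(state, profiles)
    u <- unphosphorylatedLevels(state, profiles)
    ratio <- params@kOn / params@kOff
    ftP <- state@ftP
    dsU <- u$dsU
    dsDistal <- ratio * dsU[-n] * ftP[-1L]   # Ds^u of cell j with Ft^p of j+1
    ftDistal <- ratio * ftP[-n] * dsU[-1L]   # Ft^p of cell j with Ds^u of j+1
    new("EdgeState", cTotal = dsDistal + ftDistal,
        cOrientDsDistal = dsDistal, cOrientFtDistal = ftDistal)
}

#' Polarity terms of the steady-state asymmetry decomposition
#'
#' The difference in heterodimer concentration between a cell's distal and
#' proximal edges splits algebraically into two terms: the cell's own
#' phosphorylated Ft engaged distally versus proximally,
#' \code{pFt[i] = FtP[i] * (DsU[i+1] - DsU[i-1])}, and its own
#' unphosphorylated Ds engaged distally versus proximally,
#' \code{pDs[i] = DsU[i] * (FtP[i+1] - FtP[i-1])}. Both are defined only
#' for interior cells (both neighbours required).
#'
#' @param state a \linkS4class{PhosphoState}.
#' @param profiles matching \linkS4class{ExpressionProfiles} (>= 3 cells).
#' @return list with numeric vectors \code{pFt}, \code{pDs} and the
#'   integer vector \code{cells} of interior cell indices.
#' @export
polarityTerms <- function(state, profiles) {
    n <- nCells(profiles)
    if (n < 3L) stop("polarity terms require at least 3 cells")
    .checkConservation(state, profiles)
    u <- unphosphorylatedLevels(state, profiles)
    i <- 2:(n - 1L)
    list(pFt = state@ftP[i] * (u$dsU[i + 1L] - u$dsU[i - 1L]),
         pDs = u$dsU[i] * (state@ftP[i + 1L] - state@ftP[i - 1L]),
         cells = i)
}

#' Weighted steady-state asymmetry per interior cell
#'
#' \deqn{\Delta C_i = (k_{on}/k_{off}) (P_{Ft,i} + \mu P_{Ds,i})}
#' The weight factor mu probes whether the two polarity mechanisms
#' contribute equally: at mu = 1 this reproduces exactly the difference of
#' adjacent [edgeSteadyState()] concentrations; mu > 1 boosts the
#' contribution of sub-cellular Ds polarity, mu < 1 that of Ft
#' phosphorylation polarity.
#'
#' @param state a \linkS4class{PhosphoState}.
#' @param profiles matching \linkS4class{ExpressionProfiles}.
#' @param params \linkS4class{ModelParameters} (uses kOn, kOff, mu).
#' @return numeric vector of asymmetries for interior cells, named by cell
#'   index.
#' @export
weightedAsymmetry <- function(state, profiles, params) {
    p <- polarityTerms(state, profiles)
    stats::setNames(
        params@kOn / params@kOff * (p$pFt + params@mu * p$pDs), p$cells)
}

#' Classify per-cell asymmetry
#'
#' A cell is distal when its asymmetry exceeds \code{tol}, proximal when
#' below \code{-tol}, and unpolarized otherwise. The default tolerance is
#' in normalized concentration units.
#'
#' @param deltaC numeric vector of per-cell asymmetries.
#' @param tol positive classification tolerance.
#' @return character vector of labels.
#' @examples
#' classifyPolarity(c(0.6, -2.64, 1e-12))
#' @export
classifyPolarity <- function(deltaC, tol = 1e-9) {
    if (!is.finite(tol) || tol <= 0) stop("'tol' must be positive")
    ifelse(deltaC > tol, "distal",
           ifelse(deltaC < -tol, "proximal", "unpolarized"))
}

#' Full polarity decomposition of a phosphorylation state
#'
#' Convenience wrapper combining [polarityTerms()], [weightedAsymmetry()]
#' and [classifyPolarity()] into one \linkS4class{PolarityResult}.
#'
#' @inheritParams weightedAsymmetry
#' @param tol classification tolerance, see [classifyPolarity()].
#' @return a \linkS4class{PolarityResult}.
#' @export
polarityResult <- function(state, profiles, params, tol = 1e-9) {
    p <- polarityTerms(state, profiles)
    dc <- params@kOn / params@kOff * (p$pFt + params@mu * p$pDs)
    new("PolarityResult", cells = as.integer(p$cells), pFt = p$pFt,
        pDs = p$pDs, deltaC = dc, labels = classifyPolarity(dc, tol),
        mu = params@mu, tol = tol)
}
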