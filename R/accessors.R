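#' @include AllGenerics.R AllClasses.R
NULL

#' @describeIn nCells cell count stored in the parameters.
#' @export
setMethod("nCells", "ModelParameters", function(x) x@nCells)

#' @describeIn nCells number of cells covered by the profiles.
#' @export
setMethod("nCells", "ExpressionProfiles", function(x) length(x@fj))

#' @describeIn nCells number of cells in the state.
#' @export
setMethod("nCells", "PhosphoState", function(x) length(x@ftP))

#' @describeIn nCells cell count of the configured model.
#' @export
setMethod("nCells", "RunConfig", function(x) x@params@nCells)

#' @describeIn fjProfile Fj activity vector of the profiles.
#' @export
setMethod("fjProfile", "ExpressionProfiles", function(x) x@fj)

#' @describeIn dsTotal total-Ds vector of the profiles.
#' @export
setMethod("dsTotal", "ExpressionProfiles", function(x) x@dsTotal)

#' @describeIn ftTotal total-Ft vector of the profiles.
#' @export
setMethod("ftTotal", "ExpressionProfiles", function(x) x@ftTotal)

#' @describeIn ftPhos phosphorylated Ft of the state.
#' @export
setMethod("ftPhos", "PhosphoState", function(x) x@ftP)

#' @describeIn dsPhos phosphorylated Ds of the state.
#' @export
setMethod("dsPhos", "PhosphoState", function(x) x@dsP)

#' @describeIn ftPhos final phosphorylated Ft of an experiment.
#' @export
setMethod("ftPhos", "ExperimentResult", function(x) x@finalState@ftP)

#' @describeIn dsPhos final phosphorylated Ds of an experiment.
#' @export
setMethod("dsPhos", "ExperimentResult", function(x) x@finalState@dsP)

#' @describeIn edgeTotals total heterodimer per interior edge.
#' @export
setMethod("edgeTotals", "EdgeState", function(x) x@cTotal)

#' @describeIn edgeTotals edge totals of an experiment's final state.
#' @export
setMethod("edgeTotals", "ExperimentResult", function(x) x@edges@cTotal)

#' @describeIn deltaC weighted asymmetry per interior cell.
#' @export
setMethod("deltaC", "PolarityResult", function(x) {
    stats::setNames(x@deltaC, x@cells)
})

#' @describeIn deltaC asymmetry of an experiment's final state.
#' @export
setMethod("deltaC", "ExperimentResult", function(x) deltaC(x@polarity))

#' @describeIn polarityLabels classification per interior cell.
#' @export
setMethod("polarityLabels", "PolarityResult", function(x) {
    stats::setNames(x@labels, x@cells)
})

#' @describeIn polarityLabels classification of an experiment's final state.
#' @export
setMethod("polarityLabels", "ExperimentResult", function(x) {
    polarityLabels(x@polarity)
})

#' @describeIn isConverged whether the trajectory met the steady criterion.
#' @export
setMethod("isConverged", "Trajectory", function(x) x@converged)

#' @describeIn isConverged whether the experiment's integration converged.
#' @export
setMethod("isConverged", "ExperimentResult", function(x) x@converged)

#' @describeIn convergenceTime first time the criterion held.
#' @export
setMethod("convergenceTime", "Trajectory", function(x) x@convergenceTime)

#' @describeIn convergenceTime convergence time of the experiment.
#' @export
setMethod("convergenceTime", "ExperimentResult", function(x) {
    x@convergenceTime
})

setMethod("show", "ModelParameters", function(object) {
    cat("ModelParameters:", object@nCells, "cells\n")
    cat(sprintf("  Ft phospho: alpha = %g, beta = %g\n",
                object@alphaFt, object@betaFt))
    cat(sprintf("  Ds phospho: alpha = %g, beta = %g\n",
                object@alphaDs, object@betaDs))
    cat(sprintf("  Hill: n = %g, K = %g\n", object@hillN, object@hillK))
    cat(sprintf("  heterodimer: kOn = %g, kOff = %g; mu = %g\n",
                object@kOn, object@kOff, object@mu))
})

setMethod("show", "ExpressionProfiles", function(object) {
    n <- nCells(object)
    cat("ExpressionProfiles:", n, "cells (proximal -> distal)\n")
    cat(sprintf("  fj:      %.4g .. %.4g\n", object@fj[1L], object@fj[n]))
    cat(sprintf("  dsTotal: %.4g .. %.4g\n",
                object@dsTotal[1L], object@dsTotal[n]))
    cat(sprintf("  ftTotal: %.4g .. %.4g\n",
                object@ftTotal[1L], object@ftTotal[n]))
})

setMethod("show", "PhosphoState", function(object) {
    cat("PhosphoState:", nCells(object), "cells\n")
    cat("  ftP range:", format(range(object@ftP), digits = 4), "\n")
    cat("  dsP range:", format(range(object@dsP), digits = 4), "\n")
})

setMethod("show", "EdgeState", function(object) {
    cat("EdgeState:", length(object@cTotal), "interior edges\n")
    cat("  cTotal range:", format(range(object@cTotal), digits = 4), "\n")
})

setMethod("show", "PolarityResult", function(object) {
    cat("PolarityResult:", length(object@cells), "interior cells (mu =",
        object@mu, ")\n")
    print(table(factor(object@labels,
                       levels = c("distal", "proximal", "unpolarized"))))
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", length(object@times), "stored time points, t in [0,",
        max(object@times), "]\n")
    cat("  converged:", object@converged,
        if (object@converged) sprintf("(t = %g)", object@convergenceTime)
        else "", "\n")
    if (ncol(object@edges)) cat("  edges tracked:", ncol(object@edges), "\n")
})

setMethod("show", "PerturbationSpec", function(object) {
    cat("PerturbationSpec:", object@kind)
    if (!is.na(object@flattenLevel))
        cat(" (flatten level", object@flattenLevel, ")")
    if (length(object@overrides))
        cat(" [overrides:",
            paste(names(object@overrides), unlist(object@overrides),
                  sep = "=", collapse = ", "), "]")
    cat("\n")
})

setMethod("show", "ExperimentResult", function(object) {
    cat("ExperimentResult:", object@spec@kind, "(seed", object@seed, ")\n")
    cat("  converged:", object@converged,
        if (object@converged) sprintf("at t = %g", object@convergenceTime)
        else "(hit time horizon)", "\n")
    labs <- table(factor(object@polarity@labels,
                         levels = c("distal", "proximal", "unpolarized")))
    cat("  interior cells:",
        paste(names(labs), labs, sep = ": ", collapse = ", "), "\n")
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig:", object@params@nCells, "cells;",
        object@perturbation@kind, "; seed", object@seed, "\n")
    cat(sprintf("  integration: dt = %g, tMax = %g, tol = %g\n",
                object@dt, object@tMax, object@tol))
})
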