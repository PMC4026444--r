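#' @include AllClasses.R synthetic-data.R
NULL

.CONFIG_KEYS <- c(
    n_cells = "nCells", alpha_ft = "alphaFt", beta_ft = "betaFt",
    alpha_ds = "alphaDs", beta_ds = "betaDs", hill_n = "hillN",
    hill_k = "hillK", k_on = "kOn", k_off = "kOff", mu = "mu",
    fj_proximal = "fjProximal", fj_distal = "fjDistal",
    ds_proximal = "dsProximal", ds_distal = "dsDistal",
    ft_level = "ftLevel", dt = "dt", t_max = "tMax", tol = "tol",
    thin = "thin", classify_tol = "classifyTol",
    perturbation = "kind", flatten_level = "flattenLevel",
    seed = "seed", outdir = "outdir")

#' Construct a run configuration
#'
#' All arguments default to the wild-type reference run: 20 cells,
#' symmetric kinetics, Fj activity rising linearly from 1/nCells to 1,
#' total Ds falling linearly from 1.475 to 1, uniform total Ft of 1,
#' forward-difference integration with dt = 0.1 up to tMax = 1000 (many
#' relaxation times of the slowest rate, beta = 0.1) with steady-state
#' tolerance 1e-12 on the maximum rate, followed by the integrator's
#' settling phase (see [integratePhospho()]).
#'
#' @param params \linkS4class{ModelParameters}.
#' @param fjProximal,fjDistal,dsProximal,dsDistal,ftLevel profile
#'   endpoints; see \linkS4class{RunConfig}.
#' @param dt,tMax,tol,thin integration settings.
#' @param classifyTol polarity classification tolerance.
#' @param perturbation a \linkS4class{PerturbationSpec} or its kind.
#' @param seed integer seed.
#' @param outdir output directory for [writeResults()].
#' @return a validated \linkS4class{RunConfig}.
#' @export
runConfig <- function(params = modelParameters(),
                      fjProximal = 1 / nCells(params), fjDistal = 1,
                      dsProximal = 1 + 0.5 * (nCells(params) - 1) /
                          nCells(params),
                      dsDistal = 1, ftLevel = 1,
                      dt = 0.1, tMax = 1000, tol = 1e-12, thin = 10L,
                      classifyTol = 1e-9,
                      perturbation = perturbationSpec("wild_type"),
                      seed = 1L, outdir = ".") {
    if (is.character(perturbation))
        perturbation <- perturbationSpec(perturbation)
    new("RunConfig", params = params,
        fjProximal = as.numeric(fjProximal),
        fjDistal = as.numeric(fjDistal),
        dsProximal = as.numeric(dsProximal),
        dsDistal = as.numeric(dsDistal),
        ftLevel = as.numeric(ftLevel),
        dt = as.numeric(dt), tMax = as.numeric(tMax),
        tol = as.numeric(tol), thin = as.integer(thin),
        classifyTol = as.numeric(classifyTol),
        perturbation = perturbation, seed = as.integer(seed),
        outdir = outdir)
}

#' @rdname runConfig
#' @export
defaultRunConfig <- function() runConfig()

#' Read a run configuration from a YAML file
#'
#' The file is a flat key-value YAML document; any key listed below may be
#' omitted, in which case its wild-type default applies. Unknown keys are
#' an error, so typos never pass silently. Keys: \code{n_cells},
#' \code{alpha_ft}, \code{beta_ft}, \code{alpha_ds}, \code{beta_ds},
#' \code{hill_n}, \code{hill_k}, \code{k_on}, \code{k_off}, \code{mu},
#' \code{fj_proximal}, \code{fj_distal}, \code{ds_proximal},
#' \code{ds_distal}, \code{ft_level}, \code{dt}, \code{t_max}, \code{tol},
#' \code{thin}, \code{classify_tol}, \code{perturbation},
#' \code{flatten_level}, \code{seed}, \code{outdir}.
#'
#' @param path path to the YAML file; an empty file yields the full
#'   default configuration.
#' @return a validated \linkS4class{RunConfig}.
#' @seealso [writeRunConfig()] for the lossless inverse.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) stop("config must be a YAML mapping")
    unknown <- setdiff(names(raw), names(.CONFIG_KEYS))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    bad <- names(raw)[!vapply(raw, function(v)
        length(v) == 1L && (is.numeric(v) || is.character(v)),
        logical(1))]
    if (length(bad))
        stop("config key(s) must be scalars: ", paste(bad, collapse = ", "))

    cfg <- defaultRunConfig()
    paramSlots <- c("nCells", "alphaFt", "betaFt", "alphaDs", "betaDs",
                    "hillN", "hillK", "kOn", "kOff", "mu")
    params <- cfg@params
    for (key in names(raw)) {
        slotName <- .CONFIG_KEYS[[key]]
        val <- raw[[key]]
        if (slotName %in% paramSlots) {
            slot(params, slotName) <-
                if (slotName == "nCells") as.integer(val)
                else as.numeric(val)
        } else if (slotName == "kind") {
            cfg@perturbation@kind <- as.character(val)
        } else if (slotName == "flattenLevel") {
            cfg@perturbation@flattenLevel <- as.numeric(val)
        } else if (slotName %in% c("seed", "thin")) {
            slot(cfg, slotName) <- as.integer(val)
        } else if (slotName == "outdir") {
            cfg@outdir <- as.character(val)
        } else {
            slot(cfg, slotName) <- as.numeric(val)
        }
    }
    validObject(params)
    cfg@params <- params
    # profile endpoints tied to nCells must track an overridden cell count
    if ("n_cells" %in% names(raw)) {
        n <- params@nCells
        if (!"fj_proximal" %in% names(raw)) cfg@fjProximal <- 1 / n
        if (!"ds_proximal" %in% names(raw))
            cfg@dsProximal <- 1 + 0.5 * (n - 1) / n
    }
    validObject(cfg@perturbation)
    validObject(cfg)
    cfg
}

#' Write a run configuration to a YAML file
#'
#' Writes every configuration key explicitly, so that
#' \code{readRunConfig(writeRunConfig(cfg, path))} reproduces \code{cfg}
#' exactly.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    validObject(config)
    p <- config@params
    out <- list(
        n_cells = p@nCells, alpha_ft = p@alphaFt, beta_ft = p@betaFt,
        alpha_ds = p@alphaDs, beta_ds = p@betaDs, hill_n = p@hillN,
        hill_k = p@hillK, k_on = p@kOn, k_off = p@kOff, mu = p@mu,
        fj_proximal = config@fjProximal, fj_distal = config@fjDistal,
        ds_proximal = config@dsProximal, ds_distal = config@dsDistal,
        ft_level = config@ftLevel, dt = config@dt, t_max = config@tMax,
        tol = config@tol, thin = config@thin,
        classify_tol = config@classifyTol,
        perturbation = config@perturbation@kind,
        seed = config@seed, outdir = config@outdir)
    if (!is.na(config@perturbation@flattenLevel))
        out$flatten_level <- config@perturbation@flattenLevel
    yaml::write_yaml(out, path, precision = 15L)
    invisible(path)
}
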