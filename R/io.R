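#' @include AllClasses.R experiments.R
NULL

.fmt9 <- function(x) {
    out <- vapply(x, function(v)
        if (is.na(v)) NA_character_ else sprintf("%.9g", v),
        character(1))
    out
}

#' Serialize an experiment result
#'
#' Writes three files into \code{outdir}: \code{cells.tsv} (one row per
#' cell: profiles, phosphorylation state, conservation-derived
#' unphosphorylated levels, polarity terms, asymmetry and label — the
#' polarity columns are empty for the two boundary cells, which lack a
#' neighbour on one side), \code{edges.tsv} (one row per interior edge
#' with the total heterodimer concentration and its two orientation
#' components) and \code{summary.json} (perturbation, seed, convergence,
#' label counts). Floats are printed at 9 significant digits; re-running
#' the same configuration and seed reproduces the files byte for byte.
#'
#' @param result an \linkS4class{ExperimentResult}.
#' @param outdir output directory, created if absent.
#' @return named character vector of the written paths, invisibly.
#' @export
writeResults <- function(result, outdir) {
    if (!dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    profiles <- result@profiles
    state <- result@finalState
    u <- unphosphorylatedLevels(state, profiles)
    n <- nCells(profiles)
    pol <- result@polarity
    full <- function(x, cells) replace(rep(NA_real_, n), cells, x)

    cells <- data.frame(
        cell_index = seq_len(n),
        fj = .fmt9(profiles@fj),
        ds_total = .fmt9(profiles@dsTotal),
        ft_p = .fmt9(state@ftP),
        ds_p = .fmt9(state@dsP),
        ft_u = .fmt9(u$ftU),
        ds_u = .fmt9(u$dsU),
        p_ft = .fmt9(full(pol@pFt, pol@cells)),
        p_ds = .fmt9(full(pol@pDs, pol@cells)),
        delta_c = .fmt9(full(pol@deltaC, pol@cells)),
        label = replace(rep(NA_character_, n), pol@cells, pol@labels))
    cellsPath <- file.path(outdir, "cells.tsv")
    utils::write.table(cells, cellsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")

    edges <- data.frame(
        edge_index = seq_len(n - 1L),
        proximal_cell = seq_len(n - 1L),
        distal_cell = 2:n,
        c_total = .fmt9(result@edges@cTotal),
        c_orient_ds_distal = .fmt9(result@edges@cOrientDsDistal),
        c_orient_ft_distal = .fmt9(result@edges@cOrientFtDistal))
    edgesPath <- file.path(outdir, "edges.tsv")
    utils::write.table(edges, edgesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")

    summaryPath <- file.path(outdir, "summary.json")
    jsonlite::write_json(list(
        perturbation = result@spec@kind,
        flatten_level = if (is.na(result@spec@flattenLevel)) NULL
                        else result@spec@flattenLevel,
        overrides = result@spec@overrides,
        seed = result@seed,
        converged = result@converged,
        convergence_time = if (is.na(result@convergenceTime)) NULL
                           else result@convergenceTime,
        label_counts = as.list(table(pol@labels))),
        summaryPath, auto_unbox = TRUE, digits = NA, null = "null")

    invisible(c(cells = cellsPath, edges = edgesPath,
                summary = summaryPath))
}

#' Read back a cells.tsv written by [writeResults()]
#'
#' @param path path to a \code{cells.tsv} file.
#' @return data.frame with numeric columns restored (empty polarity fields
#'   become \code{NA}).
#' @export
readCellsTable <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      na.strings = "", stringsAsFactors = FALSE)
}
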