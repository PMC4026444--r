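#' @include AllClasses.R experiments.R
NULL

#' @importFrom ggplot2 ggplot aes geom_polygon scale_fill_manual labs
#'   theme_minimal
NULL

# per-cell trapezoid vertices: left height = proximal-edge C, right
# height = distal-edge C; boundary cells are one-sided (their missing
# outer edge reuses the inner height, giving a flat-topped rectangle)
.trapezoidData <- function(result) {
    n <- nCells(result@profiles)
    C <- result@edges@cTotal
    left <- c(C[1L], C)        # proximal edge of cell i = edge i-1
    right <- c(C, C[n - 1L])   # distal edge of cell i = edge i
    pol <- rep("boundary", n)
    pol[result@polarity@cells] <- result@polarity@labels
    do.call(rbind, lapply(seq_len(n), function(i) {
        data.frame(cell = i,
                   x = c(i - 1, i, i, i - 1),
                   y = c(0, 0, right[i], left[i]),
                   label = pol[i])
    }))
}

#' Trapezoid plot of edge heterodimer concentrations
#'
#' One trapezoid per cell: the left side's height is the heterodimer
#' concentration at the cell's proximal edge, the right side's at its
#' distal edge, so a distally polarized cell reads as an ascending
#' trapezoid. The two boundary cells, which lack one neighbour, are drawn
#' one-sided. Cells are filled by their polarity classification.
#'
#' @param result an \linkS4class{ExperimentResult}.
#' @return a ggplot object.
#' @seealso [exportTrapezoidPlot()] to write the figure to a file.
#' @export
trapezoidPlot <- function(result) {
    df <- .trapezoidData(result)
    fills <- c(distal = "#2166ac", proximal = "#b2182b",
               unpolarized = "#bdbdbd", boundary = "#e0e0e0")
    ggplot(df, aes(x = x, y = y, group = cell, fill = label)) +
        geom_polygon(colour = "grey30", linewidth = 0.3) +
        scale_fill_manual(values = fills, name = "polarity") +
        labs(x = "cell (proximal to distal)",
             y = "Ft-Ds heterodimer concentration at edge",
             title = result@spec@kind) +
        theme_minimal()
}

#' Export a trapezoid plot to a figure file
#'
#' The output format follows the file extension: \code{.pdf} or
#' \code{.svg} for vector output, \code{.png} for raster.
#'
#' @param result an \linkS4class{ExperimentResult}.
#' @param path output path ending in \code{.pdf}, \code{.svg} or
#'   \code{.png}.
#' @param width,height figure size in inches.
#' @return \code{path}, invisibly.
#' @export
exportTrapezoidPlot <- function(result, path, width = 8, height = 3.5) {
    ext <- tolower(tools::file_ext(path))
    open <- switch(ext,
        pdf = function() grDevices::pdf(path, width = width,
                                        height = height),
        svg = function() grDevices::svg(path, width = width,
                                        height = height),
        png = function() grDevices::png(path, width = width * 100,
                                        height = height * 100, res = 100),
        stop("unknown figure extension: '", ext,
             "' (use pdf, svg or png)"))
    open()
    on.exit(grDevices::dev.off())
    print(trapezoidPlot(result))
    invisible(path)
}
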