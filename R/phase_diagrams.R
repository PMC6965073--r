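#' Two-parameter phase diagram of paced-cell behavior
#'
#' Classifies the paced cell's behavior on a grid of two normalized
#' parameter axes.  Each line along \code{axis1} is traversed in order
#' with warm-started initial conditions (the final state of each run seeds
#' the next), mirroring the sweep protocol; the first point of every line
#' is paced to convergence with a larger budget.
#'
#' @param params base \code{tp06_params}.
#' @param protocol pacing protocol (ignored for \code{axis2 = "CL"} grid
#'   values, which replace the cycle length).
#' @param axis1,values1 inner axis (swept with warm starts).
#' @param axis2,values2 outer axis; may be \code{"CL"} (ms).
#' @param n_beats per-point stimulus budget (convergence-stopped).
#' @param first_beats budget for the first point of each line.
#' @param both_directions if TRUE, each line is also traversed in reverse
#'   and points whose label differs are flagged \code{bistable}.
#' @param classify_opts passed to \code{\link{classify_behavior}}.
#' @return object of class \code{tp06_phase_diagram}: long data.frame
#'   \code{grid} (axis1, axis2, label, bistable) plus provenance.
#' @export
sweep_plane <- function(params, protocol, axis1, values1, axis2, values2,
                        n_beats = 15, first_beats = 60,
                        both_directions = FALSE, classify_opts = list()) {
  if (!(axis1 %in% .tp06_scale_names)) stop("unknown axis1: ", axis1)
  if (!(axis2 %in% c(.tp06_scale_names, "CL"))) stop("unknown axis2: ", axis2)
  run_line <- function(v2, v1s) {
    p2 <- if (axis2 == "CL") params else .with_axis(params, axis2, v2)
    proto <- if (axis2 == "CL") make_pacing(v2, protocol$amplitude,
                                            protocol$width) else protocol
    init <- NULL
    labs <- character(length(v1s))
    for (i in seq_along(v1s)) {
      pv <- .with_axis(p2, axis1, v1s[i])
      tr <- tryCatch(
        simulate_paced(pv, proto, init = init,
                       n_beats = if (i == 1) first_beats else n_beats,
                       stop = "converge"),
        error = function(e) NULL)
      if (is.null(tr)) { labs[i] <- "failed"; init <- NULL; next }
      labs[i] <- do.call(classify_behavior, c(list(tr), classify_opts))
      init <- tr$final_state
    }
    labs
  }
  rows <- list()
  for (v2 in values2) {
    fw <- run_line(v2, values1)
    bi <- rep(FALSE, length(values1))
    if (both_directions) {
      bw <- rev(run_line(v2, rev(values1)))
      bi <- fw != bw
    }
    rows[[length(rows) + 1]] <- data.frame(
      axis1 = values1, axis2 = v2, label = fw, bistable = bi)
  }
  structure(list(grid = do.call(rbind, rows),
                 axes = c(axis1, axis2),
                 variant = params$variant,
                 protocol = unclass(protocol)),
            class = "tp06_phase_diagram")
}

#' @export
print.tp06_phase_diagram <- function(x, ...) {
  cat("Phase diagram:", x$axes[1], "x", x$axes[2], "(",
      nrow(x$grid), "points )\n")
  print(table(x$grid$label))
  invisible(x)
}

#' Overlay non-paced bifurcation curves on a phase diagram
#'
#' Merges a paced-cell phase diagram with curves computed for the
#' non-paced cell (Hopf locus, spontaneous-oscillation onset/offset) on
#' the same axes, and reports containment statistics: the fraction of
#' SO-region grid points labeled RF, and agreement between the
#' local-response boundary and the Hopf curve.
#'
#' @param diagram a \code{tp06_phase_diagram}.
#' @param curves named list of data.frames with columns \code{axis1},
#'   \code{axis2} (e.g. \code{list(HB = ..., SO1 = ..., SO2 = ...)}).
#' @param so_region optional data.frame of grid points (axis1, axis2,
#'   so = logical) marking where SOs occur in the non-paced cell.
#' @return the diagram with \code{curves}, \code{so_region} and
#'   \code{stats} attached.
#' @export
overlay_bifurcation <- function(diagram, curves = list(), so_region = NULL) {
  stopifnot(inherits(diagram, "tp06_phase_diagram"))
  diagram$curves <- curves
  stats <- list()
  if (!is.null(so_region)) {
    g <- diagram$grid
    key <- function(d) paste(signif(d$axis1, 10), signif(d$axis2, 10))
    m <- match(key(so_region[so_region$so, , drop = FALSE]), key(g))
    m <- m[!is.na(m)]
    if (length(m))
      stats$so_in_rf <- mean(g$label[m] == "RF")
    diagram$so_region <- so_region
  }
  diagram$stats <- stats
  diagram
}

#' Export a phase diagram (and overlays) to CSV
#'
#' @param diagram a \code{tp06_phase_diagram}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
export_phase_diagram <- function(diagram, dir = ".", prefix = "phase") {
  stopifnot(inherits(diagram, "tp06_phase_diagram"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(prefix, "_grid.csv"))
  write.csv(diagram$grid, files[1], row.names = FALSE)
  for (nm in names(diagram$curves)) {
    f <- file.path(dir, paste0(prefix, "_curve_", nm, ".csv"))
    write.csv(diagram$curves[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
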