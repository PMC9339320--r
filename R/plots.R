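#' Plot mean genetic-gain trajectories
#'
#' One line per method of per-generation mean GEBV (or another metric
#' column) averaged over replicates.
#'
#' @param trajectories stacked trajectory data.frame as produced by
#'   [runReplicates()] (possibly rbind-ed across methods).
#' @param metric column to plot (default `"mean_gebv"`).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the generation x method matrix of plotted means.
#' @importFrom graphics matplot legend
#' @export
plotGainTrajectories <- function(trajectories, metric = "mean_gebv", ...) {
  agg <- stats::aggregate(trajectories[[metric]],
    by = list(generation = trajectories$generation,
              method = trajectories$method), FUN = mean)
  wide <- stats::reshape(agg, idvar = "generation", timevar = "method",
                         direction = "wide")
  wide <- wide[order(wide$generation), , drop = FALSE]
  m <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(m) <- sub("^x\\.", "", colnames(m))
  matplot(wide$generation, m, type = "b", pch = 19, lty = 1,
          xlab = "generation", ylab = metric, ...)
  legend("bottomright", legend = colnames(m), col = seq_len(ncol(m)),
         lty = 1, pch = 19, bty = "n")
  invisible(m)
}

#' Plot empirical CDFs of the present value of gains
#'
#' One ECDF per method of the replicate-level PV-of-GEBV criterion; a
#' curve lying to the right indicates stochastic dominance.
#'
#' @param trajectories stacked trajectory data.frame with columns
#'   `replicate`, `generation`, `method`, `pv`.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics plot lines legend
#' @export
plotPvEcdf <- function(trajectories, ...) {
  first <- trajectories[trajectories$generation == 1L, ]
  methods <- unique(first$method)
  rng <- range(first$pv)
  plot(NA, xlim = rng, ylim = c(0, 1), xlab = "PV of GEBV",
       ylab = "empirical CDF", ...)
  for (i in seq_along(methods)) {
    pv <- sort(first$pv[first$method == methods[i]])
    lines(pv, seq_along(pv) / length(pv), type = "s", col = i)
  }
  legend("topleft", legend = methods, col = seq_along(methods), lty = 1,
         bty = "n")
  invisible(NULL)
}
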