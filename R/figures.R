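#' Stacked resistance-fraction bars
#'
#' One stacked bar per treatment x day showing the sensitive, sm
#' (surface + double mutants) and CRISPR fractions. Errors if any bar's
#' fractions do not sum to 1.
#'
#' @param results a [run_design_grid()] table (columns `treatment`, `day`,
#'   `f_S`, `f_R`, `f_C`, `f_D`).
#' @param main plot title.
#' @return Invisibly, the 3 x bars fraction matrix.
#' @export
plot_fraction_bars <- function(results, main = "Resistance fractions") {
  need <- c("treatment", "day", "f_S", "f_R", "f_C", "f_D")
  if (!all(need %in% names(results)))
    stop("plot_fraction_bars: results lack columns ",
         paste(setdiff(need, names(results)), collapse = ", "),
         call. = FALSE)
  fr <- rbind(sensitive = results$f_S,
              sm = results$f_R + results$f_D,
              crispr = results$f_C)
  if (any(abs(colSums(fr) - 1) > 1e-6))
    stop("plot_fraction_bars: fractions do not sum to 1", call. = FALSE)
  colnames(fr) <- paste0(results$treatment, " d", results$day)
  op <- par(mar = c(9, 4, 3, 1))
  on.exit(par(op))
  barplot(fr, col = c("white", "orange", "steelblue"), las = 2,
          cex.names = 0.6, ylab = "fraction of clones", main = main)
  legend("topright", fill = c("white", "orange", "steelblue"),
         legend = c("sensitive", "sm", "CRISPR"), bg = "white", cex = 0.8)
  invisible(fr)
}

#' Log-scale density time courses
#'
#' Host compartments and free phage over a trajectory, log10 y-axis;
#' transfer boundaries marked.
#'
#' @param traj a `trajectory`.
#' @param main plot title.
#' @export
plot_density_timecourse <- function(traj, main = "Density dynamics") {
  st <- pmax(traj$states, 1e-1)
  matplot(traj$times, log10(st), type = "l", lty = 1, lwd = 1.5,
          col = c("blue", "green3", "red", "brown", "black"),
          xlab = "time (h)", ylab = "log10 density (per ml)", main = main)
  if (length(traj$boundaries) > 1)
    abline(v = traj$times[traj$boundaries[-length(traj$boundaries)]],
           col = "grey", lty = 2)
  legend("bottomright", col = c("blue", "green3", "red", "brown", "black"),
         lty = 1, legend = c("S", "R", "C", "D", "V"), cex = 0.8,
         bg = "white")
  invisible(NULL)
}

#' Linkage-disequilibrium panel
#'
#' LD(t) = f_S f_D - f_R f_C along a trajectory, with the zero line.
#'
#' @param metrics a [selection_trajectory()] table (columns `t`, `LD`).
#' @param main plot title.
#' @export
plot_ld <- function(metrics, main = "Linkage disequilibrium") {
  if (!all(c("t", "LD") %in% names(metrics)))
    stop("plot_ld: metrics lack t/LD columns", call. = FALSE)
  plot(metrics$t, metrics$LD, type = "l", lwd = 1.5, xlab = "time (h)",
       ylab = expression(LD == f[S] * f[D] - f[R] * f[C]), main = main)
  abline(h = 0, col = "grey")
  invisible(NULL)
}

#' Render the standard figure set to files
#'
#' Writes deterministic PNGs from result tables: stacked fraction bars per
#' treatment/day, log-density time courses, and an LD-vs-time panel
#' (whichever inputs are supplied).
#'
#' @param results optional [run_design_grid()] table.
#' @param traj optional `trajectory`.
#' @param metrics optional [selection_trajectory()] table.
#' @param dir output directory (created if needed).
#' @return Character vector of files written.
#' @export
render_figures <- function(results = NULL, traj = NULL, metrics = NULL,
                           dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if (!is.null(results)) {
    f <- file.path(dir, "fraction_bars.png")
    png(f, width = 1200, height = 700, res = 120)
    plot_fraction_bars(results)
    dev.off()
    out <- c(out, f)
  }
  if (!is.null(traj)) {
    f <- file.path(dir, "density_timecourse.png")
    png(f, width = 900, height = 600, res = 120)
    plot_density_timecourse(traj)
    dev.off()
    out <- c(out, f)
  }
  if (!is.null(metrics)) {
    f <- file.path(dir, "linkage_disequilibrium.png")
    png(f, width = 900, height = 600, res = 120)
    plot_ld(metrics)
    dev.off()
    out <- c(out, f)
  }
  out
}

#' @export
plot.trajectory <- function(x, ...) {
  plot_density_timecourse(x, ...)
}
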