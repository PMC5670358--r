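#' Render a six-panel diagnostic report of a trajectory
#'
#' One figure per profile - source sucrose, sink sucrose, growth rate,
#' starch, circadian phase, starch degradation rate - each with white/grey
#' day/night shading, plus a `summary.json` with the headline diagnostics
#' (including the carbon-audit residual).  Re-rendering the same trajectory
#' overwrites the same files with identical content.
#'
#' @param traj a `plant_trajectory`.
#' @param out_dir output directory (created if missing).
#' @param width,height,dpi figure geometry passed to [ggplot2::ggsave()].
#' @return invisibly, the paths of the files written.
#' @export
render_report <- function(traj, out_dir, width = 7, height = 3.5, dpi = 120) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to directory: ", out_dir)
  pp <- attr(traj, "photoperiods")
  night <- data.frame(xmin = 24 * (seq_along(pp) - 1) + pp,
                      xmax = 24 * seq_along(pp))
  panels <- list(
    source_sucrose = list(var = "S_G", lab = "Source sucrose (umolC6/gFW)"),
    sink_sucrose = list(var = "S_Y_sam", lab = "Sink sucrose (umolC6/gFW)"),
    growth_rate = list(var = "gr_sam", lab = "Growth rate (1/h)"),
    starch = list(var = "C", lab = "Starch (umolC6/gFW)"),
    phase = list(var = "phi", lab = "Circadian phase (h)"),
    degradation_rate = list(var = "beta", lab = "Starch degradation rate (1/h)"))
  paths <- character()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    gg <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$t, y = .data[[p$var]])) +
      ggplot2::geom_rect(data = night, inherit.aes = FALSE, fill = "grey85",
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = -Inf, ymax = Inf)) +
      ggplot2::geom_line(linewidth = 0.4) +
      ggplot2::labs(x = "Time (h)", y = p$lab) +
      ggplot2::theme_classic()
    f <- file.path(out_dir, paste0(nm, ".png"))
    ggplot2::ggsave(f, gg, width = width, height = height, dpi = dpi)
    paths <- c(paths, f)
  }
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(run_summary(traj), sj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, sj))
}
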