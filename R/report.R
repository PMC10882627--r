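# Report rendering: tidy CSV tables, a JSON summary, and interpolated
# scalp-topography figures for difference maps, template sets and
# correlation matrices.

# inverse-distance-weighted interpolation of channel values onto a grid
# masked to the unit disc; returns list(x, y, z) for image()
topo_grid <- function(values, positions, res = 67) {
  gx <- seq(-1.05, 1.05, length.out = res)
  gy <- gx
  z <- matrix(NA_real_, res, res)
  px <- positions[, "x"]; py <- positions[, "y"]
  for (i in seq_len(res)) for (j in seq_len(res)) {
    if (gx[i]^2 + gy[j]^2 > 1.1025) next
    d2 <- (px - gx[i])^2 + (py - gy[j])^2
    if (any(d2 < 1e-12)) { z[i, j] <- values[which.min(d2)]; next }
    w <- 1 / d2^1.5
    z[i, j] <- sum(w * values) / sum(w)
  }
  list(x = gx, y = gy, z = z)
}

topo_palette <- function(n = 64)
  grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(n)

plot_topomap <- function(values, mont, main = "", zlim = NULL) {
  scalp <- intersect(mont$labels, names(values))
  pos <- mont$positions[scalp, , drop = FALSE]
  g <- topo_grid(values[scalp], pos)
  if (is.null(zlim)) {
    r <- max(abs(g$z), na.rm = TRUE)
    zlim <- c(-r, r)
  }
  graphics::image(g$x, g$y, g$z, zlim = zlim, col = topo_palette(),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  asp = 1, useRaster = TRUE)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(cos(th), sin(th))
  graphics::points(pos[, 1], pos[, 2], pch = 20, cex = 0.5)
}

#' Render a study report to files
#'
#' Writes tidy CSV tables, a JSON summary, and PNG figures (difference
#' topographies per stage and band, template maps at group and grand-mean
#' level, correlation-matrix heatmaps). CSV and JSON content is
#' deterministic given an identical report.
#'
#' @param report a `study_report` from [run_study] (either arm may be NULL)
#' @param outdir output directory (created if needed)
#' @return invisible character vector of the files written
#' @export
render_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("cannot write to ", outdir)
  written <- character(0)
  put <- function(f) { written <<- c(written, f); f }
  sp <- report$spectral
  ms <- report$microstate
  if (!is.null(sp)) {
    utils::write.csv(sp$table, put(file.path(outdir, "band_power.csv")),
                     row.names = FALSE)
    utils::write.csv(sp$cell_fdr, put(file.path(outdir,
                                                "spectral_cells.csv")),
                     row.names = FALSE)
    utils::write.csv(sp$flags, put(file.path(outdir,
                                             "spectral_channel_flags.csv")),
                     row.names = FALSE)
    mont <- montage_1020()
    for (st in names(sp$difference)) for (b in names(sp$difference[[st]])) {
      dm <- sp$difference[[st]][[b]]
      if (is.null(dm)) next
      f <- put(file.path(outdir, sprintf("diff_%s_%s.png", st, b)))
      grDevices::png(f, 480, 480)
      plot_topomap(dm, mont, sprintf("%s %s: patient - control", st, b))
      grDevices::dev.off()
    }
  }
  if (!is.null(ms)) {
    per <- do.call(rbind, lapply(names(ms$metrics), function(sid) {
      df <- ms$metrics[[sid]]$per_class
      df$subject <- sid
      df$group <- unname(ms$groups[sid])
      df
    }))
    utils::write.csv(per, put(file.path(outdir, "ms_parameters.csv")),
                     row.names = FALSE)
    utils::write.csv(ms$parameter_tests,
                     put(file.path(outdir, "ms_parameter_tests.csv")),
                     row.names = FALSE)
    utils::write.csv(ms$transition_tests,
                     put(file.path(outdir, "ms_transition_tests.csv")),
                     row.names = FALSE)
    tr <- do.call(rbind, lapply(names(ms$metrics), function(sid) {
      m <- ms$metrics[[sid]]$transitions
      data.frame(subject = sid, group = unname(ms$groups[sid]),
                 from = rep(rownames(m), ncol(m)),
                 to = rep(colnames(m), each = nrow(m)),
                 proportion = as.vector(m))
    }))
    utils::write.csv(tr, put(file.path(outdir, "ms_transitions.csv")),
                     row.names = FALSE)
    mont <- montage_1020()
    sets <- c(ms$group_templates, list(gm = ms$gm))
    for (nm in names(sets)) {
      f <- put(file.path(outdir, sprintf("templates_%s.png", nm)))
      grDevices::png(f, 960, 260)
      old <- graphics::par(mfrow = c(1, ncol(sets[[nm]]$maps)),
                           mar = c(0.5, 0.5, 2, 0.5))
      for (k in seq_len(ncol(sets[[nm]]$maps))) {
        v <- stats::setNames(sets[[nm]]$maps[, k], sets[[nm]]$channels)
        plot_topomap(v, mont, paste(nm, sets[[nm]]$labels[k]))
      }
      graphics::par(old)
      grDevices::dev.off()
    }
    for (nm in c("patient_vs_control", "gm_vs_canonical")) {
      M <- ms$correlations[[nm]]
      f <- put(file.path(outdir, sprintf("correlation_%s.png", nm)))
      grDevices::png(f, 480, 480)
      graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M,
                      zlim = c(-1, 1), col = topo_palette(), axes = FALSE,
                      xlab = "", ylab = "", main = nm)
      graphics::axis(1, seq_len(nrow(M)), rownames(M))
      graphics::axis(2, seq_len(ncol(M)), colnames(M))
      for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
        graphics::text(i, j, sprintf("%.2f", M[i, j]), cex = 0.9)
      grDevices::dev.off()
    }
  }
  summary <- list(
    n_subjects = if (!is.null(ms)) length(ms$kept) else
      length(unique(report$spectral$table$subject)),
    spectral_significant_cells = if (!is.null(sp))
      sp$cell_fdr[sp$cell_fdr$significant, c("stage", "band")] else NULL,
    ms_gev_mean = if (!is.null(ms)) mean(ms$gev) else NULL,
    ms_excluded = if (!is.null(ms)) ms$excluded else NULL,
    significant_transitions = if (!is.null(ms)) {
      s <- ms$transition_tests
      s[s$corrected_p < report$config$alpha, c("from", "to", "corrected_p")]
    } else NULL,
    log = report$log)
  jsonlite::write_json(summary, put(file.path(outdir, "summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(written)
}
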