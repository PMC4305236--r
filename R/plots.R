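#' Diagnostic plots for a reconstructed chromosome
#'
#' Two styles: \code{"parallel"} draws the chromosome track side by side
#' with each linkage group, with one connecting line per marker (conflicts
#' show up as crossing lines); \code{"scatter"} draws physical versus map
#' position per map, with component scaffolds as alternating shaded boxes
#' and the Pearson correlation coefficient (rho) annotated on each panel
#' (|rho| near 1 indicates near-perfect colinearity).  Spearman
#' coefficients are returned alongside.
#'
#' @param configs list of \code{ScaffoldConfiguration}s (or a single one).
#' @param maps a \code{MapCollection} with scaffold sizes.
#' @param chrom which chromosome to plot.
#' @param style \code{"scatter"} or \code{"parallel"}.
#' @param file optional output path (.png or .pdf); NULL plots to the
#'   active device.
#' @param gap_size gap used when lifting marker coordinates.
#' @return invisibly, a data.frame of per-map Pearson and Spearman
#'   correlations between physical and map positions.
#' @export
plot_chromosome <- function(configs, maps, chrom,
                            style = c("scatter", "parallel"), file = NULL,
                            gap_size = 100) {
  style <- match.arg(style)
  if (inherits(configs, "ScaffoldConfiguration")) configs <- list(configs)
  cfg <- NULL
  for (c0 in configs) if (c0$chrom == chrom) cfg <- c0
  if (is.null(cfg)) stop("no configuration for chromosome ", chrom)
  cm <- consensus_map(list(cfg), maps, gap_size = gap_size)
  if (!nrow(cm)) {
    warning("no markers on chromosome ", chrom, "; empty plot")
    return(invisible(data.frame(map = character(), pearson = numeric(),
                                spearman = numeric())))
  }
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 8, height = 6)
    else grDevices::png(file, width = 900, height = 650)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pl <- config_placements(list(cfg), maps$scaffold_sizes,
                          gap_size = gap_size)
  map_names <- unique(cm$map)
  stats_out <- data.frame(
    map = map_names,
    pearson = vapply(map_names, function(m) {
      s <- cm[cm$map == m, ]
      if (nrow(s) < 2L) return(NA_real_)
      stats::cor(s$pos, s$map_pos)
    }, 0),
    spearman = vapply(map_names, function(m) {
      s <- cm[cm$map == m, ]
      if (nrow(s) < 2L) return(NA_real_)
      stats::cor(s$pos, s$map_pos, method = "spearman")
    }, 0), stringsAsFactors = FALSE)
  if (style == "scatter") {
    old <- graphics::par(mfrow = c(length(map_names), 1L),
                         mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old), add = TRUE)
    for (m in map_names) {
      s <- cm[cm$map == m, ]
      graphics::plot(NA, xlim = c(0, max(pl$start + pl$len)),
                     ylim = range(s$map_pos),
                     xlab = paste(chrom, "(bp)"),
                     ylab = paste(m, "position"), main = m)
      for (i in seq_len(nrow(pl)))
        graphics::rect(pl$start[i], graphics::par("usr")[3L],
                       pl$start[i] + pl$len[i], graphics::par("usr")[4L],
                       col = if (i %% 2L) "#00000010" else "#00000000",
                       border = NA)
      graphics::points(s$pos, s$map_pos, pch = 16, cex = 0.5,
                       col = "#205090")
      rho <- stats_out$pearson[stats_out$map == m]
      graphics::legend("topleft", bty = "n",
                       legend = sprintf("rho = %.3f", rho))
    }
  } else {
    tracks <- unique(cm[, c("map", "lg")])
    graphics::plot(NA, xlim = c(0, 1),
                   ylim = c(0, nrow(tracks) + 1L), xlab = "",
                   ylab = "", axes = FALSE,
                   main = paste(chrom, "vs linkage groups"))
    chrom_len <- max(pl$start + pl$len)
    graphics::segments(0, 0, 1, 0, lwd = 4)
    graphics::text(0.5, -0.2, chrom, xpd = NA)
    for (t in seq_len(nrow(tracks))) {
      s <- cm[cm$map == tracks$map[t] & cm$lg == tracks$lg[t], ]
      span <- range(s$map_pos)
      y <- t
      graphics::segments(0, y, 1, y, lwd = 3, col = "grey40")
      graphics::text(1.02, y, paste0(tracks$map[t], "-", tracks$lg[t]),
                     adj = 0, xpd = NA, cex = 0.8)
      xm <- if (diff(span) > 0) (s$map_pos - span[1L]) / diff(span)
            else rep(0.5, nrow(s))
      graphics::segments(s$pos / chrom_len, 0.05, xm, y - 0.05,
                         col = "#20509060")
    }
  }
  invisible(stats_out)
}
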