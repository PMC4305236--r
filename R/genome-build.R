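AGP_COLS <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "col6", "col7", "col8", "col9")

# 0-based placements of every scaffold in `configs` (internal)
config_placements <- function(configs, scaffold_sizes, gap_sizes = NULL,
                              gap_size = 100) {
  out <- list()
  for (cfg in configs) {
    n <- length(cfg$scaffolds)
    if (n == 0L) next
    gaps <- if (!is.null(gap_sizes) && !is.null(gap_sizes[[cfg$chrom]]))
      gap_sizes[[cfg$chrom]] else rep(gap_size, max(n - 1L, 0L))
    lens <- unname(scaffold_sizes[cfg$scaffolds])
    if (anyNA(lens))
      stop("missing scaffold length for: ",
           cfg$scaffolds[which(is.na(lens))[1L]])
    starts <- cumsum(c(0, lens[-n] + gaps))
    out[[cfg$chrom]] <- data.frame(
      scaffold = cfg$scaffolds, chrom = cfg$chrom, start = starts,
      len = lens, orientation = cfg$orientation,
      gap_after = c(gaps, NA_real_), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

agp_from_placements <- function(pl) {
  rows <- list()
  for (chrom in unique(pl$chrom)) {
    sub <- pl[pl$chrom == chrom, , drop = FALSE]
    part <- 0L
    for (i in seq_len(nrow(sub))) {
      part <- part + 1L
      ori <- c(`-1` = "-", `0` = "?", `1` = "+")[
        as.character(sub$orientation[i])]
      rows[[length(rows) + 1L]] <- data.frame(
        object = chrom, object_beg = sub$start[i] + 1,
        object_end = sub$start[i] + sub$len[i], part_number = part,
        component_type = "W", col6 = sub$scaffold[i], col7 = "1",
        col8 = as.character(sub$len[i]), col9 = ori,
        stringsAsFactors = FALSE)
      if (i < nrow(sub)) {
        g <- sub$gap_after[i]
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = chrom, object_beg = sub$start[i] + sub$len[i] + 1,
          object_end = sub$start[i] + sub$len[i] + g, part_number = part,
          component_type = "U", col6 = as.character(g), col7 = "scaffold",
          col8 = "yes", col9 = "map", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

chain_from_placements <- function(pl, chrom_sizes) {
  lines <- character(0)
  id <- 0L
  for (i in seq_len(nrow(pl))) {
    id <- id + 1L
    strand <- if (pl$orientation[i] < 0) "-" else "+"
    lines <- c(lines, sprintf(
      "chain %d %s %d + %d %d %s %d %s %d %d %d",
      as.integer(pl$len[i]), pl$chrom[i],
      as.integer(chrom_sizes[[pl$chrom[i]]]),
      as.integer(pl$start[i]), as.integer(pl$start[i] + pl$len[i]),
      pl$scaffold[i], as.integer(pl$len[i]), strand, 0L,
      as.integer(pl$len[i]), id),
      as.character(as.integer(pl$len[i])), "")
  }
  lines
}

#' Lift scaffold positions to chromosome coordinates
#'
#' @param placements placement table from a \code{GenomeBuild} (component
#'   \code{placements}).
#' @param scaffold character vector of scaffold ids.
#' @param pos 0-based positions on those scaffolds.
#' @return data.frame with \code{chrom} and 0-based \code{pos}; NA for
#'   unplaced scaffolds.
#' @export
lift_positions <- function(placements, scaffold, pos) {
  idx <- match(scaffold, placements$scaffold)
  chrom <- placements$chrom[idx]
  start <- placements$start[idx]
  len <- placements$len[idx]
  ori <- placements$orientation[idx]
  lifted <- ifelse(ori < 0, start + (len - 1 - pos), start + pos)
  data.frame(chrom = chrom, pos = lifted, stringsAsFactors = FALSE)
}

#' Build pseudomolecules from optimized configurations
#'
#' Concatenates scaffolds in the computed order and orientation, padding
#' junctions with N gaps (default 100 bp, or per-junction estimates from
#' \code{\link{estimate_gaps}}).  Reverse-oriented scaffolds are
#' reverse-complemented; undetermined orientations are written forward and
#' reported as "?" in the AGP.  Unanchored scaffolds are carried through
#' unchanged.  Outputs: pseudomolecule + unplaced FASTA, AGP 2.0 (gap rows
#' U/scaffold/yes/map), UCSC CHAIN records for liftOver from scaffold to
#' chromosome coordinates, and summary statistics.
#'
#' @param configs list of \code{ScaffoldConfiguration}s.
#' @param fasta scaffold FASTA path or a \code{DNAStringSet}.
#' @param gap_size default inter-scaffold gap in bp.
#' @param gap_sizes optional named list (by chromosome) of per-junction gap
#'   vectors.
#' @param maps optional \code{MapCollection} for the summary statistics.
#' @param outdir optional output directory; writes \code{genome.fasta},
#'   \code{genome.agp}, \code{genome.chain}, \code{summary.tsv}.
#' @param prefix file name stem used under \code{outdir}.
#' @return a \code{GenomeBuild} list: \code{seqs}, \code{agp},
#'   \code{chain}, \code{placements}, \code{summary}.
#' @export
build_genome <- function(configs, fasta, gap_size = 100, gap_sizes = NULL,
                         maps = NULL, outdir = NULL, prefix = "genome") {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sizes <- stats::setNames(as.numeric(Biostrings::width(seqs)), names(seqs))
  placed <- unlist(lapply(configs, `[[`, "scaffolds"))
  if (anyDuplicated(placed))
    stop("scaffold placed more than once: ",
         placed[duplicated(placed)][1L])
  missing_seq <- setdiff(placed, names(seqs))
  if (length(missing_seq))
    stop("missing scaffold sequence: ", missing_seq[1L])
  pl <- config_placements(configs, sizes, gap_sizes, gap_size)
  chrom_seqs <- Biostrings::DNAStringSet()
  chrom_sizes <- numeric(0)
  for (cfg in configs) {
    if (!length(cfg$scaffolds)) next
    sub <- pl[pl$chrom == cfg$chrom, , drop = FALSE]
    pieces <- character(2L * nrow(sub) - 1L)
    for (i in seq_len(nrow(sub))) {
      s <- seqs[[sub$scaffold[i]]]
      if (sub$orientation[i] < 0) s <- Biostrings::reverseComplement(s)
      pieces[2L * i - 1L] <- as.character(s)
      if (i < nrow(sub))
        pieces[2L * i] <- strrep("N", sub$gap_after[i])
    }
    one <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(one) <- cfg$chrom
    chrom_seqs <- c(chrom_seqs, one)
    chrom_sizes[cfg$chrom] <- Biostrings::width(one)
  }
  unplaced <- setdiff(names(seqs), placed)
  out_seqs <- c(chrom_seqs, seqs[unplaced])
  agp <- agp_from_placements(pl)
  # unplaced singletons as their own objects
  if (length(unplaced)) {
    agp <- rbind(agp, data.frame(
      object = unplaced, object_beg = 1, object_end = sizes[unplaced],
      part_number = 1L, component_type = "W", col6 = unplaced, col7 = "1",
      col8 = as.character(sizes[unplaced]), col9 = "+",
      stringsAsFactors = FALSE))
  }
  chain <- chain_from_placements(pl, chrom_sizes)
  summ <- build_summary(configs, sizes, maps)
  build <- list(seqs = out_seqs, agp = agp, chain = chain,
                placements = pl, chrom_sizes = chrom_sizes,
                summary = summ, gap_size = gap_size)
  class(build) <- "GenomeBuild"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(outdir, paste0(prefix, ".fasta"))
    Biostrings::writeXStringSet(out_seqs, fa, width = 60L)
    write_agp(build, file.path(outdir, paste0(prefix, ".agp")),
              gap_size = gap_size)
    writeLines(chain, file.path(outdir, paste0(prefix, ".chain")))
    if (!is.null(summ))
      utils::write.table(summ, file.path(outdir, paste0(prefix,
                                                        ".summary.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  build
}

#' Write the AGP file (v2.0) with a metadata header
#'
#' @param build a \code{GenomeBuild}.
#' @param path output path.
#' @param gap_size default gap recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_agp <- function(build, path, gap_size = 100) {
  header <- c("##agp-version\t2.0",
              paste0("# generated by mapanchor ",
                     as.character(utils::packageVersion("mapanchor"))),
              paste0("# default gap size: ", gap_size))
  a <- build$agp
  body <- apply(a, 1L, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# summary statistics in the style of the per-map anchoring tables (internal
# helper; exported via build_genome)
build_summary <- function(configs, sizes, maps) {
  placed <- unlist(lapply(configs, `[[`, "scaffolds"))
  total_bases <- sum(sizes)
  n50_len <- {
    sl <- sort(sizes, decreasing = TRUE)
    sl[which(cumsum(sl) >= total_bases / 2)[1L]]
  }
  one_row <- function(label, scafs, mk) {
    cnt <- table(factor(mk$scaffold, levels = scafs))
    bases <- sum(sizes[scafs])
    data.frame(
      set = label,
      linkage_groups = length(unique(paste(mk$map, mk$lg))),
      markers_unique = nrow(unique(mk[, c("scaffold", "pos")])),
      markers_per_mb = if (bases > 0)
        round(nrow(unique(mk[, c("scaffold", "pos")])) / (bases / 1e6), 1)
        else 0,
      n50_scaffolds = sum(sizes[scafs] >= n50_len),
      scaffolds = length(scafs),
      scaffolds_1_marker = sum(cnt == 1L),
      scaffolds_2_markers = sum(cnt == 2L),
      scaffolds_3_markers = sum(cnt == 3L),
      scaffolds_4plus_markers = sum(cnt >= 4L),
      total_bases = bases,
      percent_of_genome = round(100 * bases / total_bases, 1),
      stringsAsFactors = FALSE)
  }
  if (is.null(maps)) {
    mk0 <- new_markers()
    rows <- list(one_row("Anchored", placed, mk0),
                 one_row("Unplaced", setdiff(names(sizes), placed), mk0))
    return(do.call(rbind, rows))
  }
  mk <- maps$markers
  rows <- lapply(maps$map_order, function(m) {
    sub <- mk[mk$map == m, , drop = FALSE]
    one_row(m, intersect(placed, unique(sub$scaffold)), sub)
  })
  rows <- c(rows, list(
    one_row("Anchored", placed, mk[mk$scaffold %in% placed, , drop = FALSE]),
    one_row("Unplaced", setdiff(names(sizes), placed),
            mk[!(mk$scaffold %in% placed), , drop = FALSE])))
  do.call(rbind, rows)
}

#' Estimate inter-scaffold gap sizes from recombination rates
#'
#' For each map, a cubic spline interpolates map position against the
#' provisional physical position (fixed-gap build); its derivative at the
#' junction midpoint is the local recombination rate (map units per bp).
#' For every flanking marker pair across a junction the implied physical
#' span is \code{delta_map / rate}, from which both marker-to-edge
#' overhangs are deducted.  The junction gap is the smallest estimate over
#' all marker pairs and maps, clamped to \code{[min_gap, max_gap]};
#' junctions with no flanking markers keep \code{gap_default}.
#'
#' @param config a \code{ScaffoldConfiguration} (>= 2 scaffolds).
#' @param maps a \code{MapCollection} with scaffold sizes or an explicit
#'   \code{scaffold_sizes}.
#' @param scaffold_sizes named lengths (default from \code{maps}).
#' @param gap_default provisional/fallback gap (bp).
#' @param min_gap,max_gap clamping bounds in bp.
#' @return numeric vector of gap sizes, one per junction.
#' @export
estimate_gaps <- function(config, maps, scaffold_sizes = maps$scaffold_sizes,
                          gap_default = 100, min_gap = 10, max_gap = 1e6) {
  n <- length(config$scaffolds)
  if (n < 2L) return(numeric(0))
  if (is.null(scaffold_sizes)) stop("scaffold sizes required")
  pl <- config_placements(list(config), scaffold_sizes,
                          gap_size = gap_default)
  mk <- maps$markers[maps$markers$scaffold %in% config$scaffolds, ,
                     drop = FALSE]
  if (!nrow(mk)) return(rep(gap_default, n - 1L))
  lifted <- lift_positions(pl, mk$scaffold, mk$pos)
  mk$phys <- lifted$pos
  gaps <- rep(NA_real_, n - 1L)
  for (m in unique(mk$map)) {
    sub <- mk[mk$map == m, , drop = FALSE]
    if (nrow(sub) < 4L) next
    ord <- order(sub$phys)
    x <- sub$phys[ord]
    y <- sub$map_pos[ord]
    ux <- tapply(y, x, mean)
    xs <- as.numeric(names(ux))
    if (length(xs) < 4L) next
    sp <- stats::splinefun(xs, as.numeric(ux), method = "fmm")
    for (i in seq_len(n - 1L)) {
      left <- config$scaffolds[i]
      right <- config$scaffolds[i + 1L]
      lm_ <- sub[sub$scaffold == left, , drop = FALSE]
      rm_ <- sub[sub$scaffold == right, , drop = FALSE]
      if (!nrow(lm_) || !nrow(rm_)) next
      li <- match(left, pl$scaffold)
      ri <- match(right, pl$scaffold)
      # exclusive scaffold end, so that for a linear map the flanking-pair
      # separation decomposes exactly as overhang + gap + overhang
      left_end <- pl$start[li] + pl$len[li]
      right_start <- pl$start[ri]
      mid <- (left_end + right_start) / 2
      rate <- abs(sp(mid, deriv = 1L))
      if (!is.finite(rate) || rate < 1e-300) next
      for (a in seq_len(nrow(lm_))) {
        for (b in seq_len(nrow(rm_))) {
          dmap <- abs(rm_$map_pos[b] - lm_$map_pos[a])
          est <- dmap / rate - (left_end - lm_$phys[a]) -
            (rm_$phys[b] - right_start)
          if (is.na(gaps[i]) || est < gaps[i]) gaps[i] <- est
        }
      }
    }
  }
  ifelse(is.na(gaps), gap_default, pmin(pmax(gaps, min_gap), max_gap))
}

#' Consensus map in chromosome coordinates
#'
#' Re-expresses every retained marker in the coordinates of the
#' reconstructed chromosomes (the byproduct of lifting all input maps
#' through the build), sorted by lifted position.
#'
#' @param configs list of \code{ScaffoldConfiguration}s.
#' @param maps a \code{MapCollection}.
#' @param scaffold_sizes named lengths (default from \code{maps}).
#' @param gap_size,gap_sizes as in \code{\link{build_genome}}.
#' @return data.frame: chrom, pos (0-based lifted), scaffold, scaffold_pos,
#'   map, lg, map_pos.
#' @export
consensus_map <- function(configs, maps,
                          scaffold_sizes = maps$scaffold_sizes,
                          gap_size = 100, gap_sizes = NULL) {
  pl <- config_placements(configs, scaffold_sizes, gap_sizes, gap_size)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      scaffold = character(), scaffold_pos = integer(),
                      map = character(), lg = character(),
                      map_pos = numeric(), stringsAsFactors = FALSE)
  if (is.null(pl) || !nrow(pl)) return(empty)
  mk <- maps$markers[maps$markers$scaffold %in% pl$scaffold, , drop = FALSE]
  lifted <- lift_positions(pl, mk$scaffold, mk$pos)
  out <- data.frame(chrom = lifted$chrom, pos = lifted$pos,
                    scaffold = mk$scaffold, scaffold_pos = mk$pos,
                    map = mk$map, lg = mk$lg, map_pos = mk$map_pos,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$map), , drop = FALSE]
  rownames(out) <- NULL
  out
}
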