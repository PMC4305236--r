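# Scaffold length profile: log-normal fitted to the three published summary
# statistics of a typical preliminary plant assembly (20,591 sequences over
# 366 Mb, N50 46 kb, longest 346 kb).  With mean = exp(mu + s^2/2) =
# 366e6/20591 and length-weighted median (= N50) exp(mu + s^2) = 46e3 this
# gives s = 1.379, mu = 8.834; lengths are truncated at the observed
# maximum.
SIM_MEANLOG <- 8.834
SIM_SDLOG <- 1.379
SIM_MAXLEN <- 346e3

#' Simulate a fragmented genome assembly
#'
#' Cuts a multi-chromosome genome into scaffolds with lengths drawn from a
#' truncated log-normal profile and assigns each scaffold a random true
#' orientation.  The result is the 'truth' against which a reconstruction
#' is scored.
#'
#' @param genome_size total genome length in bp (default 366 Mb).
#' @param n_chrom number of chromosomes (default 8, equal lengths).
#' @param n_scaffolds approximate total scaffold count; NULL keeps the
#'   fitted profile (about 20,600 scaffolds at the default genome size).
#'   Smaller counts scale all lengths up, preserving the profile shape.
#' @param meanlog,sdlog,max_length length profile parameters.
#' @param seed optional integer seed (deterministic truth tables).
#' @return a \code{SimulationTruth} list: \code{chrom_lengths} (named) and
#'   \code{scaffolds} data.frame (scaffold, chrom, start 0-based, len,
#'   orientation).
#' @export
simulate_assembly <- function(genome_size = 366e6, n_chrom = 8L,
                              n_scaffolds = NULL, meanlog = SIM_MEANLOG,
                              sdlog = SIM_SDLOG, max_length = SIM_MAXLEN,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (genome_size <= 0 || n_chrom < 1L) stop("impossible genome profile")
  chrom_lengths <- stats::setNames(
    rep(floor(genome_size / n_chrom), n_chrom),
    paste0("chr", seq_len(n_chrom)))
  one_per_chrom <- !is.null(n_scaffolds) && n_scaffolds <= n_chrom
  scale <- 1
  if (!is.null(n_scaffolds) && !one_per_chrom) {
    mean_trunc <- exp(meanlog + sdlog^2 / 2) *
      stats::pnorm((log(max_length) - meanlog - sdlog^2) / sdlog) /
      stats::pnorm((log(max_length) - meanlog) / sdlog)
    scale <- (genome_size / n_scaffolds) / mean_trunc
    if (scale <= 0 || !is.finite(scale)) stop("impossible scaffold profile")
  }
  rows <- list()
  id <- 0L
  for (ch in names(chrom_lengths)) {
    remaining <- chrom_lengths[[ch]]
    start <- 0
    while (remaining > 0) {
      if (one_per_chrom) {
        len <- remaining
      } else {
        len <- 0
        while (len < 1 || len > max_length * scale)
          len <- round(stats::rlnorm(1, meanlog, sdlog) * scale)
        len <- min(len, remaining) # last scaffold truncated
      }
      id <- id + 1L
      rows[[id]] <- data.frame(
        scaffold = sprintf("scf%05d", id), chrom = ch, start = start,
        len = len, orientation = sample(c(-1L, 1L), 1L),
        stringsAsFactors = FALSE)
      start <- start + len
      remaining <- remaining - len
    }
  }
  truth <- list(chrom_lengths = chrom_lengths,
                scaffolds = do.call(rbind, c(rows,
                                             list(make.row.names = FALSE))))
  class(truth) <- "SimulationTruth"
  truth
}

# chromosome position -> (scaffold, scaffold pos) given the truth (internal)
truth_scaffold_coords <- function(truth, chrom, chrom_pos) {
  sc <- truth$scaffolds
  out_scaffold <- character(length(chrom))
  out_pos <- integer(length(chrom))
  for (ch in unique(chrom)) {
    sub <- sc[sc$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    idx <- findInterval(chrom_pos[sel], sub$start)
    off <- chrom_pos[sel] - sub$start[idx]
    out_scaffold[sel] <- sub$scaffold[idx]
    out_pos[sel] <- ifelse(sub$orientation[idx] < 0,
                           sub$len[idx] - 1 - off, off)
  }
  data.frame(scaffold = out_scaffold, pos = as.integer(out_pos),
             stringsAsFactors = FALSE)
}

# reverse a run of map positions in place (inversion error)
apply_inversions <- function(map_pos, target, mean_run = 20L) {
  n <- length(map_pos)
  done <- 0L
  while (done < target && n >= 2L) {
    k <- min(1L + stats::rgeom(1L, 1 / mean_run), target - done, n)
    if (k < 2L) k <- min(2L, n)
    s <- sample.int(n - k + 1L, 1L)
    idx <- s:(s + k - 1L)
    map_pos[idx] <- rev(map_pos[idx])
    done <- done + k
  }
  map_pos
}

#' Simulate genomic maps from a fragmented assembly
#'
#' Places uniform markers along the genome, converts their chromosome
#' positions to map units at a constant rate, independently subsamples each
#' map, and injects inversion and translocation errors.  Inversions reverse
#' the map order of contiguous marker runs (geometric run lengths) until a
#' fraction \code{p_inv} of each chromosome's markers is involved;
#' translocations move runs to random map positions, 75\% within the
#' chromosome and 25\% onto another chromosome (corrupting the linkage-group
#' label, which stresses the clustering stage).
#'
#' @param truth a \code{SimulationTruth}.
#' @param n_markers total markers drawn uniformly over the genome.
#' @param n_maps number of maps emitted.
#' @param keep_fraction probability each map retains each marker
#'   (default 2/3).
#' @param p_inv fraction of markers per chromosome inside implanted
#'   inversions, in [0, 0.5].
#' @param p_trans fraction of markers translocated, in [0, 1].
#' @param error_maps indices of maps receiving errors (default: all).
#' @param cm_per_mb constant map rate (default 2 cM/Mb); linear scaling has
#'   no effect on the optimization.
#' @param seed optional integer seed.
#' @return list with \code{maps} (a \code{MapCollection}; map names
#'   \code{map1..mapK}, linkage groups named by true chromosome) and
#'   \code{markers} (truth table: marker, chrom, chrom_pos, scaffold, pos).
#' @export
simulate_maps <- function(truth, n_markers = 8000L, n_maps = 1L,
                          keep_fraction = 2 / 3, p_inv = 0, p_trans = 0,
                          error_maps = seq_len(n_maps), cm_per_mb = 2,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  if (p_inv < 0 || p_inv > 0.5)
    stop("p_inv must be in [0, 0.5] (0.5 is the most extreme case)")
  if (p_trans < 0 || p_trans > 1) stop("p_trans must be in [0, 1]")
  chroms <- names(truth$chrom_lengths)
  chrom <- sample(chroms, n_markers, replace = TRUE,
                  prob = truth$chrom_lengths)
  chrom_pos <- floor(stats::runif(n_markers) *
                       truth$chrom_lengths[chrom])
  coords <- truth_scaffold_coords(truth, chrom, chrom_pos)
  truth_markers <- data.frame(
    marker = sprintf("mk%05d", seq_len(n_markers)), chrom = chrom,
    chrom_pos = chrom_pos, scaffold = coords$scaffold, pos = coords$pos,
    stringsAsFactors = FALSE)
  all_maps <- list()
  mapped_any <- rep(FALSE, n_markers)
  for (j in seq_len(n_maps)) {
    keep <- stats::runif(n_markers) < keep_fraction
    mapped_any <- mapped_any | keep
    mk <- truth_markers[keep, , drop = FALSE]
    mk$lg <- mk$chrom
    mk$map_pos <- mk$chrom_pos * cm_per_mb / 1e6
    if (j %in% error_maps && (p_inv > 0 || p_trans > 0)) {
      for (ch in chroms) {
        sel <- which(mk$lg == ch)
        if (length(sel) < 2L) next
        sel <- sel[order(mk$map_pos[sel])]
        nch <- length(sel)
        if (p_inv > 0)
          mk$map_pos[sel] <- apply_inversions(mk$map_pos[sel],
                                              round(p_inv * nch))
        if (p_trans > 0) {
          target <- round(p_trans * nch)
          done <- 0L
          while (done < target) {
            k <- min(1L + stats::rgeom(1L, 0.2), target - done, nch)
            s <- sample.int(nch - k + 1L, 1L)
            idx <- sel[s:(s + k - 1L)]
            off <- mk$map_pos[idx] - mk$map_pos[idx[1L]]
            if (length(chroms) > 1L && stats::runif(1) < 0.25) {
              # inter-chromosomal: corrupt the linkage-group label
              dest <- sample(setdiff(chroms, ch), 1L)
              u <- stats::runif(1) * truth$chrom_lengths[[dest]] *
                cm_per_mb / 1e6
              mk$lg[idx] <- dest
            } else {
              u <- stats::runif(1) * truth$chrom_lengths[[ch]] *
                cm_per_mb / 1e6
            }
            mk$map_pos[idx] <- u + off
            done <- done + k
          }
        }
      }
    }
    all_maps[[j]] <- data.frame(
      scaffold = mk$scaffold, pos = mk$pos, map = paste0("map", j),
      lg = mk$lg, map_pos = mk$map_pos, stringsAsFactors = FALSE)
  }
  truth_markers$mapped <- mapped_any
  markers <- do.call(rbind, c(all_maps, list(make.row.names = FALSE)))
  sizes <- stats::setNames(truth$scaffolds$len, truth$scaffolds$scaffold)
  list(maps = map_collection(markers, scaffold_sizes = sizes,
                             map_order = paste0("map", seq_len(n_maps))),
       markers = truth_markers)
}

#' Random scaffold sequences for a simulated assembly
#'
#' @param truth a \code{SimulationTruth} (keep it small; sequences are
#'   random bases).
#' @param seed optional integer seed.
#' @return a \code{DNAStringSet} named by scaffold.
#' @export
simulate_scaffold_fasta <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- truth$scaffolds
  seqs <- vapply(sc$len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sc$scaffold
  out
}

#' LMS-based accuracy of a reconstruction against the simulation truth
#'
#' Per reconstructed chromosome, the truth markers on its scaffolds are
#' ordered by their position in the reconstruction and the LMS of their
#' true chromosome positions is computed; the accuracy is the summed LMS
#' divided by the total marker count.  Markers on unplaced scaffolds, or on
#' scaffolds clustered onto a chromosome whose majority of markers comes
#' from a different true chromosome, count toward the denominator only.
#' Markers never observed by any input map carry no anchoring information
#' (their scaffolds may legitimately be unplaced or unoriented) and are
#' excluded from the metric by default (\code{mapped_only}).  1 means
#' perfect colinearity between reconstruction and truth (a wholly reversed
#' chromosome still scores 1: monotonic either way).
#'
#' @param configs list of \code{ScaffoldConfiguration}s.
#' @param truth a \code{SimulationTruth}.
#' @param truth_markers marker truth table from \code{\link{simulate_maps}}.
#' @param gap_size gap used for lifting (has no effect on the ordering).
#' @param mapped_only drop markers absent from every map (uses the
#'   \code{mapped} column when present).
#' @return accuracy in [0, 1].
#' @export
anchoring_accuracy <- function(configs, truth, truth_markers,
                               gap_size = 100, mapped_only = TRUE) {
  if (mapped_only && "mapped" %in% names(truth_markers))
    truth_markers <- truth_markers[truth_markers$mapped, , drop = FALSE]
  total <- nrow(truth_markers)
  if (total == 0L) return(NA_real_)
  sizes <- stats::setNames(truth$scaffolds$len, truth$scaffolds$scaffold)
  pl <- config_placements(configs, sizes, gap_size = gap_size)
  if (is.null(pl) || !nrow(pl)) return(0)
  idx <- match(truth_markers$scaffold, pl$scaffold)
  placed <- !is.na(idx)
  mk <- truth_markers[placed, , drop = FALSE]
  lifted <- lift_positions(pl, mk$scaffold, mk$pos)
  mk$rec_chrom <- lifted$chrom
  mk$rec_pos <- lifted$pos
  lms_sum <- 0L
  for (ch in unique(mk$rec_chrom)) {
    sub <- mk[mk$rec_chrom == ch, , drop = FALSE]
    major <- names(sort(table(sub$chrom), decreasing = TRUE))[1L]
    sub <- sub[sub$chrom == major, , drop = FALSE]
    sub <- sub[order(sub$rec_pos), , drop = FALSE]
    lms_sum <- lms_sum + lms_cpp(sub$chrom_pos)
  }
  lms_sum / total
}
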