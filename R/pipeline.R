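#' Run the full anchoring pipeline
#'
#' Ties the stages together: read markers/weights/FASTA, preprocess
#' (clustering, chimera alerts, outlier removal), per-chromosome two-phase
#' optimization, optional gap estimation, and genome build.  Writes the
#' preprocessing report, per-chromosome L scores before and after
#' refinement, and (when a FASTA is supplied) the FASTA/AGP/CHAIN/summary
#' outputs plus the consensus map.
#'
#' @param bed marker BED path.
#' @param fasta optional scaffold FASTA path (without it only the
#'   configurations and consensus map are produced).
#' @param weights_file optional weights file.
#' @param outdir output directory, or NULL for no files.
#' @param seed integer seed driving all randomness.
#' @param npop,ngen GA parameters (see \code{\link{ga_refine}}).
#' @param gap_size default inter-scaffold gap (bp).
#' @param do_estimate_gaps estimate per-junction gaps from recombination
#'   rates instead of the fixed default.
#' @param scaffold_sizes optional named lengths when no FASTA is given.
#' @param verbose print progress at INFO level.
#' @return list: \code{maps}, \code{prep}, \code{configs}, \code{scores}
#'   (per-chromosome L before/after), \code{gap_sizes}, \code{build} (NULL
#'   without sequences), \code{consensus}.
#' @export
run_pipeline <- function(bed, fasta = NULL, weights_file = NULL,
                         outdir = NULL, seed = 42L, npop = 100L,
                         ngen = 1000L, gap_size = 100,
                         do_estimate_gaps = FALSE, scaffold_sizes = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("INFO: ", sprintf(...))
  maps <- read_map_collection(bed, weights_file = weights_file,
                              fasta = fasta,
                              scaffold_sizes = scaffold_sizes)
  say("loaded %d markers from %d map(s)", nrow(maps$markers),
      length(maps$map_order))
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prep <- preprocess_maps(
    maps, report_file = if (!is.null(outdir))
      file.path(outdir, "preprocess.report.txt") else NULL)
  if (verbose) for (ln in prep$report) message("INFO: ", ln)
  configs <- anchor_scaffolds(prep, seed = seed, npop = npop, ngen = ngen)
  scores <- do.call(rbind, lapply(configs, function(cfg) data.frame(
    chrom = cfg$chrom, n_scaffolds = length(cfg$scaffolds),
    L_initial = attr(cfg, "L_initial") %||% NA_real_,
    L_final = attr(cfg, "L_final") %||% NA_real_,
    stringsAsFactors = FALSE)))
  if (verbose && !is.null(scores))
    for (i in seq_len(nrow(scores)))
      say("chromosome %s: %d scaffolds, L %0.1f -> %0.1f",
          scores$chrom[i], scores$n_scaffolds[i], scores$L_initial[i],
          scores$L_final[i])
  gap_sizes <- NULL
  if (do_estimate_gaps) {
    gap_sizes <- lapply(configs, function(cfg) {
      sub <- prep$maps
      estimate_gaps(cfg, sub, scaffold_sizes = maps$scaffold_sizes,
                    gap_default = gap_size)
    })
    names(gap_sizes) <- names(configs)
  }
  build <- NULL
  if (!is.null(fasta)) {
    build <- build_genome(configs, fasta, gap_size = gap_size,
                          gap_sizes = gap_sizes, maps = maps,
                          outdir = outdir)
  }
  consensus <- if (!is.null(maps$scaffold_sizes))
    consensus_map(configs, prep$maps, gap_size = gap_size,
                  gap_sizes = gap_sizes) else NULL
  if (!is.null(outdir) && !is.null(consensus))
    utils::write.table(consensus, file.path(outdir, "consensus_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(maps = maps, prep = prep, configs = configs, scores = scores,
       gap_sizes = gap_sizes, build = build, consensus = consensus)
}
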