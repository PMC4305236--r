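#' @useDynLib mapanchor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MARKER_COLS <- c("scaffold", "pos", "map", "lg", "map_pos")

new_markers <- function(scaffold = character(), pos = integer(),
                        map = character(), lg = character(),
                        map_pos = numeric()) {
  data.frame(scaffold = as.character(scaffold), pos = as.integer(pos),
             map = as.character(map), lg = as.character(lg),
             map_pos = as.numeric(map_pos), stringsAsFactors = FALSE)
}

#' Assemble a map collection
#'
#' A \code{MapCollection} bundles all markers from one or more genomic maps
#' together with per-map weights and (optionally) scaffold lengths.  A marker
#' links a physical position on a scaffold (bp) to a position on a named
#' map/linkage group (cM for genetic maps; scaled units for optical or
#' synteny maps).  Linear rescaling of a map's positions has no effect on
#' the optimization.
#'
#' @param markers data.frame with columns \code{scaffold}, \code{pos} (0-based
#'   bp), \code{map}, \code{lg}, \code{map_pos}.
#' @param weights named numeric vector of positive per-map weights; maps not
#'   named default to weight 1.
#' @param scaffold_sizes named integer vector of scaffold lengths in bp, or
#'   NULL if unknown.
#' @param map_order character vector fixing the user input order of maps
#'   (used for pivot tie-breaking); defaults to order of first appearance.
#' @return An object of class \code{MapCollection}.
#' @export
map_collection <- function(markers, weights = NULL, scaffold_sizes = NULL,
                           map_order = NULL) {
  stopifnot(is.data.frame(markers))
  missing_cols <- setdiff(MARKER_COLS, names(markers))
  if (length(missing_cols))
    stop("markers lacks columns: ", paste(missing_cols, collapse = ", "))
  markers <- new_markers(markers$scaffold, markers$pos, markers$map,
                         markers$lg, markers$map_pos)
  if (nrow(markers)) {
    if (any(markers$pos < 0)) stop("marker pos must be >= 0")
    if (any(!is.finite(markers$map_pos))) stop("map_pos must be finite")
    if (any(!nzchar(markers$map)) || any(!nzchar(markers$lg)))
      stop("map and linkage group names must be non-empty")
  }
  if (is.null(map_order)) map_order <- unique(markers$map)
  map_order <- union(map_order, unique(markers$map))
  w <- stats::setNames(rep(1, length(map_order)), map_order)
  if (!is.null(weights)) {
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("map weights must be positive and finite")
    known <- intersect(names(weights), map_order)
    extra <- setdiff(names(weights), map_order)
    if (length(extra))
      warning("weights name unknown maps: ", paste(extra, collapse = ", "))
    w[known] <- weights[known]
  }
  if (!is.null(scaffold_sizes)) {
    scaffold_sizes <- stats::setNames(as.numeric(scaffold_sizes),
                                      names(scaffold_sizes))
    absent <- setdiff(unique(markers$scaffold), names(scaffold_sizes))
    if (length(absent))
      stop("markers reference scaffolds missing from scaffold_sizes: ",
           paste(utils::head(absent, 5), collapse = ", "))
    too_far <- markers$pos >= scaffold_sizes[markers$scaffold]
    if (any(too_far))
      stop("marker positions beyond scaffold length for: ",
           paste(utils::head(unique(markers$scaffold[too_far]), 5),
                 collapse = ", "))
  }
  structure(list(markers = markers, weights = w,
                 scaffold_sizes = scaffold_sizes, map_order = map_order),
            class = "MapCollection")
}

#' @export
print.MapCollection <- function(x, ...) {
  cat("MapCollection:", nrow(x$markers), "markers,",
      length(x$map_order), "map(s)\n")
  for (m in x$map_order) {
    sub <- x$markers[x$markers$map == m, , drop = FALSE]
    cat(sprintf("  %s (w=%g): %d markers, %d linkage group(s)\n",
                m, x$weights[[m]], nrow(sub), length(unique(sub$lg))))
  }
  if (!is.null(x$scaffold_sizes))
    cat("  scaffold sizes known for", length(x$scaffold_sizes),
        "scaffolds\n")
  invisible(x)
}

#' Parse the marker BED dialect
#'
#' Reads 4+ column tab-separated lines \code{scaffold<TAB>start<TAB>end<TAB>
#' MapName-LinkageGroup:position}.  Intervals are 0-based half-open; the
#' marker point position is the interval midpoint, \code{floor((start+end)/2)},
#' so 1-bp GBS markers keep their coordinate while ranged optical or synteny
#' matches use their centre.  Exact duplicate rows are dropped once with a
#' warning; rows identical except for \code{map_pos} are distinct markers and
#' are kept.
#'
#' @param path path to a marker BED file.
#' @return data.frame of markers (columns \code{scaffold}, \code{pos},
#'   \code{map}, \code{lg}, \code{map_pos}), in file order.
#' @export
read_marker_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(new_markers())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 4L)
  if (length(bad))
    stop("line ", bad[1], ": expected >= 4 tab-separated columns")
  scaffold <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  label <- vapply(parts, `[[`, "", 4L)
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("line ", bad, ": start/end not integers")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("line ", bad, ": start must be < end (0-based half-open)")
  }
  # label is "<map>-<lg>:<pos>"; map may itself contain hyphens, so split on
  # the last hyphen before the colon
  ok <- grepl("^.+-[^-:]+:[0-9eE.+-]+$", label)
  if (any(!ok))
    stop("line ", which(!ok)[1], ": malformed marker label '",
         label[which(!ok)[1]], "' (expected <map>-<lg>:<pos>)")
  map <- sub("^(.+)-([^-:]+):([0-9eE.+-]+)$", "\\1", label)
  lg <- sub("^(.+)-([^-:]+):([0-9eE.+-]+)$", "\\2", label)
  map_pos <- as.numeric(sub("^(.+)-([^-:]+):([0-9eE.+-]+)$", "\\3", label))
  if (anyNA(map_pos))
    stop("line ", which(is.na(map_pos))[1], ": non-numeric map position")
  mk <- new_markers(scaffold, (start + end) %/% 2L, map, lg, map_pos)
  key <- paste(scaffold, start, end, label, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " exact duplicate marker row(s) dropped")
    mk <- mk[!duplicated(key), , drop = FALSE]
    rownames(mk) <- NULL
  }
  mk
}

#' Write markers in the BED dialect
#'
#' Inverse of \code{\link{read_marker_bed}}: each marker is emitted as a 1-bp
#' interval \code{[pos, pos+1)} so the midpoint rule recovers \code{pos}
#' exactly.
#'
#' @param markers marker data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_marker_bed <- function(markers, path) {
  lines <- sprintf("%s\t%d\t%d\t%s-%s:%s", markers$scaffold, markers$pos,
                   markers$pos + 1L, markers$map, markers$lg,
                   format(markers$map_pos, trim = TRUE, scientific = FALSE,
                          drop0trailing = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a map weights file
#'
#' Whitespace-separated \code{name weight} lines.  Weights bias every stage
#' that resolves conflicts between maps (pivot selection, chromosome
#' assignment, the L objective).  Maps absent from the file default to
#' weight 1; a missing file means all maps weigh 1.
#'
#' @param path path to the weights file (may not exist).
#' @return named numeric vector of weights (possibly empty).
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) {
    warning("weights file not found; all maps default to weight 1")
    return(stats::setNames(numeric(0), character(0)))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(vapply(parts, length, 0L) < 2L))
    stop("weights lines must be 'name weight'")
  nm <- vapply(parts, `[[`, "", 1L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(w) || any(w <= 0))
    stop("map weights must be positive numbers")
  stats::setNames(w, nm)
}

#' Convert per-map CSV marker tables to the BED dialect
#'
#' Each CSV row is \code{scaffold_id,pos,linkage_group,map_pos}; the map name
#' is the CSV file name without extension.  Output round-trips losslessly
#' through \code{\link{read_marker_bed}}.
#'
#' @param csv_paths character vector of CSV files.
#' @param out output BED path.
#' @return \code{out}, invisibly.
#' @export
merge_csv_maps <- function(csv_paths, out) {
  all_lines <- character(0)
  for (p in csv_paths) {
    lines <- readLines(p)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) next
    parts <- strsplit(lines, ",", fixed = TRUE)
    if (any(vapply(parts, length, 0L) != 4L))
      stop("inconsistent column count in ", p, " (expected 4)")
    map <- sub("\\.[^.]*$", "", basename(p))
    pos <- as.integer(vapply(parts, `[[`, "", 2L))
    all_lines <- c(all_lines, sprintf(
      "%s\t%d\t%d\t%s-%s:%s", vapply(parts, `[[`, "", 1L), pos, pos + 1L,
      map, vapply(parts, `[[`, "", 3L), vapply(parts, `[[`, "", 4L)))
  }
  writeLines(all_lines, out)
  invisible(out)
}

#' Read scaffold lengths from a FASTA file
#'
#' @param fasta path to a (multi-)FASTA file of scaffolds.
#' @return named numeric vector of sequence lengths.
#' @export
read_scaffold_sizes <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  stats::setNames(as.numeric(Biostrings::width(seqs)), nm)
}

#' Read marker BED + weights (+ FASTA) into a MapCollection
#'
#' @param bed marker BED path.
#' @param weights_file optional weights file path.
#' @param fasta optional scaffold FASTA (for lengths).
#' @param scaffold_sizes optional named lengths (overrides \code{fasta}).
#' @return a \code{MapCollection}.
#' @export
read_map_collection <- function(bed, weights_file = NULL, fasta = NULL,
                                scaffold_sizes = NULL) {
  markers <- read_marker_bed(bed)
  w <- if (!is.null(weights_file)) read_weights(weights_file) else NULL
  if (is.null(scaffold_sizes) && !is.null(fasta))
    scaffold_sizes <- read_scaffold_sizes(fasta)
  map_collection(markers, weights = w, scaffold_sizes = scaffold_sizes)
}

#' Construct a scaffold configuration
#'
#' The optimization variable: an ordered, signed sequence of scaffolds making
#' up one chromosome.  Orientation +1 is forward, -1 reverse, and 0 means
#' undetermined (single-marker scaffolds); 0 scores as +1 and is reported as
#' "?" in AGP output.
#'
#' @param chrom chromosome identifier.
#' @param scaffolds character vector of unique scaffold ids, in order.
#' @param orientation integer vector in \{-1, 0, 1\}, recycled if length 1.
#' @return an object of class \code{ScaffoldConfiguration}.
#' @export
scaffold_configuration <- function(chrom, scaffolds,
                                   orientation = rep(1L, length(scaffolds))) {
  scaffolds <- as.character(scaffolds)
  if (length(orientation) == 1L)
    orientation <- rep(as.integer(orientation), length(scaffolds))
  orientation <- as.integer(orientation)
  if (anyDuplicated(scaffolds)) stop("duplicate scaffold in configuration")
  if (length(orientation) != length(scaffolds))
    stop("orientation length mismatch")
  if (length(orientation) && !all(orientation %in% c(-1L, 0L, 1L)))
    stop("orientation must be -1, 0 or +1")
  structure(list(chrom = as.character(chrom), scaffolds = scaffolds,
                 orientation = orientation),
            class = "ScaffoldConfiguration")
}

#' @export
print.ScaffoldConfiguration <- function(x, ...) {
  sgn <- c(`-1` = "-", `0` = "?", `1` = "+")[as.character(x$orientation)]
  cat("ScaffoldConfiguration", x$chrom, ":",
      paste0(sgn, x$scaffolds, collapse = " || "), "\n")
  invisible(x)
}

#' Reverse a configuration end-to-end
#'
#' Reverses the scaffold order and flips every determined orientation; the
#' L score is invariant under this global flip.
#'
#' @param config a \code{ScaffoldConfiguration}.
#' @return the reversed configuration.
#' @export
reverse_configuration <- function(config) {
  scaffold_configuration(config$chrom, rev(config$scaffolds),
                         -rev(config$orientation))
}
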