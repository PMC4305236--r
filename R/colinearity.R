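#' Longest monotonic subsequence
#'
#' Returns the larger of the longest non-decreasing and longest
#' non-increasing subsequence lengths of \code{x}.  Monotonicity is
#' non-strict: markers sharing one map position (the same recombination bin)
#' all extend a run, so dense maps with co-segregating markers are not
#' penalized.  Implemented by patience sorting with right-insertion binary
#' search, O(n log n).
#'
#' @param x numeric vector of map positions in physical order.
#' @return integer length of the LMS (0 for an empty vector).
#' @export
lms <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("lms requires finite values")
  lms_cpp(x)
}

# Build the per-chromosome scoring problem consumed by the C++ kernels:
# for each map, a list (over scaffolds, in `scaffolds` order) of map
# positions sorted by ascending physical position, plus the reversed lists
# and the weight vector.  Internal.
build_problem <- function(config_or_scaffolds, maps) {
  scaffolds <- if (inherits(config_or_scaffolds, "ScaffoldConfiguration"))
    config_or_scaffolds$scaffolds else as.character(config_or_scaffolds)
  mk <- maps$markers
  unknown <- setdiff(scaffolds, unique(mk$scaffold))
  if (!is.null(maps$scaffold_sizes))
    unknown <- setdiff(unknown, names(maps$scaffold_sizes))
  if (length(unknown))
    stop("unknown scaffold(s): ", paste(utils::head(unknown, 5),
                                        collapse = ", "))
  mk <- mk[mk$scaffold %in% scaffolds, , drop = FALSE]
  mk <- mk[order(match(mk$scaffold, scaffolds), mk$pos), , drop = FALSE]
  map_names <- maps$map_order[maps$map_order %in% unique(mk$map)]
  empty <- rep(list(numeric(0)), length(scaffolds))
  names(empty) <- scaffolds
  maps_fwd <- maps_rev <- vector("list", length(map_names))
  for (j in seq_along(map_names)) {
    sub <- mk[mk$map == map_names[j], , drop = FALSE]
    fwd <- empty
    got <- split(sub$map_pos, factor(sub$scaffold, levels = scaffolds))
    fwd[names(got)] <- got
    maps_fwd[[j]] <- fwd
    maps_rev[[j]] <- lapply(fwd, rev)
  }
  list(scaffolds = scaffolds, map_names = map_names,
       weights = unname(maps$weights[map_names]),
       maps_fwd = maps_fwd, maps_rev = maps_rev)
}

#' Score a scaffold configuration against all maps
#'
#' For each map, the markers of every scaffold are concatenated in
#' configuration order (ascending physical position within a forward
#' scaffold, descending within a reversed one; undetermined orientation
#' scores as forward) and the LMS of the resulting map-position sequence is
#' taken.  The total score is \code{L = sum_j w_j * LMS_j}.
#'
#' @param config a \code{ScaffoldConfiguration}.
#' @param maps a \code{MapCollection}.
#' @return list with \code{per_map} (data.frame of map, lms, weight) and
#'   \code{total} (the weighted score L).
#' @export
score_configuration <- function(config, maps) {
  pb <- build_problem(config, maps)
  n <- length(pb$scaffolds)
  perm <- seq_len(n)
  signs <- ifelse(config$orientation < 0, -1L, 1L)
  if (length(pb$map_names) == 0L) {
    return(list(per_map = data.frame(map = character(), lms = integer(),
                                     weight = numeric()), total = 0))
  }
  lens <- config_lms_cpp(perm, signs, pb$maps_fwd, pb$maps_rev)
  per_map <- data.frame(map = pb$map_names, lms = as.integer(lens),
                        weight = pb$weights, stringsAsFactors = FALSE)
  list(per_map = per_map, total = sum(per_map$weight * per_map$lms))
}

# all permutations of seq_len(n), in lexicographic order (internal)
all_permutations <- function(n) {
  if (n == 0L) return(list())
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (r in rest) {
      v <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, v[r])
    }
  }
  out
}

#' Exhaustive search for the best configuration (test oracle)
#'
#' Enumerates all \code{n! * 2^n} signed orderings of up to 8 scaffolds and
#' returns the configuration maximizing L.  Ties are broken by lexicographic
#' order of (permutation, signs with + before -), making the result
#' deterministic.  Intended as an independent oracle for small instances.
#'
#' @param scaffolds character vector of scaffold ids (length <= 8).
#' @param maps a \code{MapCollection}.
#' @param chrom chromosome id for the returned configuration.
#' @return the optimal \code{ScaffoldConfiguration}.
#' @export
best_configuration_bruteforce <- function(scaffolds, maps, chrom = "chr") {
  scaffolds <- as.character(scaffolds)
  n <- length(scaffolds)
  if (n > 8L) stop("brute force limited to 8 scaffolds")
  if (n == 0L) return(scaffold_configuration(chrom, character(0), integer(0)))
  pb <- build_problem(scaffolds, maps)
  perms <- all_permutations(n)
  sign_rows <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n),
                                     KEEP.OUT.ATTRS = FALSE))
  best <- NULL
  best_score <- -Inf
  for (p in perms) {
    for (r in seq_len(nrow(sign_rows))) {
      sg <- sign_rows[r, ]
      sc <- score_config_cpp(p, sg, pb$maps_fwd, pb$maps_rev, pb$weights)
      if (sc > best_score + 1e-9) {
        best_score <- sc
        best <- list(perm = p, signs = sg)
      }
    }
  }
  scaffold_configuration(chrom, scaffolds[best$perm],
                         unname(best$signs[best$perm]))
}
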