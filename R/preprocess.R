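#' Select the pivot map
#'
#' The pivot map is the map with the largest weight; ties are broken by
#' first occurrence in the user input order.  The pivot's linkage groups
#' seed the chromosome clusters and therefore fix the chromosome count of
#' the final assembly.
#'
#' @param maps a \code{MapCollection}.
#' @return the pivot map name.
#' @export
select_pivot <- function(maps) {
  if (!length(maps$map_order)) stop("empty map collection")
  w <- maps$weights[maps$map_order]
  maps$map_order[which.max(w)]
}

#' Cluster homologous linkage groups across maps
#'
#' One cluster is seeded per pivot-map linkage group.  Every linkage group
#' of every non-pivot map joins the cluster with which it shares the most
#' scaffolds; ties go to the earlier cluster.  Groups sharing no scaffold
#' with any cluster are left unassigned with a warning.
#'
#' @param maps a \code{MapCollection}.
#' @param pivot pivot map name (default: \code{\link{select_pivot}}).
#' @return object of class \code{LinkageClustering}: \code{pivot}, a list
#'   \code{clusters} (each with \code{chrom}, \code{members} data.frame of
#'   map/lg), and \code{unassigned} members.
#' @export
cluster_linkage_groups <- function(maps, pivot = select_pivot(maps)) {
  mk <- maps$markers
  pivot_lgs <- unique(mk$lg[mk$map == pivot])
  clusters <- lapply(pivot_lgs, function(lg) {
    list(chrom = lg,
         members = data.frame(map = pivot, lg = lg, stringsAsFactors = FALSE),
         scaffolds = character(0), chimeric = character(0))
  })
  cluster_scaffolds <- lapply(pivot_lgs, function(lg)
    unique(mk$scaffold[mk$map == pivot & mk$lg == lg]))
  unassigned <- data.frame(map = character(), lg = character(),
                           stringsAsFactors = FALSE)
  for (m in setdiff(maps$map_order, pivot)) {
    for (lg in unique(mk$lg[mk$map == m])) {
      scafs <- unique(mk$scaffold[mk$map == m & mk$lg == lg])
      shared <- vapply(cluster_scaffolds, function(cs)
        length(intersect(scafs, cs)), 0L)
      if (!length(shared) || max(shared) == 0L) {
        warning("linkage group ", m, "-", lg,
                " shares no scaffolds with any cluster; left unassigned")
        unassigned <- rbind(unassigned,
                            data.frame(map = m, lg = lg,
                                       stringsAsFactors = FALSE))
        next
      }
      k <- which.max(shared) # ties -> first cluster
      clusters[[k]]$members <- rbind(
        clusters[[k]]$members,
        data.frame(map = m, lg = lg, stringsAsFactors = FALSE))
    }
  }
  structure(list(pivot = pivot, clusters = clusters,
                 unassigned = unassigned),
            class = "LinkageClustering")
}

#' Assign scaffolds to linkage-group clusters
#'
#' Each scaffold is assigned to the cluster maximizing its weighted marker
#' count \code{sum_j w_j * |markers on (scaffold, member lg of cluster,
#' map j)|}.  Scaffolds whose maximum is attained by two or more clusters
#' have equally good mappings to multiple chromosomes: they are flagged
#' chimeric, excluded from all clusters, and reported.  Equality is exact
#' (no tolerance) since the counts are integer-weighted sums.
#'
#' @param clustering a \code{LinkageClustering}.
#' @param maps a \code{MapCollection}.
#' @return the clustering with per-cluster \code{scaffolds} filled in and a
#'   top-level \code{chimeric} character vector.
#' @export
assign_scaffolds <- function(clustering, maps) {
  mk <- maps$markers
  ncl <- length(clustering$clusters)
  member_key <- lapply(clustering$clusters, function(cl)
    paste(cl$members$map, cl$members$lg, sep = "\r"))
  mk_key <- paste(mk$map, mk$lg, sep = "\r")
  mk_w <- unname(maps$weights[mk$map])
  counts <- matrix(0, nrow = length(unique(mk$scaffold)), ncol = ncl,
                   dimnames = list(unique(mk$scaffold), NULL))
  for (k in seq_len(ncl)) {
    in_cl <- mk_key %in% member_key[[k]]
    if (!any(in_cl)) next
    tab <- tapply(mk_w[in_cl], mk$scaffold[in_cl], sum)
    counts[names(tab), k] <- tab
  }
  chimeric <- character(0)
  assigned <- vector("list", ncl)
  for (s in rownames(counts)) {
    row <- counts[s, ]
    mx <- max(row)
    if (mx == 0) next # markers only in unassigned groups
    hits <- which(row == mx)
    if (length(hits) > 1L) {
      chimeric <- c(chimeric, s)
    } else {
      assigned[[hits]] <- c(assigned[[hits]], s)
    }
  }
  if (length(chimeric))
    warning("chimeric scaffold(s) with equally good mappings to multiple ",
            "linkage clusters skipped: ",
            paste(utils::head(chimeric, 10), collapse = ", "))
  for (k in seq_len(ncl)) {
    clustering$clusters[[k]]$scaffolds <- assigned[[k]] %||% character(0)
    clustering$clusters[[k]]$chimeric <- chimeric
  }
  clustering$chimeric <- chimeric
  clustering
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Modified z-score outlier flags
#'
#' Iglewicz-Hoaglin test: \code{z_i = 0.6745 * (y_i - median) / MAD}; values
#' with \code{|z_i| > cutoff} are outliers.  With fewer than 3 values or a
#' zero MAD nothing is flagged.
#'
#' @param y numeric vector (map positions).
#' @param cutoff flag threshold, default 3.5.
#' @param constant scale constant, default 0.6745 (normal consistency).
#' @return logical vector: TRUE marks an outlier.
#' @export
outlier_flags <- function(y, cutoff = 3.5, constant = 0.6745) {
  n <- length(y)
  if (n < 3L) return(rep(FALSE, n))
  med <- stats::median(y)
  mad0 <- stats::median(abs(y - med))
  if (mad0 == 0) return(rep(FALSE, n))
  abs(constant * (y - med) / mad0) > cutoff
}

#' Remove erratic markers from one scaffold/linkage-group pairing
#'
#' @param markers marker data.frame from a single (scaffold, map, lg) group.
#' @param cutoff,constant see \code{\link{outlier_flags}}.
#' @return the markers with outliers removed.
#' @export
remove_outlier_markers <- function(markers, cutoff = 3.5, constant = 0.6745) {
  keep <- !outlier_flags(markers$map_pos, cutoff, constant)
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop erratic markers across a whole collection
#'
#' Applies the modified z-score test per (scaffold, map, linkage group)
#' group and removes flagged markers.  Idempotent in practice for cleanly
#' separated outliers (a second pass removes nothing).
#'
#' @param maps a \code{MapCollection}.
#' @param cutoff,constant see \code{\link{outlier_flags}}.
#' @return list with the filtered \code{maps} and a data.frame
#'   \code{removed} of dropped markers.
#' @export
filter_map_outliers <- function(maps, cutoff = 3.5, constant = 0.6745) {
  mk <- maps$markers
  if (!nrow(mk)) return(list(maps = maps, removed = mk))
  grp <- paste(mk$scaffold, mk$map, mk$lg, sep = "\r")
  drop <- logical(nrow(mk))
  for (idx in split(seq_len(nrow(mk)), grp))
    drop[idx] <- outlier_flags(mk$map_pos[idx], cutoff, constant)
  filtered <- map_collection(mk[!drop, , drop = FALSE],
                             weights = maps$weights,
                             scaffold_sizes = maps$scaffold_sizes,
                             map_order = maps$map_order)
  list(maps = filtered, removed = mk[drop, , drop = FALSE])
}

#' Preprocess a map collection into per-chromosome sub-problems
#'
#' Runs pivot selection, linkage-group clustering, scaffold assignment with
#' chimera alerts, and outlier-marker removal, and emits a text report.
#'
#' @param maps a \code{MapCollection}.
#' @param cutoff,constant outlier-test parameters.
#' @param report_file optional path for the text report.
#' @return list: \code{maps} (filtered), \code{clustering},
#'   \code{removed_markers}, \code{report} (character lines).
#' @export
preprocess_maps <- function(maps, cutoff = 3.5, constant = 0.6745,
                            report_file = NULL) {
  clustering <- assign_scaffolds(cluster_linkage_groups(maps), maps)
  filt <- filter_map_outliers(maps, cutoff, constant)
  report <- c(
    sprintf("pivot map: %s", clustering$pivot),
    sprintf("clusters: %d", length(clustering$clusters)),
    vapply(clustering$clusters, function(cl)
      sprintf("  %s: members [%s]; %d scaffolds", cl$chrom,
              paste(cl$members$map, cl$members$lg, sep = "-",
                    collapse = ", "),
              length(cl$scaffolds)), ""),
    sprintf("chimeric scaffolds skipped: %d%s", length(clustering$chimeric),
            if (length(clustering$chimeric))
              paste0(" (", paste(clustering$chimeric, collapse = ", "), ")")
            else ""),
    sprintf("unassigned linkage groups: %d", nrow(clustering$unassigned)),
    sprintf("outlier markers removed: %d", nrow(filt$removed)))
  if (!is.null(report_file)) writeLines(report, report_file)
  list(maps = filt$maps, clustering = clustering,
       removed_markers = filt$removed, report = report)
}
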