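# Independent oracles used to freeze expected values.  Deliberately naive
# implementations that share no code with the package internals.

# longest monotonic subsequence by full enumeration of all 2^n subsequences
oracle_lms_enum <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) <= best) next
    s <- x[idx]
    if (all(diff(s) >= 0) || all(diff(s) <= 0)) best <- length(idx)
  }
  best
}

# all permutations of 1..n as a matrix, one row each
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# exact minimum Hamiltonian-path cost by enumeration
oracle_tsp_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  P <- oracle_perms(n)
  costs <- rep(0, nrow(P))
  for (k in seq_len(n - 1L))
    costs <- costs + D[cbind(P[, k], P[, k + 1L])]
  min(costs)
}

path_cost <- function(D, ord) {
  if (length(ord) < 2L) return(0)
  sum(D[cbind(ord[-length(ord)], ord[-1L])])
}

# maximum L over every signed ordering, via the package scorer only
# (enumeration logic is the test's own)
oracle_best_L <- function(scaffolds, maps) {
  n <- length(scaffolds)
  P <- oracle_perms(n)
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  best <- -Inf
  for (r in seq_len(nrow(P))) {
    for (s in seq_len(nrow(signs))) {
      cfg <- scaffold_configuration("chr", scaffolds[P[r, ]],
                                    signs[s, ][P[r, ]])
      sc <- score_configuration(cfg, maps)$total
      if (sc > best) best <- sc
    }
  }
  best
}

# a random small anchoring instance: n_scaf scaffolds laid along one
# chromosome, markers from n_maps maps with jittered positions
random_tiny_instance <- function(n_scaf = 4L, n_maps = 2L,
                                 markers_per_scaf = 3L, noise = 0.05) {
  rows <- list()
  sizes <- stats::setNames(rep(1000L, n_scaf), paste0("s", seq_len(n_scaf)))
  for (j in seq_len(n_maps)) {
    for (i in seq_len(n_scaf)) {
      k <- sample(0:markers_per_scaf, 1L)
      if (k == 0L) next
      pos <- sort(sample.int(999L, k))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = paste0("s", i), pos = pos, map = paste0("m", j),
        lg = "1", map_pos = (i - 1) + pos / 1000 +
          stats::rnorm(k, 0, noise),
        stringsAsFactors = FALSE)
    }
  }
  markers <- do.call(rbind, rows)
  map_collection(markers, scaffold_sizes = sizes,
                 map_order = paste0("m", seq_len(n_maps)))
}

# markers forming a perfectly collinear single map over given scaffolds
collinear_maps <- function(n_scaf = 3L, markers_per_scaf = 3L,
                           scaf_len = 1000L) {
  rows <- list()
  for (i in seq_len(n_scaf)) {
    pos <- round(seq(100, scaf_len - 100, length.out = markers_per_scaf))
    rows[[i]] <- data.frame(
      scaffold = paste0("s", i), pos = pos, map = "m1", lg = "1",
      map_pos = (i - 1) * scaf_len + pos, stringsAsFactors = FALSE)
  }
  map_collection(do.call(rbind, rows),
                 scaffold_sizes = stats::setNames(
                   rep(scaf_len, n_scaf), paste0("s", seq_len(n_scaf))))
}
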