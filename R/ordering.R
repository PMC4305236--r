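#' Relative orientation score between two scaffolds
#'
#' \code{o(a,b) = sum_j w_j * [LMS(a||b) - LMS(a||-b)]}: positive means the
#' two scaffolds are colinear in the same orientation, negative in opposite
#' orientations, zero undetermined (e.g. single-marker scaffolds or no
#' shared map).  Each orientation family is evaluated in both concatenation
#' orders (the better of \code{a||b} and \code{b||a}, versus the better of
#' \code{a||-b} and \code{-a||b}), which makes the score symmetric in its
#' arguments and independent of the arbitrary map polarity.
#'
#' @param a,b scaffold ids.
#' @param maps a \code{MapCollection} restricted to one chromosome.
#' @return numeric score.
#' @export
orientation_score <- function(a, b, maps) {
  pb <- build_problem(c(a, b), maps)
  o_pair(pb, 1L, 2L)
}

# o(a,b) from a prebuilt problem, scaffold indices ia/ib (internal).
# The concatenation a||b reads the pair in one direction only, which
# mis-signs pairs lying against the map's polarity; both readings of each
# orientation family are evaluated (b||a reverses to -a||-b, so the two
# same-orientation readings cover all four sign combinations), making
# o(a,b) == o(b,a) genuinely symmetric.
o_pair <- function(pb, ia, ib) {
  s <- 0
  for (j in seq_along(pb$map_names)) {
    fa <- pb$maps_fwd[[j]][[ia]]
    fb <- pb$maps_fwd[[j]][[ib]]
    if (!length(fa) || !length(fb)) next
    ra <- pb$maps_rev[[j]][[ia]]
    rb <- pb$maps_rev[[j]][[ib]]
    same <- max(lms_cpp(c(fa, fb)), lms_cpp(c(fb, fa)))
    opp <- max(lms_cpp(c(fa, rb)), lms_cpp(c(ra, fb)))
    s <- s + pb$weights[j] * (same - opp)
  }
  s
}

#' Pairwise orientation matrix
#'
#' Square symmetric matrix with \code{M[a,b] = o(a,b)} and zero diagonal;
#' the signs of its leading eigenvector orient the scaffolds.
#'
#' @param scaffolds scaffold ids (rows/columns, in order).
#' @param maps a \code{MapCollection} restricted to one chromosome.
#' @return numeric matrix with dimnames.
#' @export
orientation_matrix <- function(scaffolds, maps) {
  scaffolds <- as.character(scaffolds)
  n <- length(scaffolds)
  pb <- build_problem(scaffolds, maps)
  M <- matrix(0, n, n, dimnames = list(scaffolds, scaffolds))
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        M[a, b] <- M[b, a] <- o_pair(pb, a, b)
      }
    }
  }
  M
}

#' Orient scaffolds from the leading eigenvector
#'
#' Computes the eigenvector of the largest (algebraic) eigenvalue of the
#' pairwise orientation matrix; the component signs give a globally
#' consistent flipping of the scaffolds.  Components with magnitude below
#' \code{tol} are undetermined (0).  The global sign is fixed so the first
#' nonzero component is positive (the overall polarity is arbitrary).
#'
#' @param M orientation matrix (square, symmetric).
#' @param tol magnitude below which a component's sign is undetermined.
#' @return integer vector of signs in \{-1, 0, 1\}.
#' @export
orient_by_eigenvector <- function(M, tol = 1e-9) {
  n <- nrow(M)
  if (n == 0L) return(integer(0))
  if (all(M == 0)) return(rep(0L, n))
  y <- eigen(M, symmetric = TRUE)$vectors[, 1L]
  s <- ifelse(abs(y) < tol, 0L, ifelse(y > 0, 1L, -1L))
  nz <- which(s != 0L)
  if (length(nz) && s[nz[1L]] < 0L) s <- -s
  as.integer(s)
}

#' Pairwise scaffold distance
#'
#' \code{d(a,b) = sum_j w_j * min_{x in M_aj, y in M_bj} |x - y|}, the
#' weighted closest-marker distance in map units.  Maps on which either
#' scaffold has no markers contribute \code{penalty} (default: that map's
#' position span in the sub-problem) so that absent evidence neither
#' attracts nor repels strongly.
#'
#' @param a,b scaffold ids.
#' @param maps a \code{MapCollection} restricted to one chromosome.
#' @param penalty per-map penalty for missing markers; a single number, a
#'   vector named by map, or NULL for the span default.
#' @return nonnegative numeric distance.
#' @export
pairwise_distance <- function(a, b, maps, penalty = NULL) {
  if (identical(a, b)) return(0)
  D <- distance_matrix(c(a, b), maps, penalty)
  D[1L, 2L]
}

#' Pairwise distance matrix for a set of scaffolds
#'
#' @inheritParams pairwise_distance
#' @param scaffolds scaffold ids.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(scaffolds, maps, penalty = NULL) {
  scaffolds <- as.character(scaffolds)
  n <- length(scaffolds)
  pb <- build_problem(scaffolds, maps)
  nm <- length(pb$map_names)
  pen <- numeric(nm)
  for (j in seq_len(nm)) {
    # span of the whole linkage group (full collection), not just the
    # scaffolds under consideration
    allpos <- maps$markers$map_pos[maps$markers$map == pb$map_names[j]]
    pen[j] <- if (length(allpos)) diff(range(allpos)) else 0
  }
  if (!is.null(penalty)) {
    if (!is.null(names(penalty))) {
      hit <- intersect(names(penalty), pb$map_names)
      pen[match(hit, pb$map_names)] <- penalty[hit]
    } else pen[] <- penalty
  }
  D <- matrix(0, n, n, dimnames = list(scaffolds, scaffolds))
  if (n < 2L) return(D)
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      d <- 0
      for (j in seq_len(nm)) {
        xa <- pb$maps_fwd[[j]][[a]]
        xb <- pb$maps_fwd[[j]][[b]]
        d <- d + pb$weights[j] *
          (if (!length(xa) || !length(xb)) pen[j]
           else min(abs(outer(xa, xb, `-`))))
      }
      D[a, b] <- D[b, a] <- d
    }
  }
  D
}

#' Initial scaffold order by travelling-salesman heuristic
#'
#' Finds a Hamiltonian path minimizing the sum of adjacent pairwise
#' distances.  The path problem is reduced to a cyclic tour by a dummy node
#' at distance zero to every scaffold, then solved with nearest-neighbour
#' construction plus 2-opt and Or-opt improvement to local optimality.
#' Deterministic given the input order.  The result seeds Phase 2, which
#' refines it against the true L objective, so local (not exact) optimality
#' suffices here.
#'
#' @param D symmetric distance matrix.
#' @param solver optional function(D) returning a permutation, to plug in an
#'   external exact solver.
#' @return integer permutation of \code{seq_len(nrow(D))}.
#' @export
initial_order <- function(D, solver = NULL) {
  if (!is.null(solver)) return(as.integer(solver(D)))
  as.integer(tsp_path_cpp(as.matrix(D)))
}

#' Greedy orientation refinement
#'
#' Sweeps through the scaffolds, flipping any single scaffold whose flip
#' strictly increases L, and repeats until a full sweep changes nothing.
#' Undetermined orientations (0) stay undetermined (a flip cannot strictly
#' improve a single-marker scaffold).
#'
#' @param config a \code{ScaffoldConfiguration}.
#' @param maps a \code{MapCollection}.
#' @return the refined configuration (L never decreases).
#' @export
flip_pass <- function(config, maps) {
  pb <- build_problem(config, maps)
  n <- length(pb$scaffolds)
  if (n == 0L || !length(pb$map_names)) return(config)
  perm <- seq_len(n)
  signs <- ifelse(config$orientation < 0, -1L, 1L)
  cur <- score_config_cpp(perm, signs, pb$maps_fwd, pb$maps_rev, pb$weights)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (config$orientation[i] == 0L) next
      trial <- signs
      trial[i] <- -trial[i]
      sc <- score_config_cpp(perm, trial, pb$maps_fwd, pb$maps_rev,
                             pb$weights)
      if (sc > cur + 1e-9) {
        signs <- trial
        cur <- sc
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  scaffold_configuration(config$chrom, config$scaffolds,
                         ifelse(config$orientation == 0L, 0L, signs))
}

# one GA round over signed permutations: each individual carries a scaffold
# permutation plus a per-scaffold sign vector (canonical index).  The
# inversion mutation reverses a stretch AND flips its orientations, as a
# biological inversion would, so order and orientation are searched
# jointly; insertion translocates a single scaffold, sign unchanged.
# Returns the best permutation, sign vector and fitness.
ga_round <- function(pb, signs0, init_perm, npop, ngen, mutpb, cxpb,
                     maxgen) {
  n <- length(pb$scaffolds)
  pop <- matrix(rep(init_perm, npop), nrow = npop, byrow = TRUE)
  sgn <- matrix(rep(signs0, npop), nrow = npop, byrow = TRUE)
  fit <- score_population_signed_cpp(pop, sgn, pb$maps_fwd, pb$maps_rev,
                                     pb$weights)
  best_perm <- pop[1L, ]
  best_sign <- sgn[1L, ]
  best_fit <- fit[1L]
  stall <- 0L
  gen <- 0L
  while (stall < ngen && gen < maxgen) {
    gen <- gen + 1L
    # tournament selection, size 3
    sel <- matrix(sample.int(npop, 3L * npop, replace = TRUE), ncol = 3L)
    pick <- sel[cbind(seq_len(npop),
                      max.col(matrix(fit[sel], ncol = 3L),
                              ties.method = "first"))]
    newpop <- pop[pick, , drop = FALSE]
    newsgn <- sgn[pick, , drop = FALSE]
    if (n >= 2L) {
      # PMX crossover on consecutive pairs; signs travel with the scaffold
      # from their own parent
      for (i in seq(1L, npop - 1L, by = 2L)) {
        if (stats::runif(1) < cxpb) {
          cut <- sort(sample.int(n, 2L))
          p1 <- newpop[i, ]; p2 <- newpop[i + 1L, ]
          newpop[i, ] <- pmx_cpp(p1, p2, cut[1L], cut[2L])
          newpop[i + 1L, ] <- pmx_cpp(p2, p1, cut[1L], cut[2L])
        }
      }
      # mutation: inversion or insertion with equal odds when firing
      for (i in seq_len(npop)) {
        if (stats::runif(1) < mutpb) {
          if (stats::runif(1) < 0.5) {
            cut <- sort(sample.int(n, 2L))
            seg <- cut[1L]:cut[2L]
            newpop[i, seg] <- rev(newpop[i, seg])
            newsgn[i, newpop[i, seg]] <- -newsgn[i, newpop[i, seg]]
          } else {
            from <- sample.int(n, 1L)
            rest <- newpop[i, -from]
            at <- sample.int(n, 1L)
            newpop[i, ] <- append(rest, newpop[i, from], after = at - 1L)
          }
        }
      }
    }
    fit <- score_population_signed_cpp(newpop, newsgn, pb$maps_fwd,
                                       pb$maps_rev, pb$weights)
    # elitism of 1: overall best replaces this generation's worst
    worst <- which.min(fit)
    if (fit[worst] < best_fit) {
      newpop[worst, ] <- best_perm
      newsgn[worst, ] <- best_sign
      fit[worst] <- best_fit
    }
    pop <- newpop
    sgn <- newsgn
    gb <- which.max(fit)
    if (fit[gb] > best_fit + 1e-9) {
      best_fit <- fit[gb]
      best_perm <- pop[gb, ]
      best_sign <- sgn[gb, ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  list(perm = best_perm, signs = best_sign, fit = best_fit)
}

#' Genetic-algorithm refinement of a scaffold configuration
#'
#' Phase 2: an elitist generational GA over scaffold permutations, seeded
#' entirely with the Phase-1 configuration.  Mutations are 'inversion'
#' (reverse a random stretch) and 'insertion' (translocate one scaffold),
#' recombination is partially mapped crossover (PMX), selection is
#' tournament of 3 with elitism of 1, and fitness is the weighted
#' colinearity score L.  The GA runs until the best solution is unchanged
#' for \code{ngen} generations, then a greedy flip pass re-optimizes
#' orientations; order-then-flip rounds repeat until L stops improving.
#' Order and orientation are intertwined, so several rounds are sometimes
#' needed.
#'
#' @param config starting \code{ScaffoldConfiguration} (typically Phase 1).
#' @param maps a \code{MapCollection} restricted to one chromosome.
#' @param npop population size (default 100).
#' @param ngen convergence window: stop a round after this many generations
#'   without improvement (default 1000).
#' @param mutpb,cxpb mutation and crossover probabilities (defaults 0.2 and
#'   0.7).
#' @param seed optional integer seed; identical seed and inputs give
#'   identical output.
#' @param maxgen hard per-round generation cap.
#' @return refined configuration with \code{L(result) >= L(config)}.
#' @export
ga_refine <- function(config, maps, npop = 100L, ngen = 1000L, mutpb = 0.2,
                      cxpb = 0.7, seed = NULL, maxgen = 100000L) {
  if (mutpb < 0 || mutpb > 1 || cxpb < 0 || cxpb > 1)
    stop("mutation/crossover probabilities must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (length(config$scaffolds) < 2L) return(config)
  cur <- config
  cur_L <- score_configuration(cur, maps)$total
  repeat {
    pb <- build_problem(cur, maps)
    if (!length(pb$map_names)) return(cur)
    signs0 <- ifelse(cur$orientation < 0, -1L, 1L)
    res <- ga_round(pb, signs0, seq_along(cur$scaffolds), npop, ngen,
                    mutpb, cxpb, maxgen)
    new_ori <- res$signs
    new_ori[cur$orientation == 0L] <- 0L # undetermined stays undetermined
    reordered <- scaffold_configuration(cur$chrom,
                                        cur$scaffolds[res$perm],
                                        new_ori[res$perm])
    flipped <- flip_pass(reordered, maps)
    new_L <- score_configuration(flipped, maps)$total
    if (new_L > cur_L + 1e-9) {
      cur <- flipped
      cur_L <- new_L
    } else {
      if (new_L >= cur_L - 1e-9) cur <- flipped
      break
    }
  }
  cur
}

#' Canonical polarity for a chromosome configuration
#'
#' L is invariant under reversing a whole chromosome; for reproducible
#' output the configuration is reported with the pivot map's longest run
#' realized as increasing where possible.
#'
#' @param config a \code{ScaffoldConfiguration}.
#' @param maps a \code{MapCollection}.
#' @param pivot pivot map name.
#' @return \code{config} or its global reversal.
#' @export
canonicalize_configuration <- function(config, maps,
                                       pivot = select_pivot(maps)) {
  pb <- build_problem(config, maps)
  j <- match(pivot, pb$map_names)
  if (is.na(j)) return(config)
  seqs <- lapply(seq_along(config$scaffolds), function(i)
    if (config$orientation[i] < 0) pb$maps_rev[[j]][[i]]
    else pb$maps_fwd[[j]][[i]])
  y <- unlist(seqs, use.names = FALSE)
  if (!length(y)) return(config)
  inc <- lnds_cpp(y)
  dec <- lnds_cpp(-y)
  if (dec <= inc) return(config)
  flipped <- reverse_configuration(config)
  # reversal is L-invariant for well-formed configurations (orientation 0
  # only where flipping is irrelevant); guard against degrading L anyway
  if (score_configuration(flipped, maps)$total + 1e-9 <
      score_configuration(config, maps)$total) config else flipped
}

#' Order and orient the scaffolds of one chromosome
#'
#' The full two-phase optimizer for a single chromosome sub-problem:
#' Phase 1 computes initial orientations from the leading eigenvector of
#' the pairwise orientation matrix and an initial order from the
#' travelling-salesman heuristic over closest-marker distances; Phase 2
#' refines both with the genetic algorithm and greedy flip passes.
#'
#' @param scaffolds scaffold ids belonging to the chromosome.
#' @param maps a \code{MapCollection} restricted to the chromosome's
#'   markers.
#' @param chrom chromosome id.
#' @param seed optional integer seed for the GA.
#' @param npop,ngen,mutpb,cxpb GA parameters, see \code{\link{ga_refine}}.
#' @param phase1 set FALSE to skip Phase 1 (identity start).
#' @param canonical set FALSE to skip polarity canonicalization.
#' @param pivot pivot map used for canonical polarity.
#' @return the optimized \code{ScaffoldConfiguration}.
#' @export
order_chromosome <- function(scaffolds, maps, chrom = "chr", seed = NULL,
                             npop = 100L, ngen = 1000L, mutpb = 0.2,
                             cxpb = 0.7, phase1 = TRUE, canonical = TRUE,
                             pivot = select_pivot(maps)) {
  scaffolds <- as.character(scaffolds)
  n <- length(scaffolds)
  if (n == 0L)
    return(scaffold_configuration(chrom, character(0), integer(0)))
  # a scaffold with at most one marker on every map has no orientation
  # signal at all: it keeps orientation 0 throughout and is reported "?"
  cnt <- table(factor(maps$markers$scaffold, levels = scaffolds),
               maps$markers$map)
  single <- if (ncol(cnt)) apply(cnt, 1L, max)[scaffolds] <= 1L
            else rep(TRUE, n)
  if (phase1 && n >= 2L) {
    M <- orientation_matrix(scaffolds, maps)
    signs <- orient_by_eigenvector(M)
    D <- distance_matrix(scaffolds, maps)
    perm <- initial_order(D)
  } else {
    signs <- rep(1L, n)
    perm <- seq_len(n)
  }
  signs[single] <- 0L
  # determinable scaffolds with a zero eigenvector component start forward
  # and are refined by the flip pass and the GA
  signs[!single & signs == 0L] <- 1L
  init <- scaffold_configuration(chrom, scaffolds[perm], signs[perm])
  init <- flip_pass(init, maps)
  out <- ga_refine(init, maps, npop = npop, ngen = ngen, mutpb = mutpb,
                   cxpb = cxpb, seed = seed)
  if (canonical) out <- canonicalize_configuration(out, maps, pivot)
  attr(out, "L_initial") <- score_configuration(init, maps)$total
  attr(out, "L_final") <- score_configuration(out, maps)$total
  out
}

#' Restrict a MapCollection to one linkage cluster
#'
#' Keeps only markers on the cluster's member (map, linkage group) pairs
#' and assigned scaffolds.
#'
#' @param maps a \code{MapCollection}.
#' @param cluster one element of \code{LinkageClustering$clusters}.
#' @return a reduced \code{MapCollection}.
#' @export
subset_cluster_maps <- function(maps, cluster) {
  mk <- maps$markers
  key <- paste(mk$map, mk$lg, sep = "\r")
  member_key <- paste(cluster$members$map, cluster$members$lg, sep = "\r")
  keep <- key %in% member_key & mk$scaffold %in% cluster$scaffolds
  map_collection(mk[keep, , drop = FALSE], weights = maps$weights,
                 scaffold_sizes = maps$scaffold_sizes,
                 map_order = maps$map_order)
}

#' Anchor all chromosomes of a preprocessed problem
#'
#' Runs \code{\link{order_chromosome}} for every linkage cluster and
#' returns the per-chromosome configurations.
#'
#' @param prep result of \code{\link{preprocess_maps}}.
#' @param seed integer seed; chromosome k uses \code{seed + k} so runs are
#'   reproducible yet independent.
#' @param ... passed to \code{\link{order_chromosome}}.
#' @return named list of \code{ScaffoldConfiguration}s.
#' @export
anchor_scaffolds <- function(prep, seed = NULL, ...) {
  configs <- list()
  for (k in seq_along(prep$clustering$clusters)) {
    cl <- prep$clustering$clusters[[k]]
    sub <- subset_cluster_maps(prep$maps, cl)
    scafs <- intersect(unique(sub$markers$scaffold), cl$scaffolds)
    cfg <- order_chromosome(scafs, sub, chrom = cl$chrom,
                            seed = if (is.null(seed)) NULL else seed + k,
                            pivot = prep$clustering$pivot, ...)
    configs[[cl$chrom]] <- cfg
  }
  configs
}
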