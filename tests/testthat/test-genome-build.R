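random_seqs <- function(lens) {
  out <- Biostrings::DNAStringSet(vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    ""))
  names(out) <- names(lens)
  out
}

test_that("build example: lengths, AGP rows, reverse complement", {
  set.seed(41)
  seqs <- random_seqs(c(s1 = 10L, s2 = 20L))
  cfg <- scaffold_configuration("chr1", c("s1", "s2"), c(1L, -1L))
  b <- build_genome(list(cfg), seqs, gap_size = 100)
  expect_equal(unname(Biostrings::width(b$seqs["chr1"])), 130L)
  a <- b$agp[b$agp$object == "chr1", ]
  expect_equal(a$component_type, c("W", "U", "W"))
  expect_equal(a$object_beg, c(1, 11, 111))
  expect_equal(a$object_end, c(10, 110, 130))
  expect_equal(a$col9, c("+", "map", "-"))
  expect_equal(a$col6[2], "100")
  expect_equal(a[2, c("col7", "col8")], data.frame(col7 = "scaffold",
                                                   col8 = "yes", row.names = 2L),
               ignore_attr = TRUE)
  chr <- as.character(b$seqs[["chr1"]])
  expect_equal(substr(chr, 1, 10), as.character(seqs[["s1"]]))
  expect_equal(substr(chr, 11, 110), strrep("N", 100))
  expect_equal(substr(chr, 111, 130),
               as.character(Biostrings::reverseComplement(seqs[["s2"]])))
})

test_that("undetermined orientation becomes '?' and forward sequence", {
  seqs <- random_seqs(c(s1 = 10L, s2 = 12L))
  cfg <- scaffold_configuration("chr1", c("s1", "s2"), c(1L, 0L))
  b <- build_genome(list(cfg), seqs)
  a <- b$agp[b$agp$component_type == "W" & b$agp$col6 == "s2", ]
  expect_equal(a$col9, "?")
  expect_equal(substr(as.character(b$seqs[["chr1"]]), 111, 122),
               as.character(seqs[["s2"]]))
})

test_that("unanchored scaffolds pass through; errors on bad input", {
  seqs <- random_seqs(c(s1 = 10L, s2 = 20L, lone = 7L))
  cfg <- scaffold_configuration("chr1", c("s1", "s2"), 1L)
  b <- build_genome(list(cfg), seqs)
  expect_true("lone" %in% names(b$seqs))
  expect_equal(as.character(b$seqs[["lone"]]), as.character(seqs[["lone"]]))
  expect_equal(b$agp$object_end[b$agp$object == "lone"], 7)
  expect_error(build_genome(list(scaffold_configuration("c", "ghost")),
                            seqs), "missing")
  dup <- list(scaffold_configuration("c1", "s1"),
              scaffold_configuration("c2", "s1"))
  expect_error(build_genome(dup, seqs), "more than once")
})

test_that("AGP spans tile each chromosome without overlap", {
  set.seed(42)
  seqs <- random_seqs(stats::setNames(sample(50:200, 6L), paste0("s", 1:6)))
  cfgs <- list(scaffold_configuration("chr1", c("s1", "s3", "s5"),
                                      c(1L, -1L, 0L)),
               scaffold_configuration("chr2", c("s2", "s6"), c(-1L, 1L)))
  b <- build_genome(cfgs, seqs, gap_size = 37)
  for (ch in c("chr1", "chr2")) {
    a <- b$agp[b$agp$object == ch, ]
    a <- a[order(a$object_beg), ]
    expect_equal(a$object_beg[1], 1)
    expect_equal(a$object_beg[-1], a$object_end[-nrow(a)] + 1)
    expect_equal(a$object_end[nrow(a)],
                 unname(Biostrings::width(b$seqs[ch])))
    expect_equal(sum(a$object_end - a$object_beg + 1),
                 unname(Biostrings::width(b$seqs[ch])))
  }
})

test_that("CHAIN liftOver round trip is base-exact", {
  set.seed(43)
  seqs <- random_seqs(stats::setNames(sample(60:150, 5L), paste0("s", 1:5)))
  cfgs <- list(scaffold_configuration("chr1", c("s2", "s4"), c(1L, -1L)),
               scaffold_configuration("chr2", c("s1", "s5", "s3"),
                                      c(-1L, 0L, 1L)))
  b <- build_genome(cfgs, seqs, gap_size = 55)
  # parse the chain text independently
  heads <- strsplit(b$chain[grepl("^chain ", b$chain)], " ")
  for (h in heads) {
    # chain score tName tSize tStrand tStart tEnd qName qSize qStrand ...
    tName <- h[3]; tStart <- as.integer(h[6])
    qName <- h[8]; qSize <- as.integer(h[9]); qStrand <- h[10]
    qlen <- as.integer(h[7]) - as.integer(h[6])
    expect_equal(qSize, qlen) # single full-length block
    for (p in sample.int(qSize, 25L) - 1L) {
      chrom_pos <- if (qStrand == "-") tStart + (qSize - 1L - p)
                   else tStart + p
      got <- substr(as.character(b$seqs[[tName]]), chrom_pos + 1L,
                    chrom_pos + 1L)
      orig <- substr(as.character(seqs[[qName]]), p + 1L, p + 1L)
      if (qStrand == "-")
        orig <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(orig)))
      expect_equal(got, orig)
    }
  }
  # and via the package's own lift
  lift <- lift_positions(b$placements, "s4", 0:9)
  expect_equal(unique(lift$chrom), "chr1")
})

test_that("summary statistics balance anchored and unplaced totals", {
  set.seed(44)
  lens <- stats::setNames(sample(50:300, 8L), paste0("s", 1:8))
  seqs <- random_seqs(lens)
  mk <- data.frame(scaffold = c("s1", "s1", "s2", "s3", "s7"),
                   pos = c(1L, 5L, 3L, 2L, 4L), map = "m1", lg = "1",
                   map_pos = 1:5, stringsAsFactors = FALSE)
  mc <- map_collection(mk, scaffold_sizes = lens)
  cfgs <- list(scaffold_configuration("chr1", c("s1", "s2", "s3"), 1L))
  b <- build_genome(cfgs, seqs, maps = mc)
  s <- b$summary
  anc <- s[s$set == "Anchored", ]
  unp <- s[s$set == "Unplaced", ]
  expect_equal(anc$total_bases + unp$total_bases, sum(lens))
  expect_equal(anc$scaffolds + unp$scaffolds, length(lens))
  expect_equal(anc$scaffolds_1_marker, 2L) # s2, s3
  expect_equal(anc$scaffolds_2_markers, 1L) # s1
  expect_equal(anc$markers_unique + unp$markers_unique, 5L)
  expect_equal(anc$percent_of_genome + unp$percent_of_genome, 100)
})

linear_gap_fixture <- function(gap_default = 50000) {
  # two 100 kb scaffolds; all markers collinear at 1 cM/Mb in the
  # provisional (fixed-gap) coordinate system
  lens <- c(L = 100000, R = 100000)
  lpos <- c(10000L, 40000L, 80000L) # overhang of last marker: 20 kb
  rpos <- c(30000L, 60000L, 90000L) # overhang of first marker: 30 kb
  phys <- c(lpos, 100000 + gap_default + rpos)
  mk <- data.frame(scaffold = rep(c("L", "R"), each = 3L),
                   pos = c(lpos, rpos), map = "gm", lg = "1",
                   map_pos = phys * 1e-6, stringsAsFactors = FALSE)
  list(maps = map_collection(mk, scaffold_sizes = lens),
       cfg = scaffold_configuration("chr1", c("L", "R"), 1L))
}

test_that("gap estimation reproduces the linear-map arithmetic", {
  fx <- linear_gap_fixture()
  # flanking pair: 0.1 cM apart at 1 cM/Mb -> 100 kb; minus 20 kb + 30 kb
  # overhangs -> 50 kb (and every other pair agrees for a linear map)
  g <- estimate_gaps(fx$cfg, fx$maps, gap_default = 50000)
  expect_equal(length(g), 1L)
  expect_equal(g, 50000, tolerance = 1 / 50000)
})

test_that("gap estimates clamp and fall back sensibly", {
  fx <- linear_gap_fixture()
  mk <- fx$maps$markers
  # collapse the flanking genetic distance: estimate goes negative -> min_gap
  mk$map_pos[mk$scaffold == "R"] <- mk$map_pos[mk$scaffold == "L"][3] +
    c(0, 1e-4, 2e-4)
  squeezed <- map_collection(mk, scaffold_sizes = fx$maps$scaffold_sizes)
  g <- estimate_gaps(fx$cfg, squeezed, gap_default = 50000, min_gap = 10)
  expect_equal(g, 10)
  # junction with no flanking markers keeps the default
  lens <- c(A = 1000, B = 1000, C = 1000)
  mk2 <- data.frame(scaffold = rep(c("A", "C"), each = 2L),
                    pos = c(100L, 900L, 100L, 900L), map = "gm", lg = "1",
                    map_pos = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  mc2 <- map_collection(mk2, scaffold_sizes = lens)
  cfg2 <- scaffold_configuration("chr1", c("A", "B", "C"), 1L)
  expect_equal(estimate_gaps(cfg2, mc2, gap_default = 100), c(100, 100))
})

test_that("smallest estimate across maps and pairs wins", {
  set.seed(45)
  gap_default <- 1000
  lens <- c(L = 50000, R = 50000)
  pos <- c(5000L, 15000L, 30000L, 45000L)
  mk <- do.call(rbind, lapply(c(gm1 = 1.0, gm2 = 1.6), function(r) {
    phys <- c(pos, 50000 + gap_default + pos)
    data.frame(scaffold = rep(c("L", "R"), each = 4L), pos = rep(pos, 2L),
               map = NA_character_, lg = "1",
               map_pos = r * phys * 1e-6 + stats::rnorm(8L, 0, 0.002),
               stringsAsFactors = FALSE)
  }))
  mk$map <- rep(c("gm1", "gm2"), each = 8L)
  mc <- map_collection(mk, scaffold_sizes = lens,
                       map_order = c("gm1", "gm2"))
  cfg <- scaffold_configuration("chr1", c("L", "R"), 1L)
  got <- estimate_gaps(cfg, mc, gap_default = gap_default, min_gap = 10,
                       max_gap = 1e6)
  # independent recomputation of the stated rule: per map, spline of map
  # position vs provisional position; derivative at the junction midpoint;
  # min over all flanking pairs and maps; clamped
  ests <- c()
  for (m in c("gm1", "gm2")) {
    sub <- mk[mk$map == m, ]
    phys <- ifelse(sub$scaffold == "L", sub$pos,
                   50000 + gap_default + sub$pos)
    sp <- splinefun(phys, sub$map_pos, method = "fmm")
    rate <- abs(sp((50000 + 50000 + gap_default) / 2, deriv = 1))
    for (a in which(sub$scaffold == "L")) {
      for (b in which(sub$scaffold == "R")) {
        dm <- abs(sub$map_pos[b] - sub$map_pos[a])
        ests <- c(ests, dm / rate - (50000 - phys[a]) -
                    (phys[b] - (50000 + gap_default)))
      }
    }
  }
  expect_equal(got, min(max(min(ests), 10), 1e6), tolerance = 1e-9)
})

test_that("consensus map lifts and sorts markers", {
  lens <- c(a = 100, b = 100)
  mk <- data.frame(scaffold = c("a", "a", "b"), pos = c(10L, 60L, 30L),
                   map = "m1", lg = "1", map_pos = c(1, 2, 3),
                   stringsAsFactors = FALSE)
  mc <- map_collection(mk, scaffold_sizes = lens)
  cfg <- scaffold_configuration("chr1", c("a", "b"), c(1L, -1L))
  cm <- consensus_map(list(cfg), mc, gap_size = 10)
  # marker on the reversed scaffold: start + (len - 1 - pos)
  expect_equal(cm$pos[cm$scaffold == "b"], 110 + (100 - 1 - 30))
  expect_false(is.unsorted(cm$pos[cm$chrom == "chr1"], strictly = TRUE))
})

test_that("AGP writer emits a parseable 9-column file with header", {
  seqs <- random_seqs(c(s1 = 10L, s2 = 20L))
  cfg <- scaffold_configuration("chr1", c("s1", "s2"), c(1L, -1L))
  out <- tempfile()
  b <- build_genome(list(cfg), seqs, outdir = out)
  agp_file <- file.path(out, "genome.agp")
  expect_true(file.exists(agp_file))
  lines <- readLines(agp_file)
  expect_equal(lines[1], "##agp-version\t2.0")
  body <- lines[!startsWith(lines, "#")]
  expect_true(all(lengths(strsplit(body, "\t")) == 9L))
  expect_true(file.exists(file.path(out, "genome.fasta")))
  expect_true(file.exists(file.path(out, "genome.chain")))
})
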