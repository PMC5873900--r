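asm_s <- genome_assembly(c(chrA = 10000, chrB = 10000))

frag_set <- function(start, end, strand, chrom = "chrA", asm = asm_s) {
  peak_set(rep_len(chrom, length(start)), start, end, asm,
           strand = strand, label = "frags")
}

const_track <- function(value, binsize = 10, asm = asm_s) {
  nb <- ceiling(as.numeric(asm) / binsize)
  signal_track(stats::setNames(lapply(nb, function(n) rep(value, n)),
                               names(asm)), binsize, asm)
}

rand_track <- function(binsize = 10, asm = asm_s) {
  nb <- ceiling(as.numeric(asm) / binsize)
  signal_track(stats::setNames(
    lapply(nb, function(n) round(stats::runif(n, 0, 10), 3)),
    names(asm)), binsize, asm)
}

test_that("fragment coverage extends from the 5' end and counts per bin", {
  # one + fragment [0,36) extends to [0,150): bins 0..14 = 1
  tr <- coverage_track(frag_set(0, 36, "+"), extend_to = 150, binsize = 10)
  v <- tr$values$chrA
  expect_equal(v[1:15], rep(1, 15))
  expect_equal(sum(v), 15)
  expect_equal(sum(tr$values$chrB), 0)

  # minus-strand fragment anchors at its right end
  tr2 <- coverage_track(frag_set(964, 1000, "-"), extend_to = 150,
                        binsize = 10)
  expect_equal(which(tr2$values$chrA > 0), 86:100)  # [850,1000) -> bins 85..99

  # no fragments -> all-zero track
  tr0 <- coverage_track(frag_set(integer(0), integer(0), character(0)))
  expect_equal(sum(unlist(tr0$values)), 0)

  # duplicating every fragment doubles every bin (linearity)
  f1 <- frag_set(c(100, 5000), c(136, 5036), c("+", "-"))
  f2 <- frag_set(rep(c(100, 5000), 2), rep(c(136, 5036), 2),
                 rep(c("+", "-"), 2))
  expect_equal(coverage_track(f2)$values$chrA,
               2 * coverage_track(f1)$values$chrA)

  expect_error(coverage_track(f1, extend_to = 0), "positive")
  expect_error(coverage_track(frag_set(0, 36, ".")), "strand")
})

test_that("coverage agrees with the naive per-bin counting oracle", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(1:40, 1L)
    chrom <- sample(names(asm_s), n, replace = TRUE)
    start <- sample(0:9900, n, replace = TRUE)
    f <- peak_set(chrom, start, start + 36L, asm_s,
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  label = "f")
    ext <- sample(c(50L, 150L), 1L)
    bs <- sample(c(10L, 25L), 1L)
    tr <- coverage_track(f, extend_to = ext, binsize = bs)
    expect_equal(tr$values, bf_coverage(as.data.frame(f), asm_s, ext, bs),
                 ignore_attr = TRUE)
  }
})

test_that("bedGraph reads resample by length-weighted mean and round-trip", {
  f <- withr::local_tempfile(lines = "chrA\t0\t100\t5.0")
  tr <- read_bedgraph(f, asm_s, binsize = 10)
  expect_equal(tr$values$chrA[1:10], rep(5, 10))
  expect_equal(sum(tr$values$chrA[-(1:10)]), 0)

  # partial bin coverage: 5 of 10 bp at value 2 -> 1.0
  f2 <- withr::local_tempfile(lines = "chrA\t0\t15\t2.0")
  tr2 <- read_bedgraph(f2, asm_s, binsize = 10)
  expect_equal(tr2$values$chrA[1:2], c(2, 1))

  f3 <- withr::local_tempfile(lines = c("chrA\t0\t100\t1.0",
                                        "chrA\t50\t150\t2.0"))
  expect_error(read_bedgraph(f3, asm_s, 10), "overlapping")

  # write/read identity for an on-grid track
  set.seed(5)
  tr4 <- rand_track()
  out <- withr::local_tempfile()
  write_bedgraph(tr4, out)
  back <- read_bedgraph(out, asm_s, binsize = 10)
  expect_equal(back$values, tr4$values, tolerance = 1e-12)
})

test_that("reference-point matrix anchors, flips and pads correctly", {
  tr <- const_track(3)
  regions <- peak_set("chrA", c(1000, 5000), c(1200, 5400), asm_s,
                      name = c("r1", "r2"))
  m <- reference_point_matrix(tr, regions, flank = 500)
  expect_equal(dim(m), c(2L, 100L))
  expect_true(all(m == 3))

  # signal only at the bin containing r1's midpoint (1100) lights up the
  # center column only
  v <- tr$values; v$chrA[] <- 0; v$chrA[111] <- 7  # bin covering base 1100
  tr_pt <- signal_track(v, 10, asm_s)
  m2 <- reference_point_matrix(tr_pt, regions, flank = 500)
  expect_equal(unname(which(m2["r1", ] != 0)), 51L)  # column covering the anchor
  expect_equal(unname(m2["r1", 51]), 7)
  expect_true(all(m2["r2", ] == 0))

  # summit anchoring differs from midpoint when a summit is recorded
  sreg <- peak_set("chrA", 1000, 1200, asm_s, name = "s1", summit = 0L)
  ms <- reference_point_matrix(tr_pt, sreg, flank = 500, anchor = "summit")
  mm <- reference_point_matrix(tr_pt, sreg, flank = 500, anchor = "midpoint")
  expect_equal(unname(which(ms["s1", ] != 0)), 61L)  # 1100 is 100 bp right of summit
  expect_equal(unname(which(mm["s1", ] != 0)), 51L)

  # off-chromosome positions pad with zero and are counted
  edge <- peak_set("chrA", 0, 100, asm_s, name = "e1")
  me <- reference_point_matrix(tr, edge, flank = 500)
  expect_equal(attr(me, "meta")$n_out_of_bounds, 45L)
  expect_true(all(me[1, 1:45] == 0))
  expect_true(all(me[1, 46:100] == 3))

  expect_error(reference_point_matrix(tr, peak_set(assembly = asm_s), 500),
               "empty")
  expect_error(reference_point_matrix(tr, regions, flank = 505), "multiple")
})

test_that("reference-point matrix agrees with the per-base oracle", {
  set.seed(31)
  for (i in 1:20) {
    tr <- rand_track()
    n <- sample(1:20, 1L)
    start <- sample(0:9000, n, replace = TRUE)
    regions <- peak_set(sample(names(asm_s), n, replace = TRUE),
                        start, start + sample(50:400, n, replace = TRUE),
                        asm_s, strand = sample(c("+", "-", "."), n,
                                               replace = TRUE),
                        summit = ifelse(stats::runif(n) < 0.5, NA, 10L),
                        label = "r")
    flank <- sample(c(200L, 1000L), 1L)
    anchor <- sample(c("midpoint", "summit"), 1L)
    m <- reference_point_matrix(tr, regions, flank, anchor = anchor)
    expect_equal(unclass(m),
                 bf_reference_matrix(tr, as.data.frame(regions), flank, 10,
                                     anchor),
                 ignore_attr = TRUE)
  }
})

test_that("scaled-region matrix separates flanks from the scaled body", {
  # constant signal over the gene body only
  genes <- gene_table("g1", "chrA", 2000, 4000, "+", asm_s)
  v <- stats::setNames(lapply(ceiling(as.numeric(asm_s) / 10), numeric),
                       names(asm_s))
  v$chrA[201:400] <- 5  # bases [2000,4000)
  tr <- signal_track(v, 10, asm_s)
  m <- scaled_region_matrix(tr, genes, upstream = 1500, downstream = 1000,
                            body_bins = 100)
  expect_equal(dim(m), c(1L, 150 + 100 + 100))
  expect_true(all(m[1, 151:250] == 5))  # body columns
  expect_true(all(m[1, c(1:150, 251:350)] == 0))  # flank columns

  # signal confined to [TSS-1500, TSS) shows up only in upstream columns
  v2 <- stats::setNames(lapply(ceiling(as.numeric(asm_s) / 10), numeric),
                        names(asm_s))
  v2$chrA[51:200] <- 2  # bases [500,2000)
  tr2 <- signal_track(v2, 10, asm_s)
  m2 <- scaled_region_matrix(tr2, genes, 1500, 1000, 100)
  expect_true(all(m2[1, 1:150] == 2))
  expect_true(all(m2[1, -(1:150)] == 0))

  # a gene shorter than one bin is flagged and filled with its body mean
  tiny <- gene_table("t1", "chrA", 2004, 2012, "+", asm_s)
  v3 <- v; v3$chrA[] <- 0; v3$chrA[201] <- 4  # bases [2000,2010)
  tr3 <- signal_track(v3, 10, asm_s)
  m3 <- scaled_region_matrix(tr3, tiny, 1500, 1000, 100)
  expect_equal(attr(m3, "meta")$short_genes, "t1")
  expect_equal(unname(m3[1, 151:250]), rep(3, 100))  # 6 of 8 bases at 4
})

test_that("metagene rows read TSS to TES on both strands (mirror symmetry)", {
  G <- 10000
  set.seed(37)
  for (i in 1:10) {
    tr <- rand_track()
    # mirrored track: reverse every chromosome's bins
    trm <- signal_track(lapply(tr$values, rev), 10, asm_s)
    s <- sample(2000:4000, 1L); e <- s + sample(500:3000, 1L)
    g_plus <- gene_table("g", "chrA", s, e, "+", asm_s)
    g_minus <- gene_table("g", "chrA", G - e, G - s, "-", asm_s)
    mp <- scaled_region_matrix(tr, g_plus, 1500, 1000, 50)
    mm <- scaled_region_matrix(trm, g_minus, 1500, 1000, 50)
    expect_equal(unclass(mm), unclass(mp), ignore_attr = TRUE)
  }
})

test_that("scaled-region matrix agrees with the per-base oracle", {
  set.seed(41)
  for (i in 1:8) {
    tr <- rand_track()
    n <- sample(1:8, 1L)
    s <- sample(1500:6000, n, replace = TRUE)
    genes <- gene_table(sprintf("g%d", seq_len(n)),
                        sample(names(asm_s), n, replace = TRUE),
                        s, s + sample(20:3000, n, replace = TRUE),
                        sample(c("+", "-"), n, replace = TRUE), asm_s)
    keep <- genes$end - genes$start >= 10L  # short-gene rule tested above
    genes <- genes[keep, , drop = FALSE]
    class(genes) <- c("gene_table", "data.frame")
    if (nrow(genes) == 0L) next
    m <- scaled_region_matrix(tr, genes, 1000, 500, 40)
    expect_equal(unclass(m),
                 bf_scaled_matrix(tr, as.data.frame(genes), 1000, 500, 40, 10),
                 ignore_attr = TRUE)
  }
})

test_that("profiles average columns and row ordering is stable descending", {
  m <- matrix(c(0, 2, 2, 0), nrow = 2)  # rows [0,2] and [2,0]
  expect_equal(mean_profile(m), c(1, 1))
  one <- matrix(c(3, 1, 4), nrow = 1)
  expect_equal(mean_profile(one), c(3, 1, 4))
  expect_error(mean_profile(m[0, , drop = FALSE]), "empty")

  # weighted-mean decomposition over vertical concatenation
  a <- matrix(stats::runif(6), 2, 3)
  b <- matrix(stats::runif(9), 3, 3)
  expect_equal(mean_profile(rbind(a, b)),
               (2 * mean_profile(a) + 3 * mean_profile(b)) / 5)

  sm <- matrix(1:8, nrow = 4, dimnames = list(c("g1", "g2", "g3", "g4")))
  vals <- c(g1 = 5, g2 = 9, g3 = 5, g4 = 1)
  o <- order_rows_by(sm, vals)
  # g2 (max) first; g1/g3 tie keeps input order; g4 last
  expect_equal(rownames(o), c("g2", "g1", "g3", "g4"))
  expect_error(order_rows_by(sm, vals[1:3]), "no value")
})
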