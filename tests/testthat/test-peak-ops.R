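asm1 <- genome_assembly(c(chr1 = 100000))

mk <- function(start, end, asm = asm1, chrom = "chr1", ...) {
  peak_set(rep_len(chrom, length(start)), start, end, asm, ...)
}

test_that("blacklist filtering removes any-overlap peaks and is idempotent", {
  peaks <- mk(c(100, 300), c(200, 400))
  bl <- mk(150, 160)
  expect_equal(nrow(suppressMessages(filter_blacklist(peaks, bl))), 1L)

  empty_bl <- mk(integer(0), integer(0))
  expect_equal(as.data.frame(filter_blacklist(peaks, empty_bl)),
               as.data.frame(peaks))

  bl2 <- mk(390, 500)
  out <- suppressMessages(filter_blacklist(peaks, bl2))
  expect_equal(out$start, 100L)
  once <- suppressMessages(filter_blacklist(peaks, bl2))
  twice <- suppressMessages(filter_blacklist(once, bl2))
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("recursive merge reaches the pairwise-merge fixpoint", {
  # gap 450 merges at max_gap 500, gap 600 does not
  p <- mk(c(0, 550, 1200), c(100, 600, 1300))
  m <- recursive_merge(p, 500)
  expect_equal(m$start, c(0L, 1200L))
  expect_equal(m$end, c(600L, 1300L))
  expect_equal(as.data.frame(m)[, 1:3],
               bf_recursive_merge(as.data.frame(p), 500))

  # single interval is untouched
  one <- mk(10, 20)
  expect_equal(as.data.frame(recursive_merge(one, 500)),
               as.data.frame(one))

  # chained case: second merge enabled by the first
  chain <- mk(c(0, 550, 1050), c(100, 600, 1100))
  m2 <- recursive_merge(chain, 500)
  expect_equal(m2$start, 0L)
  expect_equal(m2$end, 1100L)
  expect_equal(as.data.frame(m2)[, 1:3],
               bf_recursive_merge(as.data.frame(chain), 500))

  # inclusive boundary: gap exactly 500 merges, 501 does not
  expect_equal(nrow(recursive_merge(mk(c(0, 600), c(100, 700)), 500)), 1L)
  expect_equal(nrow(recursive_merge(mk(c(0, 601), c(100, 700)), 500)), 2L)

  expect_error(recursive_merge(one, -1), "non-negative")
})

test_that("merged peaks keep the max score and drop names/summits", {
  p <- peak_set("chr1", c(0, 200), c(100, 300), asm1,
                name = c("a", "b"), score = c(10, 99), summit = c(50, 50))
  m <- recursive_merge(p, 500)
  expect_equal(m$score, 99)
  expect_true(is.na(m$name))
  expect_true(is.na(m$summit))
})

test_that("recursive merge properties hold on random inputs", {
  asm <- tiny_assembly()
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:40, 1L)
    gap <- sample(c(0L, 5L, 50L, 500L), 1L)
    ps <- rand_peak_set(n, asm)
    m <- recursive_merge(ps, gap)
    # idempotent
    expect_equal(as.data.frame(recursive_merge(m, gap))[, 1:3],
                 as.data.frame(m)[, 1:3])
    # monotone in count, and adjacent output gaps exceed the threshold
    expect_lte(nrow(m), nrow(ps))
    for (ch in unique(m$chrom)) {
      r <- m[m$chrom == ch, ]
      if (nrow(r) > 1L) expect_gt(min(r$start[-1L] - r$end[-nrow(r)]), gap)
    }
    # agrees with the pairwise fixpoint oracle
    expect_equal(as.data.frame(m)[, 1:3],
                 bf_recursive_merge(as.data.frame(ps), gap))
  }
})

test_that("any-base overlap respects half-open boundaries", {
  q <- mk(100, 200)
  expect_true(overlap_any(q, mk(199, 250)))   # shares base 199
  expect_false(overlap_any(q, mk(200, 250)))  # book-ended, no shared base
  expect_true(all(overlap_any(q, q)))

  asm2 <- genome_assembly(c(chr1 = 1000, chr2 = 1000))
  a <- peak_set("chr1", 0, 500, asm2)
  b <- peak_set("chr2", 0, 500, asm2)
  expect_false(overlap_any(a, b))
  # min_overlap option
  expect_false(overlap_any(q, mk(199, 250), min_overlap = 2))
})

test_that("overlap_any agrees with the per-base oracle on random instances", {
  asm <- tiny_assembly()
  set.seed(11)
  for (i in 1:50) {
    q <- rand_peak_set(sample(1:50, 1L), asm)
    s <- rand_peak_set(sample(1:50, 1L), asm)
    expect_equal(overlap_any(q, s),
                 bf_overlap_any(as.data.frame(q), as.data.frame(s), asm))
  }
})

test_that("classification partitions the ATPase set by accessory overlap", {
  atpase <- mk(c(100, 1000, 5000), c(200, 1100, 5100),
               name = c("p1", "p2", "p3"))
  acc1 <- mk(150, 180)    # overlaps p1
  acc2 <- mk(1050, 1200)  # overlaps p2
  cl <- suppressMessages(
    classify_peaks(subunit_panel(atpase, list(A = acc1, B = acc2))))
  expect_equal(cl$canonical$name, c("p1", "p2"))
  expect_equal(cl$noncanonical$name, "p3")
  expect_equal(cl$provenance$nc_fraction, 1 / 3)

  # every accessory everywhere -> no NC; none anywhere -> all NC
  all_cov <- mk(0, 99999)
  cl2 <- suppressMessages(classify_peaks(subunit_panel(atpase,
                                                       list(A = all_cov))))
  expect_equal(nrow(cl2$noncanonical), 0L)
  nowhere <- mk(integer(0), integer(0))
  cl3 <- suppressMessages(classify_peaks(subunit_panel(atpase,
                                                       list(A = nowhere))))
  expect_equal(nrow(cl3$canonical), 0L)
  expect_equal(nrow(cl3$noncanonical), nrow(atpase))

  expect_error(subunit_panel(atpase, list()), "at least one")
  expect_error(subunit_panel(atpase, list(mk(0, 10))), "named")
})

test_that("classification invariants hold on random panels", {
  asm <- tiny_assembly()
  set.seed(13)
  for (i in 1:30) {
    atpase <- rand_peak_set(sample(2:40, 1L), asm, label = "atpase")
    accs <- lapply(1:3, function(k) rand_peak_set(sample(1:30, 1L), asm))
    names(accs) <- c("A", "B", "C")
    cl <- suppressMessages(classify_peaks(subunit_panel(atpase, accs)))
    # partition: counts add up and classes are disjoint subsets of input
    expect_equal(nrow(cl$canonical) + nrow(cl$noncanonical), nrow(atpase))
    # matches exhaustive per-base classification
    bf <- bf_classify(as.data.frame(atpase), lapply(accs, as.data.frame), asm)
    expect_equal(cl$canonical$name, atpase$name[bf$canonical])
    expect_equal(cl$noncanonical$name, atpase$name[bf$noncanonical])
    # adding an accessory can only move peaks noncanonical -> canonical
    extra <- rand_peak_set(10, asm)
    cl4 <- suppressMessages(
      classify_peaks(subunit_panel(atpase, c(accs, list(D = extra)))))
    expect_true(all(cl$canonical$name %in% cl4$canonical$name))
  }
})

test_that("genomic distribution assigns midpoints with promoter priority", {
  asm <- genome_assembly(c(chr1 = 50000, chr2 = 50000))
  genes <- gene_table("g1", "chr1", 10000, 20000, "+", asm)
  # midpoint 300 bp upstream of the TSS, +/-1kb window -> promoter
  prom_peak <- peak_set("chr1", 9600, 9800, asm)  # midpoint 9700
  body_peak <- peak_set("chr1", 15000, 15200, asm)
  far_peak <- peak_set("chr1", 40000, 40200, asm)
  no_gene_chrom <- peak_set("chr2", 100, 200, asm)
  all4 <- peak_set(c("chr1", "chr1", "chr1", "chr2"),
                   c(9600, 15000, 40000, 100),
                   c(9800, 15200, 40200, 200), asm)
  d <- genomic_distribution(all4, genes)
  expect_equal(unname(d), c(0.25, 0.25, 0.5))
  expect_equal(sum(d), 1, tolerance = 1e-12)

  expect_equal(unname(genomic_distribution(prom_peak, genes)["promoter"]), 1)
  expect_equal(unname(genomic_distribution(no_gene_chrom, genes)["distal"]), 1)
  # promoter window is strand-aware: same window on a minus-strand gene
  genes_m <- gene_table("g1", "chr1", 10000, 20000, "-", asm)  # tss 19999
  up_m <- peak_set("chr1", 20400, 20600, asm)  # midpoint 500 bp 5' of TSS
  expect_equal(unname(genomic_distribution(up_m, genes_m)["promoter"]), 1)
  expect_error(genomic_distribution(peak_set(assembly = asm), genes), "empty")
})
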