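test_that("contigs are tiled into 10 kb fragments with the remainder policy", {
  f <- fragment_contigs(c(a = strrep("A", 25500), b = strrep("A", 20500),
                          c = strrep("A", 900), d = strrep("A", 10000)))
  expect_equal(f$length[f$contig_id == "a"], c(10000L, 10000L, 5500L))
  expect_equal(f$length[f$contig_id == "b"], c(10000L, 10500L))  # 500 bp merged
  expect_false("c" %in% f$contig_id)                             # < 1 kb dropped
  expect_equal(f$length[f$contig_id == "d"], 10000L)             # exact tile
  # tiling exactness: starts/ends nest without gaps
  for (id in unique(f$contig_id)) {
    g <- f[f$contig_id == id, ]
    expect_equal(g$start, c(0L, head(g$end, -1L)))
    expect_equal(g$length, g$end - g$start)
  }
})

test_that("tiling conserves contig length over random contigs", {
  set.seed(404)
  lens <- sample(500:40000, 50)
  contigs <- setNames(vapply(lens, function(L) strrep("A", L), ""),
                      sprintf("c%02d", seq_along(lens)))
  f <- fragment_contigs(contigs)
  got <- tapply(f$length, f$contig_id, sum)
  expect_equal(as.integer(got[names(got)]),
               unname(lens[match(names(got), names(contigs))]))
  expect_true(all(f$length >= 1000L))
  expect_setequal(unique(f$contig_id), names(contigs)[lens >= 1000])
})

test_that("fragmentation guards degenerate input", {
  expect_warning(f0 <- fragment_contigs(setNames(character(0), character(0))),
                 "empty")
  expect_equal(nrow(f0), 0L)
  expect_error(fragment_contigs(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(fragment_contigs(c(a = "ACGT"), fragment_len = 500,
                                min_contig = 1000), "fragment_len")
})

test_that("tetramer frequencies match hand-enumerated windows", {
  f <- tetramer_frequencies("AAAAA")
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f), 1)
  f <- tetramer_frequencies("ACGTACGT")  # 5 windows
  expect_equal(unname(f[c("ACGT", "CGTA", "GTAC", "TACG")]),
               c(2, 1, 1, 1) / 5)
  expect_equal(sum(f != 0), 4L)
  # windows touching N are excluded and the denominator shrinks
  f <- tetramer_frequencies("ACGNACGT")  # only ACGT at the end is clean
  expect_equal(unname(f["ACGT"]), 1)
  expect_error(tetramer_frequencies("ACGNNCGT"), "ambiguous")
  expect_equal(tetramer_frequencies("acgtacgt"), tetramer_frequencies("ACGTACGT"))
})

test_that("tetramer rows sum to one on random fragments", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(100:5000, 1))
    expect_equal(sum(tetramer_frequencies(s)), 1, tolerance = 1e-9)
  }
})

test_that("fragment coverage handles both depth dialects", {
  contigs <- c(k = strrep("A", 4000))
  f <- fragment_contigs(contigs, fragment_len = 2000L, min_contig = 1000L)
  # per-contig mean: assigned to every fragment regardless of granularity
  cov <- fragment_coverage(data.frame(contig_id = "k", mean_depth = 7), f)
  expect_equal(unname(cov), c(7, 7))
  f1 <- fragment_contigs(contigs, fragment_len = 3000L, min_contig = 1000L)
  cov1 <- fragment_coverage(data.frame(contig_id = "k", mean_depth = 7), f1)
  expect_true(all(cov1 == 7))  # invariant to fragmentation granularity
  # per-base: arithmetic mean with zero-fill for absent positions
  pb <- data.frame(contig_id = "k", pos = 1:2000, depth = 3)
  cov2 <- fragment_coverage(pb, f)
  expect_equal(unname(cov2), c(3, 0))
  half <- data.frame(contig_id = "k", pos = seq(1, 4000, by = 2), depth = 10)
  expect_equal(unname(fragment_coverage(half, f)), c(5, 5))
  expect_error(fragment_coverage(data.frame(contig_id = "zz", mean_depth = 1), f),
               "absent")
})

test_that("per-base fragment means match hand arithmetic", {
  f <- data.frame(fragment_id = "x|1", contig_id = "x", start = 0L, end = 4L,
                  length = 4L, stringsAsFactors = FALSE)
  pb <- data.frame(contig_id = "x", pos = 1:4, depth = c(1, 2, 3, 6))
  expect_equal(unname(fragment_coverage(pb, f)), 3)
})

test_that("feature matrix has 257 columns and default scaling standardises", {
  set.seed(5)
  tet <- t(vapply(1:40, function(i) tetramer_frequencies(random_dna(3000)),
                  numeric(256)))
  rownames(tet) <- sprintf("f%d", 1:40)
  cov <- setNames(runif(40, 1, 100), rownames(tet))
  x <- build_feature_matrix(tet, cov)
  expect_equal(ncol(x), 257L)
  expect_equal(colnames(x)[257], "coverage")
  expect_equal(attr(x, "scaling"), "log10_zscore")
  nonconst <- apply(x, 2, function(col) any(col != 0))
  expect_true(all(abs(colMeans(x[, nonconst])) < 1e-9))
  expect_true(all(abs(apply(x[, nonconst], 2, var) - 1) < 1e-9))
  # identical fragments get identical rows
  tet2 <- tet[c(1, 1, 3:40), ]; rownames(tet2) <- rownames(tet)
  cov2 <- cov; cov2[2] <- cov2[1]
  x2 <- build_feature_matrix(tet2, cov2)
  expect_equal(unname(x2[1, ]), unname(x2[2, ]))
  expect_error(build_feature_matrix(tet, cov[-1]), "differ")
})
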