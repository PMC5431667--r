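features_df <- function(chr, start, end, name, class = NULL) {
  df <- data.frame(chromosome = chr, start_bp = start, end_bp = end,
                   name = name, stringsAsFactors = FALSE)
  if (!is.null(class)) df$trait_class <- class
  df
}

test_that("interval overlap follows half-open semantics", {
  cnv <- data.frame(chromosome = "1", start_bp = 100, end_bp = 200,
                    cnv_id = "c1")
  genes <- features_df("1", c(150, 200), c(300, 300), c("gA", "gB"))
  ov <- overlap_features(cnv, genes)
  expect_equal(ov$feature_name, "gA")  # [100,200) vs [200,300) do not touch
  expect_equal(ov$overlap_bp, 50)
  # chromosome present on one side only: silently empty
  ov2 <- overlap_features(cnv, features_df("9", 1, 10, "gC"))
  expect_equal(nrow(ov2), 0)
})

test_that("overlap matches an all-pairs brute-force oracle and is symmetric", {
  set.seed(77)
  n <- 400
  mk <- function(n, tag) {
    chr <- sample(c("1", "2", "3"), n, replace = TRUE)
    start <- sample.int(1e5, n)
    data.frame(chromosome = chr, start_bp = start,
               end_bp = start + sample.int(5e3, n),
               name = sprintf("%s%d", tag, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  a <- mk(n, "a")
  b <- mk(n, "b")
  a$cnv_id <- a$name
  ov <- overlap_features(a, b)
  got <- sort(paste(ov$interval_id, ov$feature_name))
  brute <- character(0)
  for (i in seq_len(n)) {
    hit <- b$chromosome == a$chromosome[i] & b$start_bp < a$end_bp[i] &
      b$end_bp > a$start_bp[i]
    if (any(hit)) brute <- c(brute, paste(a$name[i], b$name[hit]))
  }
  expect_identical(got, sort(brute))
  # symmetry: swapping roles reports the same pairs
  b$cnv_id <- b$name
  ov_swap <- overlap_features(b, a[, c("chromosome", "start_bp", "end_bp",
                                       "name")])
  expect_identical(sort(paste(ov_swap$feature_name, ov_swap$interval_id)),
                   got)
})

test_that("venn partition handles degenerate and random set families", {
  singles <- list(A = "g1", B = "g2", C = "g3", D = "g4")
  v <- venn_partition(singles)
  expect_equal(unname(v[c("A", "B", "C", "D")]), rep(1L, 4),
               ignore_attr = TRUE)
  expect_equal(sum(v), 4)
  same <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"),
               D = c("x", "y"))
  v2 <- venn_partition(same)
  expect_equal(unname(v2[["A&B&C&D"]]), 2)
  expect_equal(sum(v2), 2)
  # random families agree with exhaustive membership enumeration
  for (s in 1:5) {
    set.seed(s)
    pool <- sprintf("g%02d", 1:20)
    sets <- lapply(1:4, function(i) sample(pool, sample(0:12, 1)))
    names(sets) <- c("W", "X", "Y", "Z")
    v3 <- venn_partition(sets)
    uni <- unique(unlist(sets))
    expect_equal(sum(v3), length(uni))
    for (g in uni) {
      inset <- names(sets)[vapply(sets, function(st) g %in% st, logical(1))]
      region <- paste(inset, collapse = "&")
      # count genes with exactly this membership
      expected <- sum(vapply(uni, function(h) {
        identical(inset, names(sets)[vapply(sets, function(st) h %in% st,
                                            logical(1))])
      }, logical(1)))
      expect_equal(unname(v3[[region]]), expected)
    }
  }
})

test_that("QTL class enrichment compares de novo to constant proportions", {
  qtl <- features_df("1", c(0, 50e3), c(10e3, 60e3), c("q1", "q2"),
                     class = c("Health", "Milk"))
  dn <- rbind(traj_row("S1", "1", 0, 5e3, "de_novo_3", id = "d1"),
              traj_row("S1", "1", 52e3, 58e3, "de_novo_3", id = "d2"))
  ct <- rbind(traj_row("S1", "1", 2e3, 8e3, "constant", id = "c1"),
              traj_row("S1", "1", 55e3, 59e3, "constant", id = "c2"))
  res <- qtl_class_enrichment(dn, ct, qtl)
  expect_equal(nrow(res), 6)
  h <- res[res$trait_class == "Health", ]
  # both groups overlap Health in 1 of 2 CNVs: no enrichment signal
  expect_equal(h$n_denovo_overlap, 1L)
  expect_equal(h$n_constant_overlap, 1L)
  # a class hit by every de novo CNV and no constant CNV is near-minimal p
  qtl2 <- features_df("2", 0, 1e6, "q3", class = "Reproduction")
  dn2 <- do.call(rbind, lapply(1:20, function(i) {
    traj_row("S1", "2", i * 2e3, i * 2e3 + 1e3, "de_novo_3",
             id = sprintf("d%d", i))
  }))
  res2 <- qtl_class_enrichment(dn2, ct, qtl2)
  r <- res2[res2$trait_class == "Reproduction", ]
  expect_equal(r$n_denovo_overlap, 20L)
  expect_lt(r$p_value, 1e-10)
  expect_error(qtl_class_enrichment(dn[0, ], ct, qtl), "nonempty")
})

test_that("QTL enrichment p equals exhaustive binomial enumeration at small n", {
  qtl <- features_df("1", 0, 30e3, "q1", class = "Health")
  dn <- do.call(rbind, lapply(1:8, function(i) {
    traj_row("S1", "1", (i - 1) * 10e3, (i - 1) * 10e3 + 5e3, "de_novo_3",
             id = sprintf("d%d", i))
  }))  # first 3 overlap [0,30k)
  ct <- do.call(rbind, lapply(1:10, function(i) {
    traj_row("S1", "1", (i - 1) * 8e3, (i - 1) * 8e3 + 4e3, "constant",
             id = sprintf("c%d", i))
  }))  # first 4 overlap
  res <- qtl_class_enrichment(dn, ct, qtl)
  h <- res[res$trait_class == "Health", ]
  expect_equal(h$p_value, binom_two_sided_enum(h$n_denovo_overlap, 8,
                                               h$null_proportion),
               tolerance = 1e-9)
})

test_that("gene-set enrichment reproduces the reference E and R layout", {
  # category of 127 reference genes, 2 observed among 9 analyzed, reference
  # universe 19,639: E ~ 0.058, R ~ 34.4
  sets <- list(upb = sprintf("ref%03d", 1:127))
  analyzed <- c("ref001", "ref002", sprintf("other%d", 1:7))
  res <- geneset_enrichment(analyzed, sets, reference_size = 19639)
  expect_equal(res$C, 127)
  expect_equal(res$O, 2)
  expect_equal(res$E, 127 * 9 / 19639)
  expect_equal(signif(res$R, 3), 34.4)
  expect_lt(res$raw_p, 0.01)
})

test_that("zero overlap yields R = 0 and raw p = 1", {
  res <- geneset_enrichment(c("a", "b"), list(cat = c("x", "y", "z")),
                            reference_size = 100)
  expect_equal(res$O, 0)
  expect_equal(res$R, 0)
  expect_equal(res$raw_p, 1)
})

test_that("hypergeometric p matches subset enumeration on small universes", {
  # universe of 10 genes, category of 3, draw 4, observe 2
  expect_equal(
    geneset_enrichment(sprintf("g%d", c(1, 2, 8, 9)),
                       list(cat = sprintf("g%d", 1:3)),
                       reference_size = 10)$raw_p,
    hyper_upper_enum(2, 3, 10, 4), tolerance = 1e-12)
  # more universes <= 15
  for (cfg in list(c(12, 5, 4, 1), c(15, 6, 6, 3), c(9, 2, 5, 2))) {
    N <- cfg[1]; C <- cfg[2]; k <- cfg[3]; o <- cfg[4]
    analyzed <- sprintf("g%d", c(seq_len(o), seq(C + 1, C + k - o)))
    res <- geneset_enrichment(analyzed, list(cat = sprintf("g%d", 1:C)),
                              reference_size = N)
    expect_equal(res$raw_p, hyper_upper_enum(o, C, N, k), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches a hand-computed five-category table", {
  set.seed(2)
  universe <- sprintf("u%02d", 1:40)
  gsets <- lapply(1:5, function(i) sample(universe, 8))
  names(gsets) <- sprintf("cat%d", 1:5)
  res <- geneset_enrichment(sample(universe, 10), gsets, 40)
  # hand computation: raw_p * m / rank (on the sorted table), then a
  # running minimum from the bottom up
  hand <- rev(cummin(rev(res$raw_p * 5 / seq_len(5))))
  expect_equal(res$adj_p, hand)
  expect_true(all(res$adj_p >= res$raw_p))
})
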