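test_that("gc_content is exact on enumerated strings and monotone under GC prepending", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AUAU"), 0.0)
  expect_equal(gc_content("ACGU"), 0.5)
  expect_equal(gc_content("GCNN"), 0.5)  # N in denominator only
  set.seed(12)
  for (rep_i in 1:25) {
    s <- random_rna(sample(10:200, 1), with_n = TRUE)
    expect_gte(gc_content(paste0("GC", s)), gc_content(s))
  }
  expect_error(gc_content(""), "non-empty")
})

test_that("kruskal_wallis reproduces the rank-sum arithmetic and the reference implementation", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$group_sizes, c(3L, 3L, 3L))

  expect_equal(kruskal_wallis(list(rep(1, 4), rep(1, 5)))$H, 0)

  set.seed(77)
  for (rep_i in 1:30) {
    g <- lapply(seq_len(sample(2:4, 1)), function(i) {
      round(rnorm(sample(5:40, 1), mean = i * runif(1)), 1)  # forces ties
    })
    got <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), factor(rep(seq_along(g), lengths(g))))
    expect_equal(got$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:3)), "2")
  expect_error(kruskal_wallis(list(1:3, numeric())), "non-empty")
})

test_that("kruskal_wallis is invariant under joint strictly monotone transforms", {
  set.seed(5)
  g <- list(runif(20), runif(15) + 0.2, runif(25) - 0.1)
  h0 <- kruskal_wallis(g)$H
  for (f in list(function(x) exp(x), function(x) x^3 + 5 * x,
                 function(x) atan(x))) {
    expect_equal(kruskal_wallis(lapply(g, f))$H, h0, tolerance = 1e-12)
  }
})

test_that("longest_orf follows the start-to-first-stop convention", {
  expect_equal(longest_orf("AUGUAA"), 6L)
  expect_equal(longest_orf("CCCCCC"), 0L)
  expect_equal(longest_orf("AAUGGCGUGAUU"), 9L)  # frame 2
  # appending a suffix that creates no new AUG leaves the ORF unchanged
  expect_equal(longest_orf(paste0("AUGUAA", strrep("C", 30))), 6L)
  # nested starts: the earlier AUG wins
  expect_equal(longest_orf("AUGAUGCCCUAA"), 12L)
})

test_that("longest_orf matches the brute-force scan on random and adversarial cases", {
  set.seed(404)
  for (rep_i in 1:60) {
    s <- random_rna(sample(30:250, 1))
    expect_equal(longest_orf(s), oracle_orf(s))
  }
  adversarial <- c(
    "AUGAUGUAAUAA",             # nested starts, tandem stops
    "AUGUGAAUGUAA",             # two ORFs in one frame
    "AAUGUAAUGCCCUAAUU",        # overlapping frames
    "AUGCCCAUGUAACCCUAA",       # internal start before shared stop
    "UAAAUGUAG",                # stop before start
    "AUGNNNUAA",                # N codon inside the ORF body
    strrep("AUG", 10),          # starts, no stop
    paste0(strrep("C", 7), "AUGUAA"),
    "AUGUAGAUGUGAAUGUAACCC",
    "GAUGGUGAUAAUGA"
  )
  for (s in adversarial) {
    expect_equal(longest_orf(s), oracle_orf(s))
  }
})

test_that("embedding is shape-preserving, deterministic and class-separating", {
  skip_if_not_installed("cluster")
  ds <- toy_split_dataset(n_per_class = 40, seed = 14, len = 300)
  fm <- featurize(ds, spec = kmer_spec(3))
  emb <- embed_2d(fm, n_neighbors = 15, seed = 9)
  expect_equal(nrow(emb$coords), nrow(fm))
  expect_equal(rownames(emb$coords), rownames(fm))

  emb2 <- embed_2d(fm, n_neighbors = 15, seed = 9)
  expect_identical(emb$coords, emb2$coords)

  labs <- factor(attr(fm, "labels"))
  sil <- cluster::silhouette(as.integer(labs), dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0)

  expect_error(embed_2d(fm[1:10, ], n_neighbors = 15), "reduce n_neighbors")
})

test_that("outlier rule flags only points in foreign neighbourhoods", {
  # two tight, well-separated blobs plus one planted intruder
  set.seed(2)
  blob_a <- cbind(rnorm(30, 0, 0.1), rnorm(30, 0, 0.1))
  blob_b <- cbind(rnorm(30, 10, 0.1), rnorm(30, 10, 0.1))
  intruder <- c(10, 10)
  coords <- rbind(blob_a, blob_b, intruder)
  rownames(coords) <- c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:30), "odd")
  emb <- structure(list(coords = coords,
                        params = list(n_neighbors = 10L, min_dist = 0.005,
                                      metric = "chebyshev", seed = 1L)),
                   class = "embedding_result")
  labels <- c(rep("A", 30), rep("B", 30), "A")
  expect_equal(find_outlier_members(emb, labels), "odd")
  expect_equal(find_outlier_members(emb, labels, target_class = "B"),
               character())
  # perfectly separated classes: no outliers
  clean <- structure(list(coords = coords[1:60, ],
                          params = list(n_neighbors = 10L)),
                     class = "embedding_result")
  expect_equal(find_outlier_members(clean, labels[1:60]), character())
})

test_that("class feature report summarizes GC and ORF per class with a KW test", {
  spec <- generator_spec(default_profiles(), n_per_class = 400, seed = 31)
  ds <- generate_dataset(spec)
  rep <- class_feature_report(ds)
  expect_equal(nrow(rep$per_record), nrow(ds))
  expect_equal(rownames(rep$gc_summary), class_names(ds))
  # generated GC class means land near their profile targets
  expect_lt(abs(rep$gc_summary["lncRNA_like", "mean"] - 0.465), 0.01)
  expect_lt(abs(rep$gc_summary["circRNA_like", "mean"] - 0.48), 0.01)
  expect_lt(abs(rep$gc_summary["mRNA_like", "mean"] - 0.50), 0.01)
  # mRNA-like ORFs dwarf the non-coding classes
  expect_gt(rep$orf_summary["mRNA_like", "mean"],
            3 * rep$orf_summary["lncRNA_like", "mean"])
  expect_s3_class(rep$kruskal, "kruskal_wallis_result")
  expect_lt(rep$kruskal$p, 0.01)
})
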