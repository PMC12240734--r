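test_that("k-mer frequencies match enumerated examples", {
  f3 <- kmer_frequencies("ACGU", 3)
  expect_equal(unname(f3[c("ACG", "CGU")]), c(0.5, 0.5))
  expect_equal(sum(f3), 1)

  f2 <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f2["AA"]), 1)

  f <- kmer_frequencies("ACGUACGU", 3)
  expect_equal(unname(f[c("ACG", "CGU", "GUA", "UAC")]),
               c(2, 2, 1, 1) / 6)

  # windows containing N are skipped
  fn <- kmer_frequencies("ACNGU", 2)
  expect_equal(unname(fn[c("AC", "GU")]), c(0.5, 0.5))

  expect_warning(short <- kmer_frequencies("ACG", 5), "exceeds")
  expect_true(all(short == 0))
})

test_that("multiscale fusion concatenates per-scale frequency slices", {
  spec <- kmer_spec(c(3, 4, 5))
  row <- multiscale_kmer(strrep("ACGU", 10), spec)
  expect_length(row, 1344)
  slices <- attr(row, "scale_slices")
  expect_equal(lengths(slices), c(`3mer` = 64L, `4mer` = 256L, `5mer` = 1024L))
  for (sl in slices) expect_equal(sum(row[sl]), 1)
  single <- multiscale_kmer("ACGUACGU", kmer_spec(3))
  expect_equal(as.numeric(single), as.numeric(kmer_frequencies("ACGUACGU", 3)))
})

test_that("k-mer vector of the reversed sequence is a permutation of the original", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_rna(sample(100:400, 1))
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    for (k in c(2, 3)) {
      a <- sort(kmer_frequencies(s, k))
      b <- sort(kmer_frequencies(rev_s, k))
      expect_equal(unname(a), unname(b))
    }
  }
})

test_that("NAC counts non-N positions only", {
  expect_equal(unname(nac("AACG")), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(nac("UUUU")), c(0, 0, 0, 1))
  expect_equal(unname(nac("ANGU")), c(1, 0, 1, 1) / 3)
  expect_warning(z <- nac("NNN"), "no non-N")
  expect_true(all(z == 0))
})

test_that("CKSNAP blocks enumerate gapped pairs", {
  v <- cksnap("ACGU", max_gap = 1)
  expect_equal(unname(v[c("g0:AC", "g0:CG", "g0:GU")]), rep(1 / 3, 3))
  expect_equal(sum(v[1:16]), 1)
  expect_equal(unname(v[c("g1:AG", "g1:CU")]), c(0.5, 0.5))
  homo <- cksnap(strrep("A", 6), max_gap = 4)
  for (g in 0:4) expect_equal(unname(homo[paste0("g", g, ":AA")]), 1)
  expect_error(cksnap("ACG", max_gap = 5), "must exceed")
})

test_that("covariance descriptors vanish on homopolymers", {
  tab <- dinuc_property_table()
  expect_true(all(abs(dac(strrep("A", 20), tab)) < 1e-15))
  expect_true(all(abs(dcc(strrep("G", 20), tab)) < 1e-15))
  expect_true(all(abs(dacc(strrep("U", 20), tab)) < 1e-15))
  # PseKNC on a homopolymer reduces to pure composition (theta = 0)
  v <- pseknc(strrep("A", 30), k = 2)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(unname(v[c("theta1", "theta2")]), c(0, 0))
})

test_that("property table is standardized and pseudo-descriptors collapse at weight 0", {
  tab <- dinuc_property_table()
  expect_equal(unname(colMeans(tab)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(tab, 2, var)), rep(1, 6), tolerance = 1e-9)

  set.seed(8)
  s <- random_rna(80)
  v0 <- pseknc(s, k = 3, weight = 0)
  expect_equal(unname(v0[1:64]), unname(kmer_frequencies(s, 3)))
  expect_equal(unname(v0[65:66]), c(0, 0))
  p0 <- pcpsednc(s, weight = 0)
  expect_equal(unname(p0[1:16]), unname(kmer_frequencies(s, 2)))
  expect_equal(sum(pcpsednc(s)), 1, tolerance = 1e-9)
})

test_that("descriptors match literal-formula oracles on seeded random sequences", {
  tab <- dinuc_property_table()
  set.seed(1234)
  for (rep in 1:25) {
    s <- random_rna(sample(50:120, 1))
    expect_equal(unname(kmer_frequencies(s, 3)), unname(oracle_kmer(s, 3)),
                 tolerance = 1e-12)
    expect_equal(unname(nac(s)), unname(oracle_nac(s)), tolerance = 1e-12)
    expect_equal(unname(cksnap(s)), unname(oracle_cksnap(s)),
                 tolerance = 1e-12)
    expect_equal(unname(dac(s, tab)), unname(oracle_dac(s, tab)),
                 tolerance = 1e-12)
    expect_equal(unname(dcc(s, tab)), unname(oracle_dcc(s, tab)),
                 tolerance = 1e-12)
    expect_equal(unname(dacc(s, tab)),
                 unname(c(oracle_dac(s, tab), oracle_dcc(s, tab))),
                 tolerance = 1e-12)
    expect_equal(unname(pseknc(s, 3, 2, 0.1, tab)),
                 unname(oracle_pseknc(s, 3, 2, 0.1, tab)), tolerance = 1e-12)
    expect_equal(unname(pcpsednc(s, 2, 0.1, tab)),
                 unname(oracle_pcpsednc(s, 2, 0.1, tab)), tolerance = 1e-12)
  }
})

test_that("featurize builds aligned matrices for every descriptor", {
  set.seed(6)
  ds <- rna_set(c("r1", "r2", "r3"),
                replicate(3, random_rna(120)),
                label = c("a", "b", "a"))
  for (d in c("multiscale", "kmer", "nac", "cksnap", "dac", "dcc", "dacc",
              "pseknc", "pcpsednc")) {
    fm <- featurize(ds, d)
    expect_equal(rownames(fm), ds$id)
    expect_equal(attr(fm, "labels"), ds$label)
    expect_false(anyNA(fm))
  }
  fm <- featurize(ds)
  expect_equal(ncol(fm), 1344)
  # order invariance: descriptor rows depend only on the sequence
  perm <- c(3, 1, 2)
  ds_perm <- rna_set(ds$id[perm], ds$sequence[perm], ds$label[perm])
  fm_perm <- featurize(ds_perm)
  expect_equal(fm_perm[ds$id, ], fm[ds$id, ])
})
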