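# literal containment oracle: shared word multiset / words of shorter seq
oracle_identity <- function(a, b, k = 8) {
  words <- function(s) {
    vapply(1:(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1), "")
  }
  wa <- table(words(a))
  wb <- table(words(b))
  common <- intersect(names(wa), names(wb))
  shared <- sum(pmin(wa[common], wb[common]))
  shared / min(sum(wa), sum(wb))
}

mutate_seq <- function(seq, n_subs) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "U"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

test_that("exact deduplication keeps first occurrences in order", {
  ds <- rna_set(c("a", "b", "c"),
                c(strrep("ACGU", 60), strrep("ACGU", 60), strrep("ACGG", 60)))
  out <- deduplicate_exact(ds)
  expect_equal(out$id, c("a", "c"))
  expect_equal(attr(out, "n_removed"), 1L)

  distinct <- rna_set(c("x", "y"), c(strrep("AC", 110), strrep("GU", 110)))
  expect_equal(deduplicate_exact(distinct)$id, c("x", "y"))

  many <- rna_set(sprintf("r%d", 1:10), rep(strrep("ACGU", 55), 10))
  out <- deduplicate_exact(many)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_removed"), 9L)
})

test_that("length filter keeps the boundary length", {
  set.seed(3)
  ds <- rna_set(c("s", "t", "u"),
                c(random_rna(199), random_rna(200), random_rna(201)))
  out <- length_filter(ds, 200)
  expect_equal(out$id, c("t", "u"))
  expect_equal(nrow(length_filter(ds, 1)), 3L)
  empty <- length_filter(ds, 5000)
  expect_equal(nrow(empty), 0L)
})

test_that("redundancy reduction collapses contained and near-identical pairs", {
  set.seed(11)
  base <- random_rna(500)
  # substring containment -> identity estimate 1, longer kept
  ds <- rna_set(c("short", "long"),
                c(substr(base, 50, 400), base))
  out <- reduce_redundancy(ds)
  expect_equal(out$id, "long")
  expect_equal(identity_estimate(substr(base, 50, 400), base), 1.0)

  # planted pair: 10 substitutions in 500 nt stays above the 0.8 threshold
  mut <- mutate_seq(base, 10)
  est <- identity_estimate(base, mut)
  expect_equal(est, oracle_identity(base, mut), tolerance = 1e-12)
  expect_gte(est, 0.8)
  pair <- rna_set(c("orig", "mut"), c(base, mut))
  expect_equal(nrow(reduce_redundancy(pair)), 1L)

  # independent random pairs survive at 0.8
  other <- random_rna(500)
  est2 <- identity_estimate(base, other)
  expect_equal(est2, oracle_identity(base, other), tolerance = 1e-12)
  expect_lt(est2, 0.8)
  indep <- rna_set(c("a", "b"), c(base, other))
  expect_equal(nrow(reduce_redundancy(indep)), 2L)

  expect_error(reduce_redundancy(rna_set("a", "ACG")), "word_size")
})

test_that("no surviving pair reaches the identity threshold (all-pairs audit)", {
  set.seed(21)
  base <- random_rna(300)
  seqs <- c(replicate(6, random_rna(sample(250:350, 1))),
            vapply(1:5, function(i) mutate_seq(base, i), ""),
            base)
  ds <- rna_set(sprintf("s%02d", seq_along(seqs)), seqs)
  ds <- deduplicate_exact(ds)
  out <- reduce_redundancy(ds, redundancy_params(0.8, 5))
  survivors <- out$sequence
  for (i in seq_along(survivors)) {
    for (j in seq_along(survivors)) {
      if (i < j) {
        expect_lt(oracle_identity(survivors[i], survivors[j]), 0.8)
      }
    }
  }
})

test_that("intergroup deduplication removes shared sequences from all groups", {
  set.seed(4)
  shared <- random_rna(240)
  a <- rna_set(c("a1", "a2"), c(shared, random_rna(240)), label = "circRNA")
  b <- rna_set(c("b1", "b2"), c(shared, random_rna(240)), label = "mRNA")
  c_ <- rna_set("c1", shared, label = "lncRNA")
  out <- intergroup_dedup(list(a, b, c_))
  expect_equal(vapply(out, nrow, 0L), c(1L, 1L, 0L))
  expect_false(any(vapply(out, function(d) shared %in% d$sequence, TRUE)))

  disjoint <- intergroup_dedup(list(a, rna_set("z", random_rna(240))))
  expect_equal(disjoint[[1]]$id, a$id)
})

test_that("stratified split is 70/15/15 per class and seed-deterministic", {
  set.seed(9)
  mk <- function(cl, n) {
    rna_set(sprintf("%s_%03d", cl, 1:n),
            replicate(n, random_rna(210)), label = cl)
  }
  ds <- stratified_split(list(mk("circRNA", 100), mk("lncRNA", 100),
                              mk("mRNA", 101)),
                         split_spec(seed = 1))
  counts <- attr(ds, "split_counts")
  expect_equal(unname(counts["circRNA", ]), c(70L, 15L, 15L))
  expect_equal(unname(counts["mRNA", ]), c(70L, 15L, 16L))
  expect_equal(nrow(ds), 301L)

  ds2 <- stratified_split(list(mk("circRNA", 100), mk("lncRNA", 100),
                               mk("mRNA", 101)),
                          split_spec(seed = 1))
  expect_identical(ds$split, ds2$split)

  ds3 <- stratified_split(list(mk("circRNA", 100), mk("lncRNA", 100),
                               mk("mRNA", 101)),
                          split_spec(seed = 2))
  expect_false(identical(ds$split, ds3$split))

  expect_error(stratified_split(list(mk("circRNA", 2), mk("mRNA", 5))),
               "fewer than 3")
})

test_that("curation is monotone non-increasing and split conserves count", {
  spec <- generator_spec(default_profiles(), n_per_class = 40, seed = 13)
  full <- generate_dataset(spec)
  sets <- lapply(class_names(full), function(cl) {
    d <- full[full$label == cl, , drop = FALSE]
    attr(d, "class_names") <- class_names(full)
    class(d) <- c("rna_set", "data.frame")
    d
  })
  out <- curate(sets, spec = split_spec(seed = 3))
  report <- attr(out, "curation_report")
  for (cl in class_names(full)) {
    counts <- report$count[report$class == cl]
    expect_true(all(diff(counts) <= 0))
  }
  expect_equal(nrow(out), sum(report$count[report$stage == "intergroup_dedup"]))
})
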