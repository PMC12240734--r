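# Independent literal-formula oracles used to validate the fast
# implementations. Everything here is written as plainly as possible
# (explicit loops, substring scans) and never shares code with R/.

random_rna <- function(len, with_n = FALSE) {
  alpha <- c("A", "C", "G", "U", if (with_n) "N")
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

all_kmers <- function(k) {
  nm <- ""
  for (i in seq_len(k)) nm <- paste0(rep(nm, each = 4), c("A", "C", "G", "U"))
  nm
}

oracle_kmer <- function(seq, k) {
  words <- all_kmers(k)
  counts <- setNames(numeric(length(words)), words)
  n_valid <- 0
  if (nchar(seq) >= k) {
    for (i in 1:(nchar(seq) - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) {
        counts[w] <- counts[w] + 1
        n_valid <- n_valid + 1
      }
    }
  }
  if (n_valid > 0) counts / n_valid else counts
}

oracle_nac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% c("A", "C", "G", "U")]
  out <- setNames(numeric(4), c("A", "C", "G", "U"))
  if (!length(chars)) return(out)
  for (b in names(out)) out[b] <- sum(chars == b) / length(chars)
  out
}

oracle_cksnap <- function(seq, max_gap = 5) {
  pairs <- all_kmers(2)
  chars <- strsplit(seq, "")[[1]]
  out <- numeric(0)
  for (g in 0:max_gap) {
    block <- setNames(numeric(16), paste0("g", g, ":", pairs))
    n_valid <- 0
    last <- length(chars) - g - 1
    if (last >= 1) {
      for (i in 1:last) {
        x <- chars[i]; y <- chars[i + g + 1]
        if (x != "N" && y != "N") {
          block[paste0("g", g, ":", x, y)] <-
            block[paste0("g", g, ":", x, y)] + 1
          n_valid <- n_valid + 1
        }
      }
    }
    if (n_valid > 0) block <- block / n_valid
    out <- c(out, block)
  }
  out
}

# standardized property values along the dinucleotide positions
oracle_profile <- function(seq, table) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  P <- matrix(NA_real_, L - 1, ncol(table))
  colnames(P) <- colnames(table)
  for (i in 1:(L - 1)) {
    dn <- paste0(chars[i], chars[i + 1])
    if (dn %in% rownames(table)) P[i, ] <- table[dn, ]
  }
  P
}

oracle_dac <- function(seq, table, max_lag = 2) {
  P <- oracle_profile(seq, table)
  n <- nrow(P)
  out <- numeric(0)
  for (u in colnames(table)) {
    pbar <- mean(P[, u])
    for (lag in 1:max_lag) {
      acc <- 0
      for (i in 1:(n - lag)) {
        acc <- acc + (P[i, u] - pbar) * (P[i + lag, u] - pbar)
      }
      out <- c(out, acc / (n - lag))
    }
  }
  out
}

oracle_dcc <- function(seq, table, max_lag = 2) {
  P <- oracle_profile(seq, table)
  n <- nrow(P)
  out <- numeric(0)
  for (u1 in colnames(table)) for (u2 in colnames(table)) {
    if (u1 == u2) next
    m1 <- mean(P[, u1]); m2 <- mean(P[, u2])
    for (lag in 1:max_lag) {
      acc <- 0
      for (i in 1:(n - lag)) {
        acc <- acc + (P[i, u1] - m1) * (P[i + lag, u2] - m2)
      }
      out <- c(out, acc / (n - lag))
    }
  }
  out
}

oracle_pseknc <- function(seq, k, lambda, w, table) {
  P <- oracle_profile(seq, table)
  n <- nrow(P)
  theta <- numeric(lambda)
  for (j in 1:lambda) {
    acc <- 0
    for (i in 1:(n - j)) {
      acc <- acc + mean((P[i, ] - P[i + j, ])^2)
    }
    theta[j] <- acc / (n - j)
  }
  f <- oracle_kmer(seq, k)
  denom <- sum(f) + w * sum(theta)
  c(f, w * theta) / denom
}

oracle_pcpsednc <- function(seq, lambda, w, table) {
  P <- oracle_profile(seq, table)
  n <- nrow(P)
  theta <- numeric(lambda)
  for (j in 1:lambda) {
    acc <- 0
    for (i in 1:(n - j)) {
      acc <- acc + mean(P[i, ] * P[i + j, ])
    }
    theta[j] <- acc / (n - j)
  }
  f <- oracle_kmer(seq, 2)
  denom <- sum(f) + w * sum(theta)
  c(f, w * theta) / denom
}

# two-loop softmax attention oracle for a single head
oracle_attention <- function(Q, K, V) {
  n <- nrow(Q)
  d <- ncol(Q)
  W <- matrix(0, n, nrow(K))
  for (i in 1:n) {
    logits <- numeric(nrow(K))
    for (j in 1:nrow(K)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    e <- exp(logits - max(logits))
    W[i, ] <- e / sum(e)
  }
  list(output = W %*% V, weights = W)
}

# explicit-loop implementation of the macro/weighted metric formulas
oracle_metrics <- function(cm) {
  N <- nrow(cm)
  total <- sum(cm)
  tp <- fp <- fn <- prec <- rec <- f1 <- numeric(N)
  for (i in 1:N) {
    tp[i] <- cm[i, i]
    fp[i] <- sum(cm[, i]) - cm[i, i]
    fn[i] <- sum(cm[i, ]) - cm[i, i]
    prec[i] <- if (tp[i] + fp[i] > 0) tp[i] / (tp[i] + fp[i]) else 0
    rec[i] <- if (tp[i] + fn[i] > 0) tp[i] / (tp[i] + fn[i]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else 0
  }
  pm <- 0; pw <- 0; pw3 <- 0; rm <- 0; rw <- 0; fm <- 0; fw <- 0; acc <- 0
  for (i in 1:N) {
    pm <- pm + prec[i] / N
    pw <- pw + (tp[i] + fn[i]) * prec[i] / total
    pw3 <- pw3 + (tp[i] + fp[i]) * prec[i] / total
    rm <- rm + rec[i] / N
    rw <- rw + (tp[i] + fn[i]) * rec[i] / total
    fm <- fm + f1[i] / N
    fw <- fw + (tp[i] + fn[i]) * f1[i] / total
    acc <- acc + cm[i, i] / total
  }
  list(precision_macro = pm, precision_weighted = pw,
       precision_weighted_eq3 = pw3, recall_macro = rm,
       recall_weighted = rw, f1_macro = fm, f1_weighted = fw,
       accuracy = acc)
}

# brute-force three-frame ORF scan: for every AUG, walk codon by codon to
# the first stop; length start..stop inclusive
oracle_orf <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  best <- 0
  if (L < 6) return(0L)
  for (start in 1:(L - 5)) {
    if (paste(chars[start:(start + 2)], collapse = "") != "AUG") next
    pos <- start + 3
    while (pos + 2 <= L) {
      codon <- paste(chars[pos:(pos + 2)], collapse = "")
      if (codon %in% c("UAA", "UAG", "UGA")) {
        best <- max(best, pos + 2 - start + 1)
        break
      }
      pos <- pos + 3
    }
  }
  as.integer(best)
}

# small labelled rna_set with obvious class structure, for model tests
toy_split_dataset <- function(n_per_class = 60, seed = 5, len = 300) {
  set.seed(seed)
  make_seq <- function(bias) {
    p <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
    p[names(bias)] <- p[names(bias)] + bias
    p <- p / sum(p)
    paste(sample(names(p), len, TRUE, prob = p), collapse = "")
  }
  seqs <- c(replicate(n_per_class, make_seq(c(A = 0.2))),
            replicate(n_per_class, make_seq(c(C = 0.2))),
            replicate(n_per_class, make_seq(c(G = 0.2))))
  labels <- rep(c("alpha", "beta", "gamma"), each = n_per_class)
  ds <- rna_set(sprintf("%s_%03d", labels, seq_along(seqs)), seqs,
                label = labels)
  stratified_split(ds, split_spec(seed = seed))
}
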