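# Shared fixture builders. Everything is generated in code; no data files.

make_records <- function(subject, predicate, object, s_score = 800,
                         o_score = 800, cooc = 5) {
  data.frame(subject_id = subject, predicate = predicate, object_id = object,
             subject_score = s_score, object_score = o_score,
             cooccurrence = cooc, stringsAsFactors = FALSE)
}

# Two disjoint cliques over one relation; scores uniform.
make_two_cliques <- function(size = 10L) {
  cliques <- list(sprintf("A%02d", seq_len(size)),
                  sprintf("B%02d", seq_len(size)))
  do.call(rbind, lapply(cliques, function(cl) {
    eg <- expand.grid(s = cl, o = cl, stringsAsFactors = FALSE)
    eg <- eg[eg$s < eg$o, ]
    make_records(eg$s, "REL", eg$o)
  }))
}

# Random connected graph on n vertices: a spanning path plus extra edges.
make_random_graph_records <- function(n = 50L, extra = 2L * n, seed = 42L) {
  withr::with_seed(seed, {
    v <- sprintf("V%03d", seq_len(n))
    path <- make_records(v[-n], "REL1", v[-1L])
    s <- v[sample.int(n, extra, replace = TRUE)]
    o <- v[sample.int(n, extra, replace = TRUE)]
    keep <- s != o
    rnd <- make_records(s[keep], sample(c("REL1", "REL2"), sum(keep), TRUE),
                        o[keep], s_score = runif(sum(keep), 100, 1000),
                        o_score = runif(sum(keep), 100, 1000),
                        cooc = sample(1:20, sum(keep), TRUE))
    rbind(path, rnd)
  })
}

random_embedding_table <- function(ids, dim, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(ids) * dim), nrow = length(ids))
    rownames(m) <- ids
    m
  })
}

# star with directed spokes hub -> leaves (for dead-end walks)
make_star_records <- function(n_leaves = 4L) {
  make_records("HUB", "REL", sprintf("LEAF%d", seq_len(n_leaves)))
}

# a tiny labelled pair benchmark over an embedding table
make_toy_pairs <- function(n_pos = 10L, n_neg = 10L) {
  data.frame(
    drug_id = sprintf("D%02d", seq_len(n_pos + n_neg)),
    disease_id = sprintf("X%02d", seq_len(n_pos + n_neg)),
    label = rep(c(1L, -1L), c(n_pos, n_neg)),
    stringsAsFactors = FALSE)
}

# brute-force AUC by counting concordant positive/negative pairs
brute_force_auc <- function(y, score) {
  pos <- which(y > 0); neg <- which(y <= 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  tot / (length(pos) * length(neg))
}
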