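test_that("energy is the norm of the translation residual", {
  expect_equal(energy(c(1, 2), c(3, 4), c(4, 6)), 0)
  expect_equal(energy(c(1, 0), c(0, 1), c(0, 0), norm = "L2"), sqrt(2))
  expect_equal(energy(c(1, 0), c(0, 1), c(0, 0), norm = "L1"), 2)
  withr::with_seed(1, {
    for (i in 1:100) {
      expect_gte(energy(rnorm(5), rnorm(5), rnorm(5)), 0)
    }
  })
  expect_error(energy(c(1, 2), c(1, 2, 3), c(1, 2)), "mismatch")
})

test_that("corruption replaces exactly one side, never the relation", {
  pool <- sprintf("E%02d", 1:10)
  tri <- list(head = "E01", relation = "r", tail = "E02")
  sides <- withr::with_seed(3, {
    vapply(1:10000, function(i) {
      c_tri <- corrupt(tri, pool)
      expect_identical(c_tri$relation, "r")
      if (c_tri$corrupted == "head") {
        expect_identical(c_tri$tail, tri$tail)
        expect_false(identical(c_tri$head, tri$head))
      } else {
        expect_identical(c_tri$head, tri$head)
        expect_false(identical(c_tri$tail, tri$tail))
      }
      c_tri$corrupted
    }, "")
  })
  expect_lt(abs(mean(sides == "head") - 0.5), 0.02)
  # forced case: pool of two entities
  forced <- withr::with_seed(4, replicate(50, {
    ct <- corrupt(list(head = "A", relation = "r", tail = "B"), c("A", "B"))
    if (ct$corrupted == "head") ct$head else ct$tail
  }))
  expect_true(all(forced %in% c("A", "B")))
  expect_true(all(withr::with_seed(5, replicate(20, {
    ct <- corrupt(list(head = "A", relation = "r", tail = "B"), c("A", "B"))
    (ct$corrupted == "head" && ct$head == "B") ||
      (ct$corrupted == "tail" && ct$tail == "A")
  }))))
  expect_error(corrupt(tri, "E01"), "at least two")
})

test_that("margin loss matches hand-computed toy cases", {
  # one pair: gamma=1, d=0.5, f=0.5, d'=1 -> [1 + 1 - 1]_+ = 1
  ents <- rbind(h = c(0.5, 0), t = c(0, 0), t2 = c(1.5, 0))
  rels <- rbind(r = c(0, 0))
  pos <- data.frame(head = "h", relation = "r", tail = "t", confidence = 0.5)
  neg <- data.frame(head = "h", relation = "r", tail = "t2")
  p <- transe_params(dimension = 2L, margin = 1)
  expect_equal(margin_loss(pos, neg, ents, rels, p), 1)
  # hinge inactive: d=0.2, f=1, d'=5
  ents2 <- rbind(h = c(0.2, 0), t = c(0, 0), t2 = c(5.2, 0))
  pos2 <- data.frame(head = "h", relation = "r", tail = "t", confidence = 1)
  expect_equal(margin_loss(pos2, neg, ents2, rels, p), 0)
  # hinge boundary at gamma=0 with d/f = d'
  p0 <- transe_params(dimension = 2L, margin = 1e-9)
  ents3 <- rbind(h = c(0.5, 0), t = c(0, 0), t2 = c(1.5, 0))
  expect_lt(margin_loss(pos, neg, ents3, rels, p0), 1e-8)
})

test_that("weighted loss with unit confidences equals the unweighted loss exactly", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      n <- sample(2:6, 1)
      ids <- sprintf("E%d", 1:8)
      ents <- matrix(rnorm(8 * 4), 8, dimnames = list(ids, NULL))
      rels <- matrix(rnorm(2 * 4), 2, dimnames = list(c("r1", "r2"), NULL))
      pos <- data.frame(head = sample(ids, n, TRUE),
                        relation = sample(c("r1", "r2"), n, TRUE),
                        tail = sample(ids, n, TRUE),
                        confidence = rep(1, n))
      neg <- data.frame(head = sample(ids, n, TRUE),
                        relation = pos$relation,
                        tail = sample(ids, n, TRUE))
      p <- transe_params(dimension = 4L)
      expect_identical(margin_loss(pos, neg, ents, rels, p, "divide"),
                       margin_loss(pos, neg, ents, rels, p, "none"))
    }
  })
})

test_that("lowering a positive triplet's confidence weakly increases the loss", {
  withr::with_seed(11, {
    ids <- sprintf("E%d", 1:6)
    ents <- matrix(rnorm(6 * 4), 6, dimnames = list(ids, NULL))
    rels <- matrix(rnorm(4), 1, dimnames = list("r", NULL))
    pos <- data.frame(head = ids[1:3], relation = "r", tail = ids[4:6],
                      confidence = 1)
    neg <- data.frame(head = ids[c(2, 1, 1)], relation = "r",
                      tail = ids[c(6, 5, 4)])
    p <- transe_params(dimension = 4L)
    base <- margin_loss(pos, neg, ents, rels, p)
    for (fv in c(0.8, 0.5, 0.1, 0.001)) {
      pos2 <- pos; pos2$confidence[2] <- fv
      expect_gte(margin_loss(pos2, neg, ents, rels, p), base)
      base <- margin_loss(pos2, neg, ents, rels, p)
    }
    expect_error(margin_loss(transform(pos, confidence = 2), neg, ents,
                             rels, p), "\\(0, 1\\]")
  })
})

# small planted KG used by the training tests: two relations, 20 entities,
# block structure so the tail is predictable from (head, relation)
make_tiny_kg <- function(seed) {
  withr::with_seed(seed, {
    ents <- sprintf("E%02d", 1:20)
    blocks <- rep(1:4, each = 5)
    rows <- lapply(1:60, function(i) {
      b <- sample(1:4, 1)
      memb <- ents[blocks == b]
      data.frame(head = sample(memb, 1), relation = sample(c("r1", "r2"), 1),
                 tail = sample(memb, 1), stringsAsFactors = FALSE)
    })
    tri <- do.call(rbind, rows)
    tri[tri$head != tri$tail, ]
  })
}

test_that("training lowers the rank of true tails below an untrained baseline", {
  for (s in 1:5) {
    tri <- make_tiny_kg(s)
    p <- transe_params(dimension = 16L, alpha = 0.01, batch_size = 16L,
                       epochs = 100L, seed = s)
    fit <- train_transe(tri, p)
    # untrained baseline: random unit vectors with the same layout
    rand <- fit
    withr::with_seed(1000 + s, {
      rand$entities <- l2_normalize(matrix(
        rnorm(length(fit$entities)), nrow(fit$entities),
        dimnames = dimnames(fit$entities)))
      rand$relations <- matrix(rnorm(length(fit$relations)),
                               nrow(fit$relations),
                               dimnames = dimnames(fit$relations))
    })
    expect_lt(mean(tail_ranks(fit, tri)), mean(tail_ranks(rand, tri)))
    # loss decreases on easy data
    expect_lt(fit$loss[length(fit$loss)], fit$loss[1L])
    # entity norms stay on the unit sphere
    expect_true(all(abs(sqrt(rowSums(fit$entities^2)) - 1) < 1e-6))
  }
})

test_that("training is reproducible given the seed", {
  tri <- make_tiny_kg(2)
  p <- transe_params(dimension = 8L, epochs = 10L, seed = 5L)
  expect_identical(train_transe(tri, p)$entities,
                   train_transe(tri, p)$entities)
  expect_error(train_transe(tri[0, ], p), "empty")
})

test_that("weighted training separates true from spurious triplet energies", {
  for (s in 1:5) {
    sy <- generate_synth_kg(synth_config(n_drugs = 20L, n_diseases = 5L,
                                         n_filler_concepts = 20L, n_benchmark_pairs = 40L,
                                         edges_per_vertex = 6,
                                         noise_rate = 0.3, seed = s))
    p <- transe_params(dimension = 16L, alpha = 0.01, batch_size = 64L,
                       epochs = 60L, seed = s)
    tri <- data.frame(head = sy$triplets$subject_id,
                      relation = sy$triplets$predicate,
                      tail = sy$triplets$object_id,
                      confidence = ifelse(sy$truth_flags, 1, p$f_min))
    fit <- train_transe(tri, p, weighted = TRUE)
    en <- triplet_energies(fit, tri)
    expect_lt(mean(en[sy$truth_flags]), mean(en[!sy$truth_flags]))
  }
})
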