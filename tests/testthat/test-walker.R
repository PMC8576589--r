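test_that("single-entry neighbourhoods make both samplers deterministic", {
  g <- score_graph(build_graph(make_records("A", "p", "B")))
  withr::with_seed(1, {
    expect_equal(uniform_next(g, "A"), list(predicate = "p", vertex = "B"))
    expect_equal(weighted_next(g, "A"), list(predicate = "p", vertex = "B"))
  })
  expect_error(weighted_next(build_graph(make_records("A", "p", "B")), "A"),
               "no scores")
})

test_that("uniform sampling is uniform over the adjacency entries", {
  rec <- make_records("A", c("p1", "p2", "p3"), c("B", "C", "D"))
  g <- build_graph(rec)
  draws <- withr::with_seed(11, {
    vapply(1:30000, function(i) uniform_next(g, "A")$vertex, "")
  })
  freq <- table(draws) / length(draws)
  expect_true(all(freq >= 0.30 & freq <= 0.3667))
  expect_gt(stats::chisq.test(table(draws))$p.value, 0.001)
})

test_that("weighted sampling follows the softmax of normalized scores", {
  # two entries from A whose raw weights differ 10-fold: f = (1, 0.1)
  rec <- make_records("A", c("p", "q"), c("B", "C"), s_score = 1000,
                      o_score = 1000, cooc = c(10, 1))
  g <- score_graph(build_graph(rec))
  expect_equal(sort(g$scores$f), c(0.1, 1))
  draws <- withr::with_seed(5, {
    vapply(1:30000, function(i) weighted_next(g, "A")$vertex, "")
  })
  p_b <- mean(draws == "B")
  expect_lt(abs(p_b - exp(1) / (exp(1) + exp(0.1))), 0.02)  # ~0.7109
})

test_that("equal scores reduce the weighted sampler to the uniform one", {
  rec <- make_records("A", c("p1", "p2", "p3"), c("B", "C", "D"))
  g <- score_graph(build_graph(rec))
  expect_equal(length(unique(g$scores$f)), 1L)
  draws <- withr::with_seed(2, {
    vapply(1:9000, function(i) weighted_next(g, "A")$vertex, "")
  })
  expect_gt(stats::chisq.test(table(draws))$p.value, 0.001)
})

test_that("a two-vertex graph forces alternating walks", {
  g <- build_graph(make_records("A", "p", "B"))
  co <- generate_walks(g, walk_params(num_walks_per_vertex = 2L,
                                      walk_length = 3L, seed = 1L))
  expect_equal(length(co$sequences), 4L)
  expect_true(all(vapply(co$sequences, function(s)
    identical(s, c("A", "B", "A")) || identical(s, c("B", "A", "B")),
    logical(1))))
})

test_that("dead ends terminate walks early in directed mode", {
  g <- build_graph(make_star_records(4L), mode = "directed")
  co <- generate_walks(g, walk_params(num_walks_per_vertex = 1L,
                                      walk_length = 10L, seed = 3L))
  by_start <- split(co$sequences, vapply(co$sequences, `[[`, "", 1L))
  for (leaf in sprintf("LEAF%d", 1:4)) {
    expect_equal(by_start[[leaf]][[1L]], leaf)  # length-1 walk
  }
  hub_walk <- by_start[["HUB"]][[1L]]
  expect_equal(length(hub_walk), 2L)  # hub -> leaf -> dead end
})

test_that("every consecutive token pair in a corpus is a graph edge", {
  g <- build_graph(make_random_graph_records(50L, 100L, seed = 9L))
  co <- generate_walks(g, walk_params(num_walks_per_vertex = 5L,
                                      walk_length = 10L, seed = 4L))
  expect_equal(length(co$sequences), 50L * 5L)
  edge_keys <- unique(c(paste(g$edges$subject_id, g$edges$object_id),
                        paste(g$edges$object_id, g$edges$subject_id)))
  for (s in co$sequences) {
    if (length(s) < 2L) next
    expect_true(all(paste(s[-length(s)], s[-1L]) %in% edge_keys))
  }
})

test_that("corpora are reproducible from the seed and emit_predicates works", {
  g <- score_graph(build_graph(make_random_graph_records(20L, 40L)))
  p <- walk_params(num_walks_per_vertex = 3L, walk_length = 8L, seed = 17L,
                   sampler = "weighted")
  expect_identical(generate_walks(g, p)$sequences,
                   generate_walks(g, p)$sequences)
  p2 <- p; p2$seed <- 18L
  expect_false(identical(generate_walks(g, p)$sequences,
                         generate_walks(g, p2)$sequences))
  p$emit_predicates <- TRUE
  co <- generate_walks(g, p)
  s <- co$sequences[[1L]]
  expect_true(all(startsWith(s[seq(2L, length(s), by = 2L)], "p:")))
})

test_that("weighted walks favour high-confidence entries", {
  # hub H: edge to U has f = 1, edge to V has f ~ 0.01
  rec <- make_records("H", c("p", "p"), c("U", "V"), s_score = c(1000, 100),
                      o_score = c(1000, 100), cooc = c(10, 1))
  g <- score_graph(build_graph(rec))
  co <- generate_walks(g, walk_params(num_walks_per_vertex = 20L,
                                      walk_length = 100L, seed = 8L,
                                      sampler = "weighted"))
  toks <- unlist(co$sequences)
  expect_gt(sum(toks == "U") / sum(toks == "V"), 1)
})

test_that("uniform walk visits approach uniformity on a regular graph", {
  n <- 20L
  v <- sprintf("R%02d", seq_len(n))
  ring <- make_records(v, "p", v[c(2:n, 1L)])  # cycle, degree 2 undirected
  g <- build_graph(ring)
  co <- generate_walks(g, walk_params(num_walks_per_vertex = 50L,
                                      walk_length = 100L, seed = 21L))
  freq <- table(factor(unlist(co$sequences), levels = v))
  emp <- as.numeric(freq) / sum(freq)
  tv <- 0.5 * sum(abs(emp - 1 / n))
  expect_lt(tv, 0.05)
})

test_that("weighted walks require scores and error otherwise", {
  g <- build_graph(make_records("A", "p", "B"))
  expect_error(generate_walks(g, walk_params(sampler = "weighted")),
               "scored graph")
})
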