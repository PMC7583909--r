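test_that("union vectors have the documented lengths per kind", {
  fx <- tiny_fixture()
  fm_l <- fit_feature_model(fx$lncs, features = c("kmer", "ctd", "doc2vec"),
                            d2v_epochs = 2, seed = 1)
  fm_m <- fit_feature_model(fx$mirs, features = c("kmer", "ctd", "doc2vec"),
                            d2v_epochs = 2, seed = 1)
  b_l <- encode_rna(fx$lncs[1, ], fm_l)
  b_m <- encode_rna(fx$mirs[1, ], fm_m)
  expect_length(union_vector(b_l), 340L + 30L + 128L)  # 498
  expect_length(union_vector(b_m), 84L + 30L + 64L)    # 178
  b_l$phases <- lapply(b_l$phases, function(p) p[c("kmer", "ctd")])
  expect_error(union_vector(b_l), "doc2vec")
})

test_that("LNS weights satisfy the simplex constraints and recover duplicates", {
  # exact duplicate neighbor takes all the weight
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1))
  W <- lns_weights(X, k_nn = 2)
  expect_equal(W[1, 2], 1, tolerance = 1e-6)
  expect_equal(W[2, 1], 1, tolerance = 1e-6)
  # degenerate all-identical rows still produce a valid simplex row
  Wd <- lns_weights(matrix(1, 4, 3), k_nn = 2)
  expect_equal(unname(rowSums(Wd)), rep(1, 4), tolerance = 1e-6)
  expect_error(lns_weights(matrix(1, 1, 3)), "at least 2")
})

test_that("LNS objective is no worse than uniform neighbor weights", {
  for (s in 1:5) {
    X <- withr::with_seed(s, matrix(rnorm(12 * 6), 12, 6))
    W <- lns_weights(X, k_nn = 4)
    for (i in 1:3) {
      nb <- which(W[i, ] > 0)
      d2 <- colSums((t(X) - X[i, ])^2)
      d2[i] <- Inf
      near <- order(d2)[1:4]
      obj <- function(w, idx) sum((X[i, ] - colSums(w * X[idx, , drop = FALSE]))^2)
      w_opt <- W[i, near]
      expect_lte(obj(w_opt, near), obj(rep(0.25, 4), near) + 1e-8)
    }
  }
})

test_that("graph construction follows the strict positive top-k rule", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.5; W[1, 3] <- 0.3; W[1, 4] <- 0.2
  W[2, 1] <- 1; W[3, 1] <- 1; W[4, 3] <- 1
  g <- build_graph(W, top_k = 15)
  expect_equal(g$adj[[1]], c(2L, 3L, 4L))   # 3 positive entries, top_k larger
  # zero weight never creates an edge
  W0 <- matrix(0, 3, 3); W0[1, 2] <- 1; W0[2, 1] <- 1; W0[3, 1] <- 1e-9
  g0 <- build_graph(W0, top_k = 2)
  expect_equal(g0$adj[[1]], c(2L, 3L))
  expect_length(g0$adj[[2]], 1L)
  W0[3, 1] <- 0
  g0 <- build_graph(W0, top_k = 2)
  expect_length(g0$adj[[3]], 0L)
  # degree bound: union of two directed top-k selections
  X <- withr::with_seed(3, matrix(rnorm(20 * 5), 20, 5))
  g2 <- build_graph(lns_weights(X, k_nn = 6), top_k = 3)
  expect_true(all(lengths(g2$adj) <= 6L))
})

test_that("a chain of near-duplicates yields a connected graph", {
  # 5 points on a line; each point's nearest neighbors are its chain
  # neighbors, so the union graph must be connected
  X <- cbind(c(0, 1, 2, 3, 4), 0)
  g <- build_graph(lns_weights(X, k_nn = 2), top_k = 2)
  visited <- 1L; frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- setdiff(unlist(g$adj[frontier]), visited)
    visited <- c(visited, nxt); frontier <- nxt
  }
  expect_setequal(visited, 1:5)
})

test_that("role-based embeddings are 128-d by default, deterministic, and role-shared", {
  X <- withr::with_seed(5, matrix(rnorm(12 * 8), 12, 8))
  X[2, ] <- X[1, ]  # identical attributes -> identical role -> identical vector
  g <- build_graph(lns_weights(X, k_nn = 3), top_k = 3)
  e1 <- embed_nodes(g, X, n_walks = 4, walk_len = 10, epochs = 2, seed = 9)
  expect_equal(dim(e1$vectors), c(12L, 128L))
  expect_identical(e1$vectors[1, ], e1$vectors[2, ])
  e2 <- embed_nodes(g, X, n_walks = 4, walk_len = 10, epochs = 2, seed = 9)
  expect_identical(e1$roles, e2$roles)
  expect_identical(e1$vectors, e2$vectors)
})

test_that("two attribute-distinct cliques separate in embedding space", {
  # disconnected cliques with different attribute profiles: within-clique
  # cosine similarity should exceed between-clique similarity for most seeds
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  adj <- apply(A > 0, 1, which, simplify = FALSE)
  wins <- 0L
  for (s in 1:10) {
    X <- withr::with_seed(s, {
      base <- matrix(rnorm(8 * 10, sd = 0.1), 8, 10)
      base[1:4, 1] <- base[1:4, 1] + 3
      base[5:8, 2] <- base[5:8, 2] + 3
      base
    })
    g <- structure(list(node_ids = as.character(1:8),
                        W = A / rowSums(A), adj = adj),
                   class = "similarity_graph")
    emb <- suppressWarnings(
      embed_nodes(g, X, dim = 16, n_roles = 8, n_walks = 5, walk_len = 10,
                  epochs = 3, seed = 400 + s)$vectors)
    pairs_within <- c(); pairs_between <- c()
    for (i in 1:7) for (j in (i + 1):8) {
      cs <- cosine(emb[i, ], emb[j, ])
      if (is.na(cs)) next
      if ((i <= 4) == (j <= 4)) pairs_within <- c(pairs_within, cs)
      else pairs_between <- c(pairs_between, cs)
    }
    if (mean(pairs_within) > mean(pairs_between)) wins <- wins + 1L
  }
  expect_gt(wins, 5L)
})

test_that("unseen nodes embed through their role; unwalked roles warn and zero", {
  X <- withr::with_seed(6, matrix(rnorm(10 * 6), 10, 6))
  g <- build_graph(lns_weights(X, k_nn = 3), top_k = 3)
  emb <- embed_nodes(g, X, dim = 8, n_roles = 4, n_walks = 4, walk_len = 8,
                     epochs = 2, seed = 2)
  # a new node identical to node 1 gets node 1's (role) embedding
  v <- embed_new_nodes(emb, X[1, , drop = FALSE])
  expect_equal(v[1, ], unname(emb$vectors[1, ]))
  # force a role that never occurs in walks
  emb2 <- emb
  emb2$walked_roles <- setdiff(emb2$walked_roles, emb2$roles[1])
  expect_warning(v2 <- embed_new_nodes(emb2, X[1, , drop = FALSE]),
                 "absent from all walks")
  expect_equal(unname(v2[1, ]), rep(0, 8))
})
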