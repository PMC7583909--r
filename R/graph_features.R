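#' Union feature vector of an RNA
#'
#' Concatenates the whole-sequence (phase-0) k-mer, CTD and doc2vec vectors of
#' a feature bundle into the attribute vector used to build the similarity
#' graph: length 340 + 30 + 128 = 498 for a lncRNA, 84 + 30 + 64 = 178 for a
#' miRNA.
#'
#' @param bundle A `feature_bundle` (see [encode_rna()]).
#' @return Numeric vector.
#' @export
union_vector <- function(bundle) {
  p0 <- bundle$phases[[1]]
  for (cat in c("kmer", "ctd", "doc2vec"))
    if (is.null(p0[[cat]]))
      stop_input("bundle for '%s' lacks the %s category", bundle$rna_id, cat)
  unname(c(p0$kmer, p0$ctd, p0$doc2vec))
}

# Euclidean projection onto the probability simplex (sort-based algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Linear neighborhood similarity (LNS) weights
#'
#' For each row `x_i` of `X`, finds its `k_nn` Euclidean-nearest other rows
#' and solves the constrained reconstruction problem
#' `min || x_i - sum_j w_ij x_j ||^2` subject to `w_ij >= 0`,
#' `sum_j w_ij = 1` (weights outside the neighborhood are zero), by projected
#' gradient descent on the simplex. The resulting row-stochastic matrix is the
#' similarity used to build the neighborhood graph.
#'
#' @param X Numeric matrix, one RNA per row (union vectors), `n >= 2` rows.
#' @param k_nn Neighborhood size for the reconstruction (default 15, shared
#'   with the top-k edge rule; capped at `n - 1`).
#' @param max_iter,tol Projected-gradient iteration cap (default 1000) and
#'   convergence tolerance on the weight update (default 1e-8).
#' @return `n x n` matrix with zero diagonal; each row is non-negative and
#'   sums to 1.
#' @export
lns_weights <- function(X, k_nn = 15L, max_iter = 1000L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop_input("LNS needs at least 2 rows, got %d", n)
  k <- min(as.integer(k_nn), n - 1L)
  W <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(X, 2L, X[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    C <- X[nb, , drop = FALSE]
    G <- tcrossprod(C)                      # k x k Gram matrix
    b <- as.numeric(C %*% X[i, ])
    L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
    w <- rep(1 / k, k)
    if (L > 0) {
      step <- 1 / L
      for (it in seq_len(max_iter)) {
        w_new <- project_simplex(w - step * (as.numeric(G %*% w) - b))
        if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
        w <- w_new
      }
    }
    W[i, nb] <- w
  }
  W
}

#' Build the top-k neighborhood graph from an LNS weight matrix
#'
#' Node `i` selects the up-to-`top_k` highest-weight entries of row `i` that
#' have weight strictly greater than zero; the undirected edge set is the
#' union of the directed selections (an edge exists if either endpoint selects
#' the other).
#'
#' @param W Row-stochastic similarity matrix from [lns_weights()].
#' @param top_k Maximum neighbors selected per row (default 15).
#' @param node_ids Optional node identifiers (default: rownames of `W`).
#' @return An object of class `similarity_graph`: `node_ids`, `W`, and `adj`
#'   (list of neighbor indices per node).
#' @export
build_graph <- function(W, top_k = 15L, node_ids = rownames(W)) {
  n <- nrow(W)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n))
  sel <- lapply(seq_len(n), function(i) {
    w <- W[i, ]
    cand <- which(w > 0)
    cand[order(w[cand], decreasing = TRUE)][seq_len(min(top_k, length(cand)))]
  })
  adj <- vector("list", n)
  for (i in seq_len(n))
    for (j in sel[[i]]) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(node_ids = node_ids, W = W, adj = adj),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  ne <- sum(lengths(x$adj)) / 2
  cat(sprintf("similarity graph: %d nodes, %d undirected edges\n",
              length(x$node_ids), ne))
  invisible(x)
}

#' Write a similarity graph as an edge-list TSV
#'
#' @param graph A `similarity_graph`.
#' @param path Output path; columns `id1`, `id2`, `weight` (the larger of the
#'   two directed LNS weights).
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  rows <- list()
  for (i in seq_along(graph$adj))
    for (j in graph$adj[[i]])
      if (i < j)
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = graph$node_ids[i], id2 = graph$node_ids[j],
          weight = max(graph$W[i, j], graph$W[j, i]))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(), id2 = character(), weight = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Discrete role assignment: random projection of the attribute vectors to at
# most `proj_dim` dimensions, 2-bin median split per projected dimension, and
# a deterministic integer hash of the bit signature into `n_roles` buckets.
# Returns the projection/median parameters so unseen nodes can be assigned
# the same way.
fit_roles <- function(X, n_roles = 32L, proj_dim = 64L, seed = 1L) {
  d <- ncol(X)
  p <- min(proj_dim, d)
  P <- with_seed(seed, matrix(stats::rnorm(d * p), d, p) / sqrt(d))
  Z <- X %*% P
  med <- apply(Z, 2L, stats::median)
  model <- list(P = P, med = med, n_roles = as.integer(n_roles))
  model$roles <- assign_roles(model, X)
  model
}

assign_roles <- function(model, X) {
  Z <- as.matrix(X) %*% model$P
  bits <- sweep(Z, 2L, model$med, `>`)
  apply(bits, 1L, function(b) {
    h <- 0
    for (bit in as.integer(b)) h <- (h * 31 + bit + 1) %% 1000003
    as.integer(h %% model$n_roles) + 1L
  })
}

# Memoryless (order-1) uniform random walks over the adjacency list.
random_walks <- function(adj, n_walks, walk_len) {
  walks <- list()
  for (start in seq_along(adj))
    for (r in seq_len(n_walks)) {
      walk <- integer(walk_len)
      walk[1] <- start
      cur <- start
      len <- 1L
      while (len < walk_len) {
        nb <- adj[[cur]]
        if (length(nb) == 0L) break
        cur <- nb[sample.int(length(nb), 1L)]
        len <- len + 1L
        walk[len] <- cur
      }
      walks[[length(walks) + 1L]] <- walk[seq_len(len)]
    }
  walks
}

#' Embed graph nodes by attributed random walks over discrete roles
#'
#' Role-based walk embedding in the role2vec family: (i) each node is assigned
#' a discrete role by median-binning a random projection of its attribute
#' vector and hashing the bit signature into `n_roles` buckets; (ii) order-1
#' (memoryless) uniform random walks are started from every node; (iii) node
#' ids in the walks are replaced by role ids; (iv) a skip-gram model with
#' negative sampling is trained on the role sequences; (v) a node's embedding
#' is the vector of its role. Nodes sharing a role share an embedding, which
#' also gives a natural embedding for unseen nodes via [embed_new_nodes()].
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param attributes Numeric matrix of node attribute (union) vectors, rows
#'   aligned with `graph$node_ids`.
#' @param dim Embedding dimension (default 128).
#' @param n_roles Role vocabulary size (default 32).
#' @param n_walks,walk_len Walks per node and walk length (defaults 10, 40).
#' @param window,epochs Skip-gram context window and epochs (defaults 5, 10).
#' @param seed Integer seed; the whole procedure is reproducible.
#' @return An object of class `role2vec`: `vectors` (one row per node, named),
#'   `role_vectors` (`n_roles x dim`), per-node `roles`, and the role
#'   assignment parameters.
#' @export
embed_nodes <- function(graph, attributes, dim = 128L, n_roles = 32L,
                        n_walks = 10L, walk_len = 40L, window = 5L,
                        epochs = 10L, seed = 1L) {
  if (!inherits(graph, "similarity_graph")) stop_input("not a similarity_graph")
  X <- as.matrix(attributes)
  if (nrow(X) != length(graph$node_ids))
    stop_input("attribute rows (%d) do not match graph nodes (%d)",
               nrow(X), length(graph$node_ids))
  role_model <- fit_roles(X, n_roles = n_roles, seed = derive_seed(seed, 1L))
  walks <- with_seed(derive_seed(seed, 2L),
                     random_walks(graph$adj, n_walks, walk_len))
  role_walks <- lapply(walks, function(w) role_model$roles[w] - 1L)
  role_vec <- cpp_sgns_train(role_walks, as.integer(n_roles), as.integer(dim),
                             as.integer(window), as.integer(epochs), 5L,
                             0.025, 1e-4, derive_seed(seed, 3L))
  role_vec <- t(role_vec)  # n_roles x dim
  walked_roles <- sort(unique(unlist(lapply(role_walks, `+`, 1L))))
  obj <- structure(list(role_model = role_model,
                        role_vectors = role_vec,
                        walked_roles = walked_roles,
                        roles = role_model$roles,
                        dim = as.integer(dim)),
                   class = "role2vec")
  obj$vectors <- embed_new_nodes(obj, X, ids = graph$node_ids)
  obj
}

#' Embed nodes (including unseen ones) with a fitted role embedding
#'
#' Assigns each attribute vector its role under the fitted role model and
#' returns the role's skip-gram vector. A role that never appeared in any
#' training walk gets the zero vector, with a warning.
#'
#' @param model A `role2vec` object from [embed_nodes()].
#' @param attributes Numeric matrix of attribute vectors (rows = nodes).
#' @param ids Optional row names for the result.
#' @return Numeric matrix, one row of length `model$dim` per node.
#' @export
embed_new_nodes <- function(model, attributes, ids = NULL) {
  X <- as.matrix(attributes)
  roles <- assign_roles(model$role_model, X)
  V <- model$role_vectors[roles, , drop = FALSE]
  unseen <- !(roles %in% model$walked_roles)
  if (any(unseen)) {
    warning(sprintf("%d node(s) map to roles absent from all walks; zero embeddings used",
                    sum(unseen)), call. = FALSE)
    V[unseen, ] <- 0
  }
  rownames(V) <- ids
  V
}

#' Write node embeddings as TSV
#'
#' @param vectors Matrix of embeddings with row names as ids.
#' @param path Output path (`id` column followed by the embedding values).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(vectors, path) {
  df <- data.frame(id = rownames(vectors) %||% seq_len(nrow(vectors)),
                   as.data.frame(unname(vectors)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
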