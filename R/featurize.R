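#' Fit the feature encoders on a set of RNA records
#'
#' Fits everything that has trainable or corpus-level state for one RNA kind:
#' the PV-DM document embedder (trained on the 3-mer tokenized sequences), the
#' LNS similarity graph over the union vectors, and the role-based walk
#' embedding of that graph. Records passed here play the part of the training
#' corpus; sequences not in it can still be encoded afterwards (doc2vec by
#' inference, graph by role lookup), which is what keeps cross-validation free
#' of test-set leakage.
#'
#' @param records Record data frame of a single kind ([rna_records()]).
#' @param features Character subset of
#'   `c("kmer", "ctd", "doc2vec", "graph")`; encoders not needed for the
#'   subset are skipped (the graph always needs kmer, ctd and doc2vec for its
#'   union vectors).
#' @param d2v_dim doc2vec dimension; default 128 for lncRNA, 64 for miRNA.
#' @param d2v_epochs,d2v_window doc2vec training epochs and window (40, 5).
#' @param d2v_infer_epochs Inference epochs for encoding (default: the
#'   [infer_doc_vector()] default).
#' @param lns_k LNS reconstruction neighborhood size (default 15).
#' @param top_k Neighbors kept per row in the graph (default 15).
#' @param emb_dim Graph embedding dimension (default 128).
#' @param n_roles,n_walks,walk_len Role vocabulary and walk parameters
#'   (defaults 32, 10, 40).
#' @param r2v_epochs Skip-gram epochs for the walk embedding (default 10).
#' @param seed Integer seed for the stochastic encoders.
#' @return An object of class `feature_model`.
#' @export
fit_feature_model <- function(records,
                              features = c("kmer", "ctd", "doc2vec", "graph"),
                              d2v_dim = NULL, d2v_epochs = 40L,
                              d2v_window = 5L, d2v_infer_epochs = NULL,
                              lns_k = 15L, top_k = 15L,
                              emb_dim = 128L, n_roles = 32L, n_walks = 10L,
                              walk_len = 40L, r2v_epochs = 10L, seed = 1L) {
  features <- match.arg(features, several.ok = TRUE)
  if (nrow(records) == 0L) stop_input("no records to fit on")
  kind <- records$kind[1]
  if (!all(records$kind == kind)) stop_input("records must all be of one kind")
  d2v_dim <- d2v_dim %||% if (kind == "lncRNA") 128L else 64L

  model <- structure(
    list(kind = kind, features = features, ids = records$id,
         ks = kmer_ks(kind), d2v_dim = as.integer(d2v_dim),
         infer_epochs = d2v_infer_epochs,
         seed = as.integer(seed), cache = new.env(parent = emptyenv())),
    class = "feature_model")

  need_d2v <- any(c("doc2vec", "graph") %in% features)
  if (need_d2v) {
    corpus <- lapply(records$seq, tokenize_kmers)
    names(corpus) <- records$id
    model$embedder <- train_doc_embedder(
      corpus, dim = d2v_dim, window = d2v_window, epochs = d2v_epochs,
      seed = derive_seed(seed, 11L))
  }
  if ("graph" %in% features) {
    U <- t(vapply(seq_len(nrow(records)), function(i) {
      b <- encode_phases(records$seq[i], records$id[i], model,
                         cats = c("kmer", "ctd", "doc2vec"), phase_idx = 1L)
      c(b[[1]]$kmer, b[[1]]$ctd, b[[1]]$doc2vec)
    }, numeric(sum(4^model$ks) + 30L + d2v_dim)))
    rownames(U) <- records$id
    model$union <- U
    model$W <- lns_weights(U, k_nn = lns_k)
    model$graph <- build_graph(model$W, top_k = top_k, node_ids = records$id)
    model$r2v <- embed_nodes(model$graph, U, dim = emb_dim, n_roles = n_roles,
                             n_walks = n_walks, walk_len = walk_len,
                             epochs = r2v_epochs,
                             seed = derive_seed(seed, 12L))
  }
  model
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("feature model (%s): %d training records, features: %s\n",
              x$kind, length(x$ids), paste(x$features, collapse = ", ")))
  invisible(x)
}

# Per-phase vectors for the sequence-intrinsic categories, with a per-model
# cache so the same (id, phase) inference is never recomputed.
encode_phases <- function(seq, id, model, cats, phase_idx = 1:3) {
  phases <- phase_subsequences(seq)
  lapply(phase_idx, function(p) {
    out <- list()
    if ("kmer" %in% cats) out$kmer <- kmer_vector(phases[p], model$ks)
    if ("ctd" %in% cats) out$ctd <- ctd_vector(phases[p])
    if ("doc2vec" %in% cats) {
      key <- paste0(id, "\r", p)
      if (is.null(model$cache[[key]]))
        model$cache[[key]] <- infer_doc_vector(model$embedder, phases[p],
                                               epochs = model$infer_epochs)
      out$doc2vec <- model$cache[[key]]
    }
    out
  })
}

#' Encode one RNA record into a feature bundle
#'
#' Computes, for each of the three phase sub-sequences, the selected
#' sequence-intrinsic category vectors (k-mer, CTD, doc2vec) and, if selected,
#' the single graph embedding of the RNA. Records that were part of the fitted
#' model reuse their graph-node embedding; unseen records are embedded through
#' their role (see [embed_new_nodes()]).
#'
#' @param record One-row record data frame (or a row of one).
#' @param model A `feature_model` of the matching kind.
#' @return An object of class `feature_bundle` with elements `rna_id`,
#'   `kind`, `phases` (list of 3 lists of category vectors) and `graph`.
#' @export
encode_rna <- function(record, model) {
  if (!inherits(model, "feature_model")) stop_input("not a feature_model")
  if (record$kind != model$kind)
    stop_input("record kind '%s' does not match model kind '%s'",
               record$kind, model$kind)
  cats <- intersect(c("kmer", "ctd", "doc2vec"), model$features)
  if ("graph" %in% model$features)
    cats <- union(cats, c("kmer", "ctd", "doc2vec"))
  phases <- encode_phases(record$seq, record$id, model, cats)
  bundle <- structure(list(rna_id = record$id, kind = record$kind,
                           phases = phases, graph = NULL),
                      class = "feature_bundle")
  if ("graph" %in% model$features) {
    if (record$id %in% rownames(model$r2v$vectors)) {
      bundle$graph <- model$r2v$vectors[record$id, ]
    } else {
      u <- matrix(c(phases[[1]]$kmer, phases[[1]]$ctd, phases[[1]]$doc2vec),
                  nrow = 1)
      bundle$graph <- embed_new_nodes(model$r2v, u)[1, ]
    }
    # drop categories that were only computed to build the union vector
    keep <- intersect(c("kmer", "ctd", "doc2vec"), model$features)
    bundle$phases <- lapply(bundle$phases, function(p) p[keep])
  }
  bundle
}

#' Encode many records into feature bundles
#'
#' @param records Record data frame.
#' @param model A `feature_model` of the matching kind.
#' @return Named list of `feature_bundle` objects.
#' @export
encode_rnas <- function(records, model) {
  out <- lapply(seq_len(nrow(records)), function(i)
    encode_rna(records[i, ], model))
  names(out) <- records$id
  out
}

#' Write feature bundles to a columnar TSV
#'
#' One row per `rna_id` x phase x category with the vector serialized as a
#' comma-joined float list.
#'
#' @param bundles List of `feature_bundle` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_bundles <- function(bundles, path) {
  rows <- list()
  for (b in bundles) {
    for (p in seq_along(b$phases))
      for (cat in names(b$phases[[p]]))
        rows[[length(rows) + 1L]] <- data.frame(
          rna_id = b$rna_id, phase = p - 1L, category = cat,
          values = paste(format(b$phases[[p]][[cat]], digits = 10),
                         collapse = ","))
    if (!is.null(b$graph))
      rows[[length(rows) + 1L]] <- data.frame(
        rna_id = b$rna_id, phase = NA_integer_, category = "graph",
        values = paste(format(b$graph, digits = 10), collapse = ","))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
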