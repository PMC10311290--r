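# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately reimplement the math with plain loops so
# they share no code path with the package internals.

# plain-loop cosine distance matrix
oracle_cosdist <- function(A, B) {
  d <- matrix(NA_real_, nrow(A), nrow(B),
              dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    u <- A[i, ]; v <- B[j, ]
    d[i, j] <- 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  pmax(d, 0)
}

# all-pairs threshold -> per-gene sorted top-k -> union/intersection rule
oracle_match_graph <- function(A, B, tau, k, rule = "union") {
  d <- oracle_cosdist(A, B)
  cand <- list()
  for (i in rownames(d)) for (j in colnames(d))
    if (d[i, j] <= tau) cand[[length(cand) + 1L]] <- c(i, j, d[i, j])
  if (!length(cand)) return(data.frame(gene_a = character(),
                                       gene_b = character()))
  tab <- data.frame(gene_a = sapply(cand, `[`, 1L),
                    gene_b = sapply(cand, `[`, 2L),
                    d = as.numeric(sapply(cand, `[`, 3L)))
  picked <- function(by, partner) {
    sel <- rep(FALSE, nrow(tab))
    for (g in unique(tab[[by]])) {
      rows <- which(tab[[by]] == g)
      rows <- rows[order(tab$d[rows], tab[[partner]][rows])]
      sel[rows[seq_len(min(k, length(rows)))]] <- TRUE
    }
    sel
  }
  in_a <- picked("gene_a", "gene_b")
  in_b <- picked("gene_b", "gene_a")
  keep <- if (rule == "union") in_a | in_b else in_a & in_b
  out <- tab[keep, c("gene_a", "gene_b")]
  out[order(out$gene_a, out$gene_b), ]
}

# exhaustive alignment-loss oracle (one direction): per cell, sort all
# opposite distances, take the k nearest, weight them, MSE of the feature
# prediction
oracle_align_dir <- function(emb_s, emb_o, feat_s, feat_o, k, mode) {
  per_cell <- numeric(nrow(emb_s))
  for (i in seq_len(nrow(emb_s))) {
    d2 <- apply(emb_o, 1L, function(r) sum((emb_s[i, ] - r)^2))
    nb <- order(d2, seq_along(d2))[seq_len(k)]
    w <- if (mode == "hard") rep(1 / k, k) else {
      e <- exp(-d2[nb] - max(-d2[nb]))
      e / sum(e)
    }
    pred <- colSums(feat_o[nb, , drop = FALSE] * w)
    per_cell[i] <- mean((pred - feat_s[i, ])^2)
  }
  mean(per_cell)
}

# exhaustive reciprocal-best-hit scan on an admitted pair table
oracle_rbh <- function(pairs) {
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[r]; b <- pairs$gene_b[r]
    sa <- pairs[pairs$gene_a == a, ]
    sb <- pairs[pairs$gene_b == b, ]
    keep[r] <- sa$gene_b[which.max(sa$score)] == b &&
      sb$gene_a[which.max(sb$score)] == a
  }
  out <- pairs[keep, c("gene_a", "gene_b")]
  out[order(out$gene_a, out$gene_b), ]
}

rand_emb <- function(n, d, species, seed, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)), NULL))
  protein_embedding_set(species, m)
}

# unit-circle embeddings: a gene at angle theta has distance 1 - cos(dtheta)
# to a gene at angle theta + dtheta, monotone in |dtheta|
circle_emb <- function(angles, species) {
  m <- cbind(cos(angles), sin(angles))
  rownames(m) <- names(angles)
  protein_embedding_set(species, m)
}

# crowded-neighbourhood fixture: gene "u" has 8 candidate partners within
# tau = 0.005, but every partner has five strictly closer decoy genes, so
# u's retained edges are exactly its own top-k selection
crowded_fixture <- function() {
  th_b <- 0.01 * (1:8)
  names(th_b) <- sprintf("b%d", 1:8)
  th_decoy <- rep(th_b, each = 5)
  names(th_decoy) <- sprintf("d%02d", seq_along(th_decoy))
  th_a <- c(u = 0, th_decoy)
  list(a = circle_emb(th_a, "A"), b = circle_emb(th_b, "B"))
}

quick_fit <- function(sim, epochs = 40, batch = 150, seed = 1,
                      k_align = 10, ...) {
  shared <- prepare_shared_features(sim$dataset_a, sim$dataset_b, sim$graph)
  fit <- cellmatch(shared$a, shared$b, sim$dataset_a$cell_types,
                   sim$dataset_b$cell_types,
                   config = match_config(epochs = epochs,
                                         batch_per_species = batch,
                                         k_align = k_align,
                                         seed = seed, ...))
  list(fit = fit, shared = shared)
}
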