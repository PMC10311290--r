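#' @title Weighted bipartite gene-match graphs
#' @description Internal constructor for the graph of cross-species gene
#'   matches. Edges carry a distance (cosine, embedding mode), a weight used by
#'   the imputation step, and a provenance tag.
#' @keywords internal
new_match_graph <- function(edges, species_a, species_b, params) {
  rownames(edges) <- NULL
  structure(list(
    edges = edges,
    genes_a = sort(unique(edges$gene_a)),
    genes_b = sort(unique(edges$gene_b)),
    species = c(a = unname(species_a), b = unname(species_b)),
    params = params
  ), class = "gene_match_graph")
}

#' @export
print.gene_match_graph <- function(x, ...) {
  cat(sprintf("Gene match graph: %s vs %s\n", x$species["a"], x$species["b"]))
  cat(sprintf("  %d edges, %d %s genes, %d %s genes (source: %s)\n",
              nrow(x$edges), length(x$genes_a), x$species["a"],
              length(x$genes_b), x$species["b"],
              paste(unique(x$edges$source), collapse = ",")))
  invisible(x)
}

#' Linear edge weight from an embedding distance
#'
#' Maps a cosine distance `d` to a weight `1 - d / tau`, so that identical
#' proteins get weight 1 and pairs at the admission threshold get weight 0.
#' Distances beyond `tau` (non-matching pairs) get weight 0.
#'
#' @param distance nonnegative numeric vector of cosine distances.
#' @param tau distance threshold (> 0); default 0.005.
#' @return numeric vector of weights in `[0, 1]`.
#' @export
edge_weight <- function(distance, tau = 0.005) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number")
  if (any(distance < 0)) stop("'distance' must be nonnegative")
  w <- 1 - distance / tau
  w[distance > tau] <- 0
  pmin(pmax(w, 0), 1)
}

# Per-gene directed top-k selection on a candidate edge table.
# Returns a logical vector: is edge within the k closest candidates of `gene`?
# Ordering: ascending rank_key, ties broken by partner id (lexicographic).
.topk_keep <- function(gene, partner, rank_key, k) {
  keep <- logical(length(gene))
  for (idx in split(seq_along(gene), gene)) {
    o <- idx[order(rank_key[idx], partner[idx])]
    keep[o[seq_len(min(k, length(o)))]] <- TRUE
  }
  keep
}

#' Build the cross-species gene-match graph from protein embeddings
#'
#' Candidate edges are all gene pairs with cosine distance at most `tau`
#' (default 0.005). Each gene then keeps only its `k_max` closest candidate
#' partners (default 5); an edge is retained if it survives the cut of at
#' least one endpoint (`topk_rule = "union"`, the default) or of both
#' (`"intersection"`). Ties at the k-th position are broken by the partner's
#' gene id so results are reproducible across platforms.
#'
#' When a species' embeddings are per-isoform rather than per-gene, pass
#' `gene_map_a` / `gene_map_b` (named vectors mapping embedding row id to gene
#' id); the gene-gene distance is then aggregated over all isoform pairs with
#' `isoform_agg` (`"min"`: one similar isoform suffices, the default).
#'
#' Highly-variable-gene filtering is a separate step: see [hvg_filter()].
#'
#' @param a,b [protein_embedding_set()] objects for the two species.
#' @param tau cosine-distance admission threshold.
#' @param k_max per-gene cap on retained candidate partners.
#' @param topk_rule `"union"` or `"intersection"` of the two directed top-k
#'   selections.
#' @param gene_map_a,gene_map_b optional named character vectors mapping
#'   embedding row ids to gene ids (for isoform-level embeddings).
#' @param isoform_agg `"min"` or `"mean"` aggregation of isoform-pair
#'   distances.
#' @return a `gene_match_graph`; edges have columns `gene_a`, `gene_b`,
#'   `distance`, `weight`, `source`.
#' @export
build_match_graph <- function(a, b, tau = 0.005, k_max = 5L,
                              topk_rule = c("union", "intersection"),
                              gene_map_a = NULL, gene_map_b = NULL,
                              isoform_agg = c("min", "mean")) {
  stopifnot(inherits(a, "protein_embedding_set"),
            inherits(b, "protein_embedding_set"))
  if (nrow(a$vectors) == 0L || nrow(b$vectors) == 0L)
    stop("empty embedding set")
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be positive")
  if (k_max < 1L) stop("'k_max' must be >= 1")
  topk_rule <- match.arg(topk_rule)
  isoform_agg <- match.arg(isoform_agg)

  D <- cosine_distance_matrix(a$vectors, b$vectors)
  rownames(D) <- rownames(a$vectors); colnames(D) <- rownames(b$vectors)
  D <- .aggregate_isoforms(D, gene_map_a, gene_map_b, isoform_agg)

  cand <- which(D <= tau, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        distance = numeric(), weight = numeric(),
                        source = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = rownames(D)[cand[, 1L]],
                        gene_b = colnames(D)[cand[, 2L]],
                        distance = D[cand], stringsAsFactors = FALSE)
    in_a <- .topk_keep(edges$gene_a, edges$gene_b, edges$distance, k_max)
    in_b <- .topk_keep(edges$gene_b, edges$gene_a, edges$distance, k_max)
    keep <- if (topk_rule == "union") in_a | in_b else in_a & in_b
    edges <- edges[keep, , drop = FALSE]
    edges$weight <- edge_weight(edges$distance, tau)
    edges$source <- "embedding"
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  }
  new_match_graph(edges, a$species, b$species,
                  params = list(tau = tau, k_max = as.integer(k_max),
                                topk_rule = topk_rule,
                                isoform_agg = isoform_agg))
}

# Aggregate an isoform-level distance matrix to gene level.
.aggregate_isoforms <- function(D, map_a, map_b, agg) {
  fun <- if (agg == "min") min else mean
  collapse <- function(M, map, margin) {
    if (is.null(map)) return(M)
    ids <- if (margin == 1L) rownames(M) else colnames(M)
    if (!all(ids %in% names(map)))
      stop("gene map does not cover all embedding row ids")
    grp <- map[ids]
    genes <- sort(unique(grp))
    out <- if (margin == 1L)
      t(vapply(genes, function(g) apply(M[grp == g, , drop = FALSE], 2L, fun),
               numeric(ncol(M))))
    else
      vapply(genes, function(g) apply(M[, grp == g, drop = FALSE], 1L, fun),
             numeric(nrow(M)))
    if (margin == 1L) { rownames(out) <- genes; colnames(out) <- colnames(M) }
    else { colnames(out) <- genes; rownames(out) <- rownames(M) }
    out
  }
  D <- collapse(D, map_a, 1L)
  collapse(D, map_b, 2L)
}

#' Keep only gene matches touching a highly variable gene
#'
#' An edge survives if its species-A endpoint is in `hvg_a` **or** its
#' species-B endpoint is in `hvg_b`. The per-species matched gene sets are
#' recomputed from the surviving edges.
#'
#' @param g a `gene_match_graph`.
#' @param hvg_a,hvg_b character vectors of highly variable gene ids per
#'   species.
#' @return the filtered `gene_match_graph`.
#' @export
hvg_filter <- function(g, hvg_a, hvg_b) {
  stopifnot(inherits(g, "gene_match_graph"))
  keep <- g$edges$gene_a %in% hvg_a | g$edges$gene_b %in% hvg_b
  params <- g$params
  params$hvg_filtered <- TRUE
  new_match_graph(g$edges[keep, , drop = FALSE],
                  g$species["a"], g$species["b"], params)
}

#' Gene matches from directional BLAST hit tables
#'
#' Builds a `gene_match_graph` from protein BLAST results run in both
#' directions. A gene pair enters the candidate set if at least one direction
#' has E-value below `evalue_max` (default 1e-6); its score is that
#' direction's bitscore, or the mean of the two bitscores when both directions
#' qualify. Multiple HSPs for one pair within a direction are reduced to the
#' highest bitscore.
#'
#' In `"many_to_many"` mode each gene keeps only its `k_max` highest-scoring
#' partners (higher bitscore = closer), with the same union/intersection rule
#' as [build_match_graph()]; in `"one_to_one"` mode each gene keeps its single
#' best partner and only reciprocal best pairs survive. If `hvg_a`/`hvg_b` are
#' given the highly-variable filter of [hvg_filter()] is applied afterwards.
#'
#' Edge `weight` is the raw (average) bitscore — the downstream imputation
#' normalises weights within each gene's match group, so no global rescaling
#' is applied; `distance` is `NA` for BLAST edges.
#'
#' @param hits_ab data frame of hits with species-A queries (columns `query`,
#'   `subject`, `evalue`, `bitscore`; see [read_blast_table()]).
#' @param hits_ba same, with species-B queries.
#' @param evalue_max E-value admission threshold.
#' @param mode `"many_to_many"` or `"one_to_one"`.
#' @param k_max per-gene partner cap (many-to-many mode only).
#' @param topk_rule see [build_match_graph()].
#' @param hvg_a,hvg_b optional highly variable gene sets; when given, the
#'   HVG filter is applied.
#' @param genes_a,genes_b optional universes of valid gene ids; hits
#'   referencing other genes are dropped with a message.
#' @param species_a,species_b species labels for the resulting graph.
#' @return a `gene_match_graph` with `source` `"blast_mm"` or `"blast_11"`.
#' @export
blast_to_matches <- function(hits_ab, hits_ba, evalue_max = 1e-6,
                             mode = c("many_to_many", "one_to_one"),
                             k_max = 5L, topk_rule = c("union", "intersection"),
                             hvg_a = NULL, hvg_b = NULL,
                             genes_a = NULL, genes_b = NULL,
                             species_a = "A", species_b = "B") {
  mode <- match.arg(mode)
  topk_rule <- match.arg(topk_rule)
  check_hits <- function(h, nm) {
    need <- c("query", "subject", "evalue", "bitscore")
    if (!all(need %in% names(h)))
      stop(sprintf("'%s' must have columns %s", nm, paste(need, collapse = ", ")))
    if (any(h$evalue < 0)) stop("negative E-value")
    if (any(h$bitscore <= 0)) stop("non-positive bitscore")
    h
  }
  hits_ab <- check_hits(as.data.frame(hits_ab), "hits_ab")
  hits_ba <- check_hits(as.data.frame(hits_ba), "hits_ba")
  drop_unknown <- function(h, qset, sset, nm) {
    ok <- rep(TRUE, nrow(h))
    if (!is.null(qset)) ok <- ok & h$query %in% qset
    if (!is.null(sset)) ok <- ok & h$subject %in% sset
    if (any(!ok))
      message(sprintf("dropping %d %s hits referencing unknown genes",
                      sum(!ok), nm))
    h[ok, , drop = FALSE]
  }
  hits_ab <- drop_unknown(hits_ab, genes_a, genes_b, "A->B")
  hits_ba <- drop_unknown(hits_ba, genes_b, genes_a, "B->A")

  # best HSP per directed pair
  best_dir <- function(h) {
    if (nrow(h) == 0L)
      return(data.frame(key = character(), evalue = numeric(),
                        bitscore = numeric(), stringsAsFactors = FALSE))
    key <- paste(h$query, h$subject, sep = "\r")
    o <- order(key, -h$bitscore, h$evalue)
    h <- h[o, , drop = FALSE]; key <- key[o]
    first <- !duplicated(key)
    data.frame(key = key[first], evalue = h$evalue[first],
               bitscore = h$bitscore[first], stringsAsFactors = FALSE)
  }
  ab <- best_dir(hits_ab)
  ba <- best_dir(hits_ba)
  # reorient B->A keys to (gene_a, gene_b)
  if (nrow(ba) > 0L) {
    parts <- strsplit(ba$key, "\r", fixed = TRUE)
    ba$key <- vapply(parts, function(p) paste(p[2L], p[1L], sep = "\r"), "")
  }
  keys <- union(ab$key, ba$key)
  e_ab <- ab$evalue[match(keys, ab$key)]; s_ab <- ab$bitscore[match(keys, ab$key)]
  e_ba <- ba$evalue[match(keys, ba$key)]; s_ba <- ba$bitscore[match(keys, ba$key)]
  q_ab <- !is.na(e_ab) & e_ab < evalue_max
  q_ba <- !is.na(e_ba) & e_ba < evalue_max
  admit <- q_ab | q_ba
  score <- ifelse(q_ab & q_ba, (s_ab + s_ba) / 2,
                  ifelse(q_ab, s_ab, s_ba))
  keys <- keys[admit]; score <- score[admit]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    distance = rep(NA_real_, length(keys)),
    weight = score,
    stringsAsFactors = FALSE)

  if (nrow(edges) > 0L) {
    if (mode == "many_to_many") {
      in_a <- .topk_keep(edges$gene_a, edges$gene_b, -edges$weight, k_max)
      in_b <- .topk_keep(edges$gene_b, edges$gene_a, -edges$weight, k_max)
      keep <- if (topk_rule == "union") in_a | in_b else in_a & in_b
      edges <- edges[keep, , drop = FALSE]
    } else {
      best_a <- .topk_keep(edges$gene_a, edges$gene_b, -edges$weight, 1L)
      best_b <- .topk_keep(edges$gene_b, edges$gene_a, -edges$weight, 1L)
      edges <- edges[best_a & best_b, , drop = FALSE]  # reciprocal best hits
    }
  }
  edges$source <- rep(if (mode == "many_to_many") "blast_mm" else "blast_11",
                      nrow(edges))
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  g <- new_match_graph(edges, species_a, species_b,
                       params = list(evalue_max = evalue_max, mode = mode,
                                     k_max = as.integer(k_max),
                                     topk_rule = topk_rule))
  if (!is.null(hvg_a) || !is.null(hvg_b))
    g <- hvg_filter(g, hvg_a %||% character(), hvg_b %||% character())
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Rank one-to-one BLAST partners by embedding distance
#'
#' For every pair in a one-to-one BLAST match graph, reports where the BLAST
#' partner ranks (1-based) among all species-B genes ordered by cosine
#' distance to the species-A gene's embedding. Genes missing from either
#' embedding set get an `NA` rank.
#'
#' @param blast_11 a one-to-one `gene_match_graph` (see [blast_to_matches()]).
#' @param emb_a,emb_b [protein_embedding_set()] objects.
#' @return data frame with columns `gene_a`, `blast_match`,
#'   `embed_rank_of_blast_match`.
#' @export
compare_match_ranks <- function(blast_11, emb_a, emb_b) {
  stopifnot(inherits(blast_11, "gene_match_graph"))
  e <- blast_11$edges
  rank_of <- function(ga, gb) {
    if (!(ga %in% rownames(emb_a$vectors)) || !(gb %in% rownames(emb_b$vectors)))
      return(NA_real_)
    d <- cosine_distance_matrix(emb_a$vectors[ga, , drop = FALSE],
                                emb_b$vectors)[1L, ]
    o <- order(d, names(d))
    as.numeric(which(names(d)[o] == gb))
  }
  data.frame(
    gene_a = e$gene_a,
    blast_match = e$gene_b,
    embed_rank_of_blast_match =
      mapply(rank_of, e$gene_a, e$gene_b, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Pearson correlation of matched genes over harmonized cell-type profiles
#'
#' For each matched gene pair, computes the Pearson correlation between the
#' two species' per-cell-type mean expression vectors, taken over the
#' harmonized cell types present in both species. A constant profile makes the
#' correlation undefined; such pairs get `NA`.
#'
#' @param x_a,x_b expression matrices (cells x genes) on comparable scales,
#'   e.g. log-normalized.
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @param types_a,types_b per-cell harmonized type labels (shared vocabulary).
#' @return data frame with columns `gene_a`, `gene_b`, `pearson_r`.
#' @export
expression_correlation_report <- function(x_a, x_b, pairs, types_a, types_b) {
  stopifnot(nrow(x_a) == length(types_a), nrow(x_b) == length(types_b))
  shared <- sort(intersect(unique(as.character(types_a)),
                           unique(as.character(types_b))))
  if (length(shared) < 2L) stop("need >= 2 shared harmonized cell types")
  type_means <- function(x, types) {
    m <- vapply(shared, function(tt) colMeans(x[types == tt, , drop = FALSE]),
                numeric(ncol(x)))
    t(matrix(m, nrow = ncol(x), dimnames = list(colnames(x), shared)))
  }
  ma <- type_means(x_a, as.character(types_a))  # types x genes
  mb <- type_means(x_b, as.character(types_b))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    pa <- ma[, pairs$gene_a[i]]; pb <- mb[, pairs$gene_b[i]]
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(NA_real_)
    stats::cor(pa, pb)
  }, numeric(1L))
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, pearson_r = r,
             stringsAsFactors = FALSE)
}
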