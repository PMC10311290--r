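#' Configuration for the paired-species simulator
#'
#' Generates two species' datasets with known ground truth: homologous genes
#' share a latent embedding vector (plus independent Gaussian noise) and
#' matched cell types share mean expression profiles (up to a per-species
#' log-normal divergence). Counts are negative-binomial around log-normal
#' gene means with per-type marker elevation; matched types are
#' well-separated by construction. Defaults give 5 matched types with a
#' mild per-species proportion imbalance (50 vs 40 cells per type), 150
#' one-to-one homologous gene pairs plus 25 species-specific genes each,
#' 32-dimensional embeddings with noise sd 0.01, and no gene duplications.
#'
#' @param n_types number of matched cell types.
#' @param cells_per_type_a,cells_per_type_b cells per matched type in each
#'   species (unequal values emulate cross-species proportion imbalance).
#' @param n_types_specific_a,n_types_specific_b species-specific types with
#'   no counterpart.
#' @param n_genes_shared number of homologous ancestral genes.
#' @param n_genes_specific_a,n_genes_specific_b species-specific genes.
#' @param embedding_dim embedding dimension D.
#' @param embedding_noise_sd sd of the per-species perturbation around the
#'   shared latent embedding.
#' @param frac_one_to_two fraction of shared genes duplicated in species B
#'   (one A gene matched to two B genes).
#' @param mean_logmean,mean_logsd log-normal prior on per-gene base means.
#' @param marker_fold mean fold-elevation of a type's marker genes.
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param type_divergence sd of the per-species log-normal perturbation of
#'   type/gene means.
#' @param dropout probability of zeroing any count.
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_types = 5L, cells_per_type_a = 50L,
                       cells_per_type_b = 40L,
                       n_types_specific_a = 0L, n_types_specific_b = 0L,
                       n_genes_shared = 150L, n_genes_specific_a = 25L,
                       n_genes_specific_b = 25L, embedding_dim = 32L,
                       embedding_noise_sd = 0.01, frac_one_to_two = 0,
                       mean_logmean = 0.5, mean_logsd = 0.5, marker_fold = 6,
                       dispersion = 0.5, type_divergence = 0.1,
                       dropout = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(n_types >= 2, cells_per_type_a > 0, cells_per_type_b > 0,
                      n_genes_shared >= n_types, embedding_dim >= 2,
                      embedding_noise_sd >= 0, frac_one_to_two >= 0,
                      frac_one_to_two <= 1, marker_fold > 0, dispersion > 0,
                      type_divergence >= 0, dropout >= 0, dropout < 1))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a paired-species dataset bundle with known ground truth
#'
#' Returns everything the matching pipeline consumes plus the ground truth it
#' should recover: expression datasets and protein embedding sets for both
#' species, the true gene-match graph, the true type correspondence, and a
#' synthetic BLAST hit table pair whose bitscores decrease with embedding
#' distance (true homolog hits get qualifying E-values, distractor hits do
#' not).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset_a`, `dataset_b` ([expression_dataset()]),
#'   `embeddings_a`, `embeddings_b` ([protein_embedding_set()]), `graph`
#'   (true `gene_match_graph`), `correspondence` ([type_correspondence()]),
#'   `blast_ab`, `blast_ba` (hit data frames) and `config`.
#' @export
simulate_species_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_genes_shared
  genes_a <- sprintf("gA%04d", seq_len(S))
  genes_b <- sprintf("gB%04d", seq_len(S))
  n_dup <- round(cfg$frac_one_to_two * S)
  dup_of <- if (n_dup > 0) sort(sample.int(S, n_dup)) else integer()
  genes_b_dup <- sprintf("gB%04dd", dup_of)
  spec_a <- if (cfg$n_genes_specific_a > 0)
    sprintf("sA%04d", seq_len(cfg$n_genes_specific_a)) else character()
  spec_b <- if (cfg$n_genes_specific_b > 0)
    sprintf("sB%04d", seq_len(cfg$n_genes_specific_b)) else character()

  D <- cfg$embedding_dim
  latent <- matrix(stats::rnorm(S * D), S, D)
  perturb <- function(Z) Z + matrix(stats::rnorm(length(Z), 0,
                                                 cfg$embedding_noise_sd),
                                    nrow(Z), ncol(Z))
  emb_a <- rbind(perturb(latent),
                 matrix(stats::rnorm(length(spec_a) * D), ncol = D))
  rownames(emb_a) <- c(genes_a, spec_a)
  emb_b <- rbind(perturb(latent), perturb(latent[dup_of, , drop = FALSE]),
                 matrix(stats::rnorm(length(spec_b) * D), ncol = D))
  rownames(emb_b) <- c(genes_b, genes_b_dup, spec_b)

  # true homology edges, with realised embedding distances
  pair_a <- c(genes_a, genes_a[dup_of])
  pair_b <- c(genes_b, genes_b_dup)
  d <- vapply(seq_along(pair_a), function(i)
    cosine_distance(emb_a[pair_a[i], ], emb_b[pair_b[i], ]), numeric(1L))
  truth <- data.frame(gene_a = pair_a, gene_b = pair_b, distance = d,
                      weight = edge_weight(d), source = "embedding",
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene_a, truth$gene_b), , drop = FALSE]
  graph <- new_match_graph(truth, "speciesA", "speciesB",
                           params = list(tau = 0.005, truth = TRUE))

  # expression model: log-normal base means, disjoint marker blocks per
  # matched type over the shared genes, per-species divergence
  types <- sprintf("T%d", seq_len(cfg$n_types))
  types_sa <- if (cfg$n_types_specific_a > 0)
    sprintf("Aonly%d", seq_len(cfg$n_types_specific_a)) else character()
  types_sb <- if (cfg$n_types_specific_b > 0)
    sprintf("Bonly%d", seq_len(cfg$n_types_specific_b)) else character()
  base <- stats::rlnorm(S, cfg$mean_logmean, cfg$mean_logsd)
  marker_block <- split(seq_len(S),
                        rep(seq_len(cfg$n_types), length.out = S))
  mu_shared <- matrix(base, cfg$n_types, S, byrow = TRUE,
                      dimnames = list(types, NULL))
  for (t in seq_len(cfg$n_types))
    mu_shared[t, marker_block[[t]]] <- mu_shared[t, marker_block[[t]]] *
      cfg$marker_fold

  make_species <- function(species, gene_names, shared_idx, spec_genes,
                           cells_per_type, own_types) {
    all_types <- c(types, own_types)
    n_genes <- length(gene_names) + length(spec_genes)
    mu <- matrix(stats::rlnorm(length(all_types) * n_genes, cfg$mean_logmean,
                               cfg$mean_logsd),
                 length(all_types), n_genes,
                 dimnames = list(all_types, c(gene_names, spec_genes)))
    # shared genes inherit the ancestral type profile (duplicates inherit
    # their parent's), distorted by the per-species divergence
    mu[types, seq_along(gene_names)] <-
      mu_shared[, shared_idx, drop = FALSE] *
      matrix(stats::rlnorm(cfg$n_types * length(gene_names), 0,
                           cfg$type_divergence),
             cfg$n_types, length(gene_names))
    # species-specific types mark their own gene block
    for (j in seq_along(own_types)) {
      blk <- spec_genes[seq_along(spec_genes) %% length(own_types) == (j - 1L)]
      mu[own_types[j], blk] <- mu[own_types[j], blk] * cfg$marker_fold
    }
    labels <- rep(all_types, each = cells_per_type)
    n_cells <- length(labels)
    counts <- matrix(stats::rnbinom(n_cells * n_genes,
                                    mu = mu[labels, , drop = FALSE],
                                    size = 1 / cfg$dispersion),
                     n_cells, n_genes)
    if (cfg$dropout > 0)
      counts[matrix(stats::runif(length(counts)) < cfg$dropout,
                    n_cells, n_genes)] <- 0L
    empty <- rowSums(counts) == 0
    if (any(empty))  # keep every cell observable
      counts[cbind(which(empty), sample.int(n_genes, sum(empty), TRUE))] <- 1L
    dimnames(counts) <- list(sprintf("%s_c%04d", species, seq_len(n_cells)),
                             c(gene_names, spec_genes))
    expression_dataset(counts, labels, species)
  }

  ds_a <- make_species("speciesA", genes_a, seq_len(S), spec_a,
                       cfg$cells_per_type_a, types_sa)
  ds_b <- make_species("speciesB", c(genes_b, genes_b_dup),
                       c(seq_len(S), dup_of), spec_b,
                       cfg$cells_per_type_b, types_sb)

  corr <- type_correspondence(data.frame(type_a = types, type_b = types),
                              specific_a = types_sa, specific_b = types_sb)

  # synthetic BLAST: true homologs hit well below the E-value threshold with
  # bitscores decreasing in embedding distance; each gene also gets a weaker
  # qualifying secondary hit and a non-qualifying distractor
  bit <- function(dist) round(500 * exp(-5 * dist), 1)
  mk_hits <- function(q, s, evalue, bitscore)
    data.frame(query = q, subject = s, evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
  nxt <- c(seq_len(S)[-1L], 1L)
  blast_ab <- rbind(
    mk_hits(pair_a, pair_b, 1e-30, bit(truth$distance[match(paste(pair_a, pair_b),
                                       paste(truth$gene_a, truth$gene_b))])),
    mk_hits(genes_a, genes_b[nxt], 1e-8, bit(1)),
    mk_hits(genes_a, genes_b[nxt], 5e-3, 30))
  blast_ba <- rbind(
    mk_hits(pair_b, pair_a, 1e-30, bit(truth$distance[match(paste(pair_a, pair_b),
                                       paste(truth$gene_a, truth$gene_b))]) + 2),
    mk_hits(genes_b, genes_a[nxt], 1e-8, bit(1)),
    mk_hits(genes_b, genes_a[nxt], 5e-3, 30))

  list(dataset_a = ds_a, dataset_b = ds_b,
       embeddings_a = protein_embedding_set("speciesA", emb_a),
       embeddings_b = protein_embedding_set("speciesB", emb_b),
       graph = graph, correspondence = corr,
       blast_ab = blast_ab, blast_ba = blast_ba, config = cfg)
}

#' Simulate per-residue embedding matrices
#'
#' One L x D matrix per gene, rows drawn around a per-gene base vector so the
#' pooled (column-mean) embedding concentrates on that base. Lengths are
#' caller-controlled and may exceed the 2500-residue truncation limit to
#' exercise pooling.
#'
#' @param lengths named integer vector: residue count per gene id.
#' @param dim embedding dimension.
#' @param residue_sd sd of per-residue noise around the gene's base vector.
#' @param seed integer seed.
#' @return named list of matrices; attribute `base` holds the per-gene base
#'   vectors (genes x dim).
#' @export
simulate_residue_embeddings <- function(lengths, dim = 16L, residue_sd = 0.1,
                                        seed = 1L) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L))
  if (is.null(names(lengths)))
    names(lengths) <- sprintf("g%03d", seq_along(lengths))
  set.seed(seed)
  base <- matrix(stats::rnorm(length(lengths) * dim), length(lengths), dim,
                 dimnames = list(names(lengths), NULL))
  out <- lapply(seq_along(lengths), function(i)
    matrix(base[i, ], lengths[i], dim, byrow = TRUE) +
      matrix(stats::rnorm(lengths[i] * dim, 0, residue_sd), lengths[i], dim))
  names(out) <- names(lengths)
  attr(out, "base") <- base
  out
}

#' Normalize, z-score and impute the shared feature space for a dataset pair
#'
#' Convenience wrapper: log-normalizes both species' counts, restricts to the
#' graph's matched gene sets, z-scores per gene, and imputes the shared
#' feature space over the match graph.
#'
#' @param ds_a,ds_b [expression_dataset()] objects.
#' @param graph a `gene_match_graph`.
#' @param scale library-size scale for [lognormalize()].
#' @return list with `shared_features` elements `a` and `b`.
#' @export
prepare_shared_features <- function(ds_a, ds_b, graph, scale = 1e4) {
  na <- zscore(lognormalize(ds_a, scale)[, graph$genes_a, drop = FALSE])
  nb <- zscore(lognormalize(ds_b, scale)[, graph$genes_b, drop = FALSE])
  impute_shared(na, nb, graph)
}

#' Run the full matching pipeline on raw inputs
#'
#' Builds the gene-match graph from protein embeddings, applies the
#' highly-variable-gene filter, constructs the shared feature space, trains
#' the matching model, and scores the cell-type match.
#'
#' @param ds_a,ds_b [expression_dataset()] objects.
#' @param emb_a,emb_b [protein_embedding_set()] objects.
#' @param corr optional [type_correspondence()] for scoring.
#' @param tau,k_max,topk_rule gene-matching parameters
#'   (see [build_match_graph()]).
#' @param n_hvg highly variable genes per species (see [select_hvg()]).
#' @param norm_scale library-size scale.
#' @param config a [match_config()].
#' @return list with `result` (a `match_result`), `model`, `graph` and
#'   `shared`.
#' @export
match_pipeline <- function(ds_a, ds_b, emb_a, emb_b, corr = NULL,
                           tau = 0.005, k_max = 5L, topk_rule = "union",
                           n_hvg = 2000L, norm_scale = 1e4,
                           config = match_config()) {
  # genes without an embedding cannot be matched; genes without expression
  # cannot feed the model
  keep_a <- intersect(rownames(emb_a$vectors), ds_a$gene_ids)
  keep_b <- intersect(rownames(emb_b$vectors), ds_b$gene_ids)
  if (length(keep_a) == 0L || length(keep_b) == 0L)
    stop("no overlap between embedding and expression gene ids")
  dropped <- (nrow(emb_a$vectors) - length(keep_a)) +
    (nrow(emb_b$vectors) - length(keep_b))
  if (dropped > 0)
    message(sprintf("%d embedding gene(s) absent from expression data dropped",
                    dropped))
  emb_a <- protein_embedding_set(emb_a$species,
                                 emb_a$vectors[keep_a, , drop = FALSE])
  emb_b <- protein_embedding_set(emb_b$species,
                                 emb_b$vectors[keep_b, , drop = FALSE])
  graph <- build_match_graph(emb_a, emb_b, tau = tau, k_max = k_max,
                             topk_rule = topk_rule)
  if (nrow(graph$edges) == 0L) stop("no gene matches below the threshold")
  hvg_a <- suppressWarnings(select_hvg(ds_a, n_hvg, scale = norm_scale))
  hvg_b <- suppressWarnings(select_hvg(ds_b, n_hvg, scale = norm_scale))
  graph <- hvg_filter(graph, hvg_a, hvg_b)
  if (nrow(graph$edges) == 0L) stop("no gene matches survive the HVG filter")
  shared <- prepare_shared_features(ds_a, ds_b, graph, scale = norm_scale)
  model <- cellmatch(shared$a, shared$b, ds_a$cell_types, ds_b$cell_types,
                     config = config)
  result <- match_types(model, shared$a, shared$b,
                        ds_a$cell_types, ds_b$cell_types, corr)
  list(result = result, model = model, graph = graph, shared = shared)
}
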