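#' Construct a single-species expression dataset
#'
#' Raw integer counts (cells x genes) with per-cell type labels. Counts may be
#' a base matrix or a `Matrix` sparse matrix; they are stored dense.
#'
#' @param counts cells x genes matrix of nonnegative integers; rownames are
#'   cell ids, colnames gene ids.
#' @param cell_types per-cell labels (character or factor), one per row.
#' @param species single species label.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, cell_types, species) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) stop("counts must have gene ids as colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(cell_types) != nrow(counts))
    stop("one cell type label per cell required")
  stopifnot(is.character(species), length(species) == 1L)
  structure(list(species = species, counts = counts,
                 cell_types = as.character(cell_types),
                 gene_ids = colnames(counts), cell_ids = rownames(counts)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %s, %d cells x %d genes, %d cell types\n",
              x$species, nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_types))))
  invisible(x)
}

#' Library-size normalize and log-transform raw counts
#'
#' Each cell's counts are scaled so its total equals `scale` (default 10 000),
#' then `ln(x + 1)` is applied: `x'_ij = ln(x_ij / sum_k x_ik * scale + 1)`.
#'
#' @param x an [expression_dataset()] or a cells x genes count matrix.
#' @param scale per-cell target total after normalization.
#' @return dense numeric matrix of the same shape.
#' @export
lognormalize <- function(x, scale = 1e4) {
  m <- if (inherits(x, "expression_dataset")) x$counts else as.matrix(x)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    bad <- rownames(m)[totals == 0]
    stop(sprintf("cell(s) with zero total count: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  log(m / totals * scale + 1)
}

#' Z-score a matrix per gene (column)
#'
#' Centers and scales every column to mean 0 and (population, `ddof = 0`)
#' standard deviation 1. Zero-variance columns become all-zeros rather than
#' `NaN`, so uninformative genes contribute a flat baseline downstream.
#'
#' @param m numeric matrix, cells x genes.
#' @param ddof degrees-of-freedom correction for the standard deviation
#'   (0 = population, the default; 1 = sample).
#' @return matrix of the same shape.
#' @export
zscore <- function(m, ddof = 0) {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- colMeans(m)
  cen <- sweep(m, 2L, mu)
  sd0 <- sqrt(colSums(cen^2) / max(n - ddof, 1L))
  keep <- sd0 > 0
  cen[, keep] <- sweep(cen[, keep, drop = FALSE], 2L, sd0[keep], "/")
  cen[, !keep] <- 0
  cen
}

#' Select highly variable genes by binned dispersion
#'
#' Ranks genes by normalized dispersion computed on the log-normalized matrix,
#' in the classic dispersion flavour: the log-normalized values are
#' exponentiated back (`expm1`), per-gene mean and dispersion (variance/mean)
#' are computed, log-dispersion is z-normalized within 20 equal-width bins of
#' log mean, and the top `n_hvg` genes by normalized dispersion are returned.
#' Ties are broken by gene id for determinism.
#'
#' @param x an [expression_dataset()] or raw count matrix with gene colnames.
#' @param n_hvg number of genes to select (default 2000). If fewer genes
#'   qualify (nonzero expression), all qualifying genes are returned with a
#'   warning.
#' @param scale library-size scale passed to [lognormalize()].
#' @param n_bins number of mean bins for dispersion normalization.
#' @return character vector of gene ids, length `min(n_hvg, available)`.
#' @export
select_hvg <- function(x, n_hvg = 2000L, scale = 1e4, n_bins = 20L) {
  m <- lognormalize(x, scale = scale)
  if (all(m == 0)) stop("all-zero expression matrix")
  y <- expm1(m)
  mu <- colMeans(y)
  v <- colSums(sweep(y, 2L, mu)^2) / max(nrow(y) - 1L, 1L)
  ok <- mu > 0 & v > 0
  if (!any(ok)) stop("no gene with positive dispersion")
  disp <- log(v[ok] / mu[ok])
  lmu <- log1p(mu[ok])
  bin <- if (n_bins < 2) rep(1L, length(lmu))
         else cut(lmu, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  ndisp <- disp
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    # degenerate bins (one gene, or identical dispersions): scale by the
    # dispersion itself so such genes get a fixed unit score
    ndisp[i] <- if (is.na(s) || s == 0)
      ifelse(disp[i] == 0, 0, sign(disp[i]))
    else (disp[i] - mean(disp[i])) / s
  }
  genes <- names(disp)
  if (length(genes) < n_hvg)
    warning(sprintf("only %d genes qualify for HVG selection (requested %d)",
                    length(genes), n_hvg))
  o <- order(-ndisp, genes)
  genes[o][seq_len(min(n_hvg, length(genes)))]
}

#' Impute a shared cross-species feature space over the gene-match graph
#'
#' Builds, for each species, a cells x (G_A union G_B) matrix over one common
#' ordered feature list. Within-species genes keep their (z-scored) values;
#' each opposite-species gene `u` is imputed as the weighted average of the
#' within-species genes it is matched to: `sum_v e_uv X_v / sum_v e_uv`.
#' Feature ids are namespaced as `species:gene` so the two species' gene
#' symbols cannot collide.
#'
#' @param x_a,x_b z-scored expression matrices (cells x genes, gene colnames)
#'   covering at least the graph's matched gene sets.
#' @param g a `gene_match_graph` (its `weight` column supplies `e_uv`; BLAST
#'   bitscore weights work unchanged because of the within-group
#'   normalization).
#' @return list with elements `a` and `b`, each a `shared_features` object:
#'   `values` (cells x features), `feature_ids`, `origin`
#'   (`"native"`/`"imputed"` per feature), `species`.
#' @export
impute_shared <- function(x_a, x_b, g) {
  stopifnot(inherits(g, "gene_match_graph"))
  if (nrow(g$edges) == 0L) stop("empty match graph")
  ga <- g$genes_a; gb <- g$genes_b
  if (!all(ga %in% colnames(x_a)))
    stop("x_a is missing matched species-A genes")
  if (!all(gb %in% colnames(x_b)))
    stop("x_b is missing matched species-B genes")
  sp_a <- unname(g$species["a"]); sp_b <- unname(g$species["b"])
  feat <- c(paste0(sp_a, ":", ga), paste0(sp_b, ":", gb))

  # weight matrix W[v in G_A, u in G_B]
  W <- matrix(0, length(ga), length(gb), dimnames = list(ga, gb))
  W[cbind(match(g$edges$gene_a, ga), match(g$edges$gene_b, gb))] <-
    g$edges$weight

  impute_block <- function(native, W_to_other, other_names) {
    sums <- colSums(W_to_other)
    zero <- sums == 0
    if (any(zero)) {
      warning(sprintf("%d feature(s) with zero total match weight set to 0",
                      sum(zero)))
      sums[zero] <- 1
    }
    imp <- native %*% sweep(W_to_other, 2L, sums, "/")
    imp[, zero] <- 0
    colnames(imp) <- other_names
    imp
  }

  na_ <- x_a[, ga, drop = FALSE]
  nb_ <- x_b[, gb, drop = FALSE]
  va <- cbind(na_, impute_block(na_, W, gb))
  vb <- cbind(impute_block(nb_, t(W), ga), nb_)
  colnames(va) <- feat
  colnames(vb) <- feat
  origin_a <- c(rep("native", length(ga)), rep("imputed", length(gb)))
  origin_b <- c(rep("imputed", length(ga)), rep("native", length(gb)))
  list(
    a = structure(list(species = sp_a, values = va, feature_ids = feat,
                       origin = origin_a), class = "shared_features"),
    b = structure(list(species = sp_b, values = vb, feature_ids = feat,
                       origin = origin_b), class = "shared_features"))
}

#' @export
print.shared_features <- function(x, ...) {
  cat(sprintf("Shared feature matrix: %s, %d cells x %d features (%d native, %d imputed)\n",
              x$species, nrow(x$values), length(x$feature_ids),
              sum(x$origin == "native"), sum(x$origin == "imputed")))
  invisible(x)
}

#' @export
as.matrix.shared_features <- function(x, ...) x$values
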