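#' Construct a per-gene protein embedding set
#'
#' Bundles fixed-length protein embedding vectors for one species. Each gene
#' maps to one numeric vector of a common dimension `D` (protein language
#' models typically emit `D = 1024`, but any dimension is accepted). Genes with
#' several isoforms may be represented by several rows sharing a gene id in
#' `vectors` only after pooling; within a set, gene ids must be unique.
#'
#' @param species single character label for the species.
#' @param vectors numeric matrix, genes in rows (rownames are gene ids),
#'   embedding dimensions in columns. All entries must be finite.
#' @return an object of class `protein_embedding_set` with elements `species`,
#'   `vectors` and `dim`.
#' @examples
#' emb <- protein_embedding_set("mouse", matrix(rnorm(20), 4, 5,
#'   dimnames = list(paste0("g", 1:4), NULL)))
#' emb$dim
#' @export
protein_embedding_set <- function(species, vectors) {
  stopifnot(is.character(species), length(species) == 1L)
  vectors <- as.matrix(vectors)
  if (!is.numeric(vectors) || ncol(vectors) < 1L)
    stop("'vectors' must be a numeric matrix with >= 1 column")
  if (is.null(rownames(vectors)))
    stop("'vectors' must have gene ids as rownames")
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate gene ids in embedding set")
  if (any(!is.finite(vectors)))
    stop("non-finite entries in embedding vectors")
  structure(list(species = species, vectors = vectors, dim = ncol(vectors)),
            class = "protein_embedding_set")
}

#' @export
print.protein_embedding_set <- function(x, ...) {
  cat(sprintf("Protein embedding set: %s, %d genes, dimension %d\n",
              x$species, nrow(x$vectors), x$dim))
  invisible(x)
}

#' Pool a per-residue embedding matrix into one gene-level vector
#'
#' Protein language models emit one embedding per residue. The gene-level
#' embedding is the column-wise mean over positions; sequences longer than
#' `max_len` residues are truncated to their first `max_len` positions before
#' pooling (default 2500).
#'
#' @param m numeric matrix, residues in rows (L x D).
#' @param max_len maximum number of leading residue positions used.
#' @return numeric vector of length `ncol(m)`.
#' @examples
#' m <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE)
#' pool_residue_embedding(m)  # c(1, 1)
#' @export
pool_residue_embedding <- function(m, max_len = 2500L) {
  m <- as.matrix(m)
  if (nrow(m) < 1L) stop("empty sequence")
  stopifnot(max_len >= 1L)
  keep <- seq_len(min(nrow(m), max_len))
  colMeans(m[keep, , drop = FALSE])
}

#' Cosine distance between two embedding vectors
#'
#' `1 - cos(u, v)`; lies in `[0, 2]`. Both vectors must be nonzero.
#'
#' @param u,v numeric vectors of equal length.
#' @return a single number in `[0, 2]`.
#' @examples
#' cosine_distance(c(1, 0), c(1, 1))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("embedding dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm embedding")
  min(max(1 - sum(u * v) / (nu * nv), 0), 2)  # guard rounding at 0 and 2
}

# All-pairs cosine distance between the rows of two matrices, via one
# crossproduct. Rows must be nonzero.
cosine_distance_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("embedding dimension mismatch between species")
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-norm embedding")
  d <- 1 - tcrossprod(A / na, B / nb)
  # numerical guard: exact self-similarity can land at -1e-16
  d[d < 0] <- 0
  d
}
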