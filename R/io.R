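#' @title File formats
#' @description Readers and writers for the plain-text formats the pipeline
#'   consumes and emits: embedding TSVs, BLAST tabular (outfmt-6) hits,
#'   MatrixMarket expression bundles, match-graph TSVs, correspondence
#'   tables, shared-feature matrices, match results, model checkpoints and
#'   run manifests.
#' @name scXmatch-io
NULL

.feature_hash <- function(ids) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(ids, f)
  unname(tools::md5sum(f))
}

#' Read a per-gene embedding TSV
#'
#' Format: one gene per line, `gene_id` followed by D tab-separated floats;
#' a header line is detected and skipped automatically.
#'
#' @param path file path.
#' @param species species label for the resulting set.
#' @return a [protein_embedding_set()].
#' @export
read_embedding_tsv <- function(path, species) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  colnames(m) <- NULL
  protein_embedding_set(species, m)
}

#' Write a per-gene embedding TSV
#' @param emb a [protein_embedding_set()].
#' @param path file path.
#' @export
write_embedding_tsv <- function(emb, path) {
  stopifnot(inherits(emb, "protein_embedding_set"))
  lines <- vapply(seq_len(nrow(emb$vectors)), function(i)
    paste(c(rownames(emb$vectors)[i], sprintf("%.17g", emb$vectors[i, ])),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Expects the 12-column tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`); only query,
#' subject, E-value and bitscore are consumed. A malformed row raises an
#' error naming its line number.
#'
#' @param path file path.
#' @return data frame with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_blast_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 12L))
    stop(sprintf("malformed BLAST row at line %d: expected 12 fields, got %d",
                 which(n_fields != 12L)[1L], n_fields[n_fields != 12L][1L]))
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 11L)))
  bs <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 12L)))
  if (anyNA(ev) || anyNA(bs))
    stop(sprintf("malformed BLAST row at line %d: non-numeric evalue/bitscore",
                 which(is.na(ev) | is.na(bs))[1L]))
  data.frame(query = vapply(parts, `[`, "", 1L),
             subject = vapply(parts, `[`, "", 2L),
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Write hits as BLAST outfmt-6
#'
#' Alignment-detail columns not represented in the hit table are filled with
#' placeholder values; query, subject, E-value and bitscore are faithful.
#'
#' @param hits data frame with columns `query`, `subject`, `evalue`,
#'   `bitscore`.
#' @param path file path.
#' @export
write_blast_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t100.0\t100\t0\t0\t1\t100\t1\t100\t%g\t%g",
                   hits$query, hits$subject, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a gene-match graph TSV
#'
#' Columns: `gene_a`, `gene_b`, `distance`, `weight`, `source`.
#'
#' @param g a `gene_match_graph`.
#' @param path file path.
#' @export
write_match_graph <- function(g, path) {
  stopifnot(inherits(g, "gene_match_graph"))
  e <- g$edges
  e$distance <- ifelse(is.na(e$distance), "NA", sprintf("%.17g", e$distance))
  e$weight <- sprintf("%.17g", e$weight)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_graph
#' @param species_a,species_b species labels for the loaded graph.
#' @export
read_match_graph <- function(path, species_a = "A", species_b = "B") {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  e$distance <- as.numeric(e$distance)
  e$weight <- as.numeric(e$weight)
  new_match_graph(e, species_a, species_b, params = list(loaded_from = path))
}

#' Write / read an expression dataset as a MatrixMarket bundle
#'
#' Writes `matrix.mtx` (cells x genes), `genes.tsv`, `barcodes.tsv` and
#' `metadata.tsv` (columns `cell_id`, `cell_type`) into a directory.
#'
#' @param ds an [expression_dataset()].
#' @param dir directory (created if missing).
#' @export
write_mtx_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(ds$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(cell_id = ds$cell_ids,
                                cell_type = ds$cell_types),
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_mtx_dataset
#' @param species species label.
#' @param type_col name of the metadata column holding cell types.
#' @export
read_mtx_dataset <- function(dir, species, type_col = "cell_type") {
  need <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                           "metadata.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(Matrix::readMM(need[1L]))
  genes <- readLines(need[2L])
  cells <- readLines(need[3L])
  meta <- utils::read.table(need[4L], sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!type_col %in% names(meta))
    stop(sprintf("metadata has no '%s' column", type_col))
  dimnames(m) <- list(cells, genes)
  types <- meta[[type_col]][match(cells, meta$cell_id)]
  if (anyNA(types)) stop("metadata does not cover all barcodes")
  expression_dataset(m, types, species)
}

#' Write / read a type correspondence TSV
#'
#' Columns `type_a`, `type_b`, `status`; `status` is `paired`, `specific_a`
#' (type_b empty) or `specific_b` (type_a empty).
#'
#' @param corr a [type_correspondence()].
#' @param path file path.
#' @export
write_correspondence <- function(corr, path) {
  stopifnot(inherits(corr, "type_correspondence"))
  tab <- rbind(
    data.frame(type_a = corr$pairs$type_a, type_b = corr$pairs$type_b,
               status = "paired"),
    if (length(corr$specific_a))
      data.frame(type_a = corr$specific_a, type_b = "", status = "specific_a"),
    if (length(corr$specific_b))
      data.frame(type_a = "", type_b = corr$specific_b, status = "specific_b"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
read_correspondence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  if (!"status" %in% names(tab)) tab$status <- "paired"
  type_correspondence(tab[tab$status == "paired", c("type_a", "type_b")],
                      specific_a = tab$type_a[tab$status == "specific_a"],
                      specific_b = tab$type_b[tab$status == "specific_b"])
}

#' Write / read a shared-feature matrix as TSV
#'
#' Values go to `path` (first column `cell_id`, then one column per feature);
#' feature origins and the species label go to a `<path>.meta.tsv` sidecar.
#' The round trip reproduces the matrix exactly (values are printed with 17
#' significant digits).
#'
#' @param sf a `shared_features` object (see [impute_shared()]).
#' @param path file path for the values TSV.
#' @export
write_shared_features <- function(sf, path) {
  stopifnot(inherits(sf, "shared_features"))
  header <- paste(c("cell_id", sf$feature_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(sf$values)), function(i)
    paste(c(rownames(sf$values)[i], sprintf("%.17g", sf$values[i, ])),
          collapse = "\t"), "")
  writeLines(c(header, rows), path)
  utils::write.table(data.frame(feature_id = sf$feature_ids,
                                origin = sf$origin, species = sf$species),
                     paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_shared_features
#' @export
read_shared_features <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta <- utils::read.table(paste0(path, ".meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- tab[[1L]]
  structure(list(species = meta$species[1L], values = v,
                 feature_ids = colnames(v), origin = meta$origin),
            class = "shared_features")
}

#' Serialize a match result to a directory
#'
#' Writes the combined and per-direction matrices as TSVs, the per-cell
#' transfers as CSVs, and `metrics.json` (ADS, recall, per-pair combined
#' scores).
#'
#' @param res a `match_result` (see [match_types()]).
#' @param dir output directory.
#' @export
write_match_result <- function(res, dir) {
  stopifnot(inherits(res, "match_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    data.frame(type = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm(res$combined, "combined_matrix.tsv")
  wm(res$m_ab, "confusion_a_to_b.tsv")
  wm(res$m_ba, "confusion_b_to_a.tsv")
  utils::write.csv(res$transfers$a, file.path(dir, "transfers_a.csv"),
                   row.names = FALSE)
  utils::write.csv(res$transfers$b, file.path(dir, "transfers_b.csv"),
                   row.names = FALSE)
  metrics <- list(ads = res$ads, recall = res$recall)
  if (!is.null(res$correspondence)) {
    idx <- .corr_index(res$combined, res$correspondence)
    p <- res$correspondence$pairs
    metrics$per_pair <- data.frame(type_a = p$type_a, type_b = p$type_b,
                                   combined_score = res$combined[idx])
  }
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint stores weights, config, feature ordering (plus its md5),
#' type vocabularies and the training log; loading verifies the feature-order
#' hash and refuses a corrupted or reordered checkpoint.
#'
#' @param model a fitted [cellmatch()] object.
#' @param path file path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cellmatch"))
  saveRDS(list(model = model, feature_hash = .feature_hash(model$feature_ids)),
          path)
  invisible(path)
}

#' @rdname save_model
#' @param expected_features optional feature-id vector that the checkpoint
#'   must match.
#' @export
load_model <- function(path, expected_features = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$feature_hash, .feature_hash(obj$model$feature_ids)))
    stop("feature-order hash mismatch: corrupted checkpoint")
  if (!is.null(expected_features) &&
      !identical(expected_features, obj$model$feature_ids))
    stop("feature-order hash mismatch: checkpoint trained on other features")
  obj$model
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed, package version, R version and md5 sums
#' of the input files next to every pipeline run.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param seed integer seed used for the run.
#' @param inputs character vector of input file paths.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    config = config, seed = seed,
    package = as.character(utils::packageVersion("scXmatch")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
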