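#' Ground-truth cell-type correspondence between two species
#'
#' @param pairs data frame with columns `type_a`, `type_b`: the corresponding
#'   (harmonized) type pairs.
#' @param specific_a,specific_b character vectors of species-specific types
#'   (no counterpart in the other species); these are excluded from ADS and
#'   recall by construction.
#' @return an object of class `type_correspondence`.
#' @export
type_correspondence <- function(pairs, specific_a = character(),
                                specific_b = character()) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("type_a", "type_b") %in% names(pairs)))
  pairs$type_a <- as.character(pairs$type_a)
  pairs$type_b <- as.character(pairs$type_b)
  if (anyDuplicated(pairs[c("type_a", "type_b")]))
    stop("duplicate correspondence pairs")
  if (any(pairs$type_a %in% specific_a) || any(pairs$type_b %in% specific_b))
    stop("a type cannot be both paired and species-specific")
  structure(list(pairs = pairs,
                 specific_a = as.character(specific_a),
                 specific_b = as.character(specific_b)),
            class = "type_correspondence")
}

#' @export
print.type_correspondence <- function(x, ...) {
  cat(sprintf("Type correspondence: %d pairs, %d + %d species-specific types\n",
              nrow(x$pairs), length(x$specific_a), length(x$specific_b)))
  invisible(x)
}

#' Transfer cell-type labels across species by classifier swapping
#'
#' Runs cells of one species through the trained embedding stack and the
#' *opposite* species' classifier; each cell gets the opposite-species type
#' with the highest probability (exact ties go to the first type in the
#' vocabulary).
#'
#' @param model a fitted [cellmatch()] object.
#' @param x shared-feature rows for the cells of species `from`.
#' @param from which species the cells belong to (`"a"` or `"b"`).
#' @return factor of opposite-species types, with attribute `max_prob`.
#' @export
transfer_labels <- function(model, x, from = c("a", "b")) {
  from <- match.arg(from)
  predict(model, x, species = from, classifier = "cross", type = "class")
}

#' Row-normalized confusion matrix of transferred labels
#'
#' Entry `(s, d)` is the fraction of source cells of type `s` whose
#' transferred label is destination type `d`. Vocabularies are fixed in
#' advance; source types with no cells give all-zero rows, recorded in the
#' `empty_rows` attribute.
#'
#' @param true_types per-cell source-species labels.
#' @param transferred_types per-cell transferred destination-species labels.
#' @param types_src,types_dst fixed source/destination vocabularies.
#' @return `|types_src| x |types_dst|` matrix; nonempty rows sum to 1.
#' @export
confusion_normalized <- function(true_types, transferred_types,
                                 types_src, types_dst) {
  true_types <- as.character(true_types)
  transferred_types <- as.character(transferred_types)
  if (!all(true_types %in% types_src))
    stop("unseen source label: ",
         paste(setdiff(true_types, types_src), collapse = ", "))
  if (!all(transferred_types %in% types_dst))
    stop("unseen destination label: ",
         paste(setdiff(transferred_types, types_dst), collapse = ", "))
  counts <- table(factor(true_types, levels = types_src),
                  factor(transferred_types, levels = types_dst))
  m <- unclass(counts / pmax(rowSums(counts), 1L))
  m <- matrix(m, nrow = length(types_src),
              dimnames = list(types_src, types_dst))
  attr(m, "empty_rows") <- types_src[rowSums(counts) == 0L]
  m
}

#' Combine the two transfer directions into one matrix
#'
#' `combined = (M_AtoB + t(M_BtoA)) / 2`, oriented rows = species-A types,
#' columns = species-B types. High entries indicate reciprocal matches.
#'
#' @param m_ab `|T_A| x |T_B|` row-normalized confusion matrix (A cells,
#'   B labels).
#' @param m_ba `|T_B| x |T_A|` row-normalized confusion matrix (B cells,
#'   A labels).
#' @return `|T_A| x |T_B|` combined matrix with entries in `[0, 1]`.
#' @export
combine_directions <- function(m_ab, m_ba) {
  if (!identical(dim(m_ab), rev(dim(m_ba))))
    stop("matrix shapes are not transposes of each other")
  if (!is.null(dimnames(m_ab)) && !is.null(dimnames(m_ba)) &&
      (!identical(rownames(m_ab), colnames(m_ba)) ||
       !identical(colnames(m_ab), rownames(m_ba))))
    stop("matrix dimnames are not transposes of each other")
  (m_ab + t(m_ba)) / 2
}

.corr_index <- function(combined, corr) {
  stopifnot(inherits(corr, "type_correspondence"))
  if (nrow(corr$pairs) == 0L) stop("empty correspondence pair list")
  ra <- match(corr$pairs$type_a, rownames(combined))
  cb <- match(corr$pairs$type_b, colnames(combined))
  if (any(is.na(ra)) || any(is.na(cb)))
    stop("correspondence pair not present in the combined matrix")
  cbind(ra, cb)
}

#' Average diagonal score (ADS)
#'
#' Mean combined-matrix score over the ground-truth corresponding type pairs;
#' species-specific types are excluded by construction of the correspondence.
#' A perfect reciprocal transfer gives 1.
#'
#' @param combined matrix from [combine_directions()] with type dimnames.
#' @param corr a [type_correspondence()].
#' @return a number in `[0, 1]`.
#' @export
ads <- function(combined, corr) {
  mean(combined[.corr_index(combined, corr)])
}

#' Matching recall over the ground-truth correspondence
#'
#' Fraction of corresponding pairs `(a, b)` whose combined score is the
#' *strict* maximum of both row `a` and column `b`; ties count as failures.
#'
#' @inheritParams ads
#' @return a number in `[0, 1]`.
#' @export
match_recall <- function(combined, corr) {
  idx <- .corr_index(combined, corr)
  hits <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1L]; cc <- idx[i, 2L]; v <- combined[r, cc]
    all(v > combined[r, -cc]) && all(v > combined[-r, cc])
  }, logical(1L))
  mean(hits)
}

#' End-to-end cell-type matching of two species
#'
#' Transfers labels in both directions with a fitted model, builds the two
#' row-normalized confusion matrices and the combined matrix, and scores the
#' match with ADS and recall against a ground-truth correspondence.
#'
#' @param model a fitted [cellmatch()] object.
#' @param x_a,x_b shared-feature matrices for all cells of each species.
#' @param labels_a,labels_b the cells' true (within-species) type labels.
#' @param corr a [type_correspondence()]; if `NULL`, ADS/recall are `NA` and
#'   only the matrices are returned.
#' @return an object of class `match_result`: `m_ab`, `m_ba`, `combined`,
#'   `ads`, `recall`, and per-cell `transfers` (a list of two data frames).
#' @export
match_types <- function(model, x_a, x_b, labels_a, labels_b, corr = NULL) {
  stopifnot(inherits(model, "cellmatch"))
  ta <- transfer_labels(model, x_a, from = "a")
  tb <- transfer_labels(model, x_b, from = "b")
  m_ab <- confusion_normalized(labels_a, ta, model$types_a, model$types_b)
  m_ba <- confusion_normalized(labels_b, tb, model$types_b, model$types_a)
  combined <- combine_directions(m_ab, m_ba)
  xa <- as.matrix(x_a); xb <- as.matrix(x_b)
  transfers <- list(
    a = data.frame(cell_id = rownames(xa) %||% seq_along(ta),
                   true_type = as.character(labels_a),
                   transferred_type = as.character(ta),
                   max_probability = attr(ta, "max_prob"),
                   stringsAsFactors = FALSE),
    b = data.frame(cell_id = rownames(xb) %||% seq_along(tb),
                   true_type = as.character(labels_b),
                   transferred_type = as.character(tb),
                   max_probability = attr(tb, "max_prob"),
                   stringsAsFactors = FALSE))
  structure(list(
    m_ab = m_ab, m_ba = m_ba, combined = combined,
    ads = if (is.null(corr)) NA_real_ else ads(combined, corr),
    recall = if (is.null(corr)) NA_real_ else match_recall(combined, corr),
    correspondence = corr, species = model$species,
    transfers = transfers), class = "match_result")
}

#' @export
print.match_result <- function(x, digits = 3L, ...) {
  cat(sprintf("Cell-type match result: %s vs %s\n",
              x$species["a"], x$species["b"]))
  cat(sprintf("  ADS: %s   recall: %s\n",
              format(round(x$ads, digits)), format(round(x$recall, digits))))
  cat("  combined matrix (rows = ", x$species["a"], " types):\n", sep = "")
  print(round(x$combined, digits))
  invisible(x)
}

#' @export
summary.match_result <- function(object, ...) {
  print(object)
  if (!is.null(object$correspondence)) {
    idx <- .corr_index(object$combined, object$correspondence)
    cat("\nPer-pair combined scores:\n")
    p <- object$correspondence$pairs
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %s ~ %s: %.3f\n", p$type_a[i], p$type_b[i],
                  object$combined[idx[i, 1L], idx[i, 2L]]))
  }
  invisible(object)
}
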