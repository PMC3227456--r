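# Descriptor matching, database ranking, and retrieval evaluation.

#' Euclidean distance between two descriptor vectors
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return Nonnegative scalar, `sqrt(sum((v1 - v2)^2))`.
#' @export
euclidean_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop_sp("descriptor length mismatch: %d vs %d", length(v1), length(v2))
  }
  sqrt(sum((v1 - v2)^2))
}

#' Build a descriptor database
#'
#' Collects the matching vectors of a set of chains under one scheme so a
#' query can be ranked against them.
#'
#' @param descriptors List of `surface_descriptor` objects sharing `b` and
#'   `tau_p`.
#' @param scheme One of `"dd1"`, `"dd2"`, `"rc"`, `"drc"`.
#' @param groups Optional character vector of group labels, one per
#'   descriptor (NA for unknown).
#' @return A `descriptor_db`: `$ids` data.frame (structure_id, chain_id,
#'   group), `$vectors` (n x p matrix), `$scheme`, `$b`, `$tau_p`.
#' @export
descriptor_db <- function(descriptors, scheme = c("drc", "dd1", "dd2", "rc"),
                          groups = NULL) {
  scheme <- match.arg(scheme)
  if (length(descriptors) == 0L) stop_sp("empty descriptor list")
  b <- descriptors[[1L]]$b
  tau_p <- descriptors[[1L]]$tau_p
  for (g in descriptors) {
    if (g$b != b || g$tau_p != tau_p) stop_sp("descriptors disagree on b or tau_p")
  }
  vec <- t(vapply(descriptors, descriptor_vector, scheme = scheme,
                  FUN.VALUE = numeric(scheme_length(scheme, b))))
  ids <- data.frame(
    structure_id = vapply(descriptors, function(g) g$structure_id, character(1)),
    chain_id = vapply(descriptors, function(g) g$chain_id, character(1)),
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    stringsAsFactors = FALSE
  )
  key <- paste(ids$structure_id, ids$chain_id)
  if (anyDuplicated(key)) {
    stop_sp("duplicate (structure_id, chain_id): %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(list(ids = ids, vectors = vec, scheme = scheme, b = b,
                 tau_p = tau_p),
            class = "descriptor_db")
}

#' @export
print.descriptor_db <- function(x, ...) {
  cat(sprintf("<descriptor_db: %d chains, scheme %s (length %d), b = %d, tau_p = %g A>\n",
              nrow(x$ids), toupper(x$scheme), ncol(x$vectors), x$b, x$tau_p))
  invisible(x)
}

#' Rank a database against a query descriptor
#'
#' Every database chain is ordered by ascending Euclidean distance to the
#' query; ties are broken by (structure_id, chain_id) so the ranking is
#' deterministic. A query present in the database ranks first at distance 0.
#'
#' @param query A `surface_descriptor`, or a numeric vector already in the
#'   database's scheme.
#' @param db A [descriptor_db()].
#' @param query_id Identifier recorded in the result (derived from the
#'   descriptor when available).
#' @return A `ranked_list`: `$query_id` and `$hits` data.frame
#'   (structure_id, chain_id, group, distance, rank).
#' @export
rank_database <- function(query, db, query_id = NULL) {
  stopifnot(inherits(db, "descriptor_db"))
  if (nrow(db$ids) == 0L) stop_sp("empty database")
  if (inherits(query, "surface_descriptor")) {
    query_id <- query_id %||% paste(query$structure_id, query$chain_id)
    query <- descriptor_vector(query, db$scheme)
  }
  if (length(query) != ncol(db$vectors)) {
    stop_sp("query length %d does not match %s database length %d",
            length(query), toupper(db$scheme), ncol(db$vectors))
  }
  d <- sqrt(colSums((t(db$vectors) - as.numeric(query))^2))
  ord <- order(d, db$ids$structure_id, db$ids$chain_id)
  hits <- db$ids[ord, , drop = FALSE]
  hits$distance <- unname(d[ord])
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  structure(list(query_id = query_id %||% "query", hits = hits,
                 scheme = db$scheme),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  cat(sprintf("<ranked_list: query %s, %d hits (%s)>\n",
              x$query_id, nrow(x$hits), toupper(x$scheme)))
  print(utils::head(x$hits, n))
  if (nrow(x$hits) > n) cat(sprintf("  ... %d more\n", nrow(x$hits) - n))
  invisible(x)
}

#' Write a ranking as TSV
#'
#' Columns mirror the ranked-hit tables of a retrieval screen:
#' structure_id, chain, rank, distance, annotation (the group label).
#'
#' @param ranked A `ranked_list`.
#' @param path Output path.
#' @param header Optional named list echoed as leading `# key: value` lines.
#' @export
write_ranking_tsv <- function(ranked, path, header = NULL) {
  stopifnot(inherits(ranked, "ranked_list"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  df <- data.frame(structure_id = ranked$hits$structure_id,
                   chain = ranked$hits$chain_id,
                   rank = ranked$hits$rank,
                   distance = ranked$hits$distance,
                   annotation = ranked$hits$group,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ranked_groups <- function(ranked, labels = NULL) {
  grp <- ranked$hits$group
  if (!is.null(labels)) {
    key <- paste(ranked$hits$structure_id, ranked$hits$chain_id)
    grp <- unname(labels[key])
  }
  grp
}

#' Enrichment curve for a ranked retrieval
#'
#' At screening fraction `f`, the top `ceiling(f * N)` hits are retrieved;
#' the enrichment factor is `N_obs / N_exp` where `N_obs` counts retrieved
#' members of the query's group and `N_exp = ceiling(f * N) * n_group / N`
#' is the count expected under random selection. EF decays to 1 at 100%
#' screening when the whole group is in the database.
#'
#' @param ranked A `ranked_list`.
#' @param query_group Group label of the query.
#' @param fractions Screening fractions in `(0, 1]`.
#' @param labels Optional named group vector keyed by
#'   `paste(structure_id, chain_id)`, overriding the database labels.
#' @param drop_self If TRUE the rank-1 self-hit is removed before scoring.
#' @return data.frame: fraction, n_retrieved, n_obs, n_exp, ef.
#' @export
enrichment_curve <- function(ranked, query_group,
                             fractions = seq(0.05, 1, by = 0.05),
                             labels = NULL, drop_self = FALSE) {
  stopifnot(inherits(ranked, "ranked_list"))
  grp <- ranked_groups(ranked, labels)
  if (drop_self) grp <- grp[-1L]
  if (!query_group %in% grp) stop_sp("group '%s' absent from labels", query_group)
  N <- length(grp)
  n_group <- sum(grp == query_group, na.rm = TRUE)
  is_hit <- cumsum(!is.na(grp) & grp == query_group)
  out <- lapply(fractions, function(f) {
    k <- min(N, ceiling(f * N))
    n_obs <- is_hit[k]
    n_exp <- k * n_group / N
    data.frame(fraction = f, n_retrieved = k, n_obs = n_obs,
               n_exp = n_exp, ef = n_obs / n_exp)
  })
  do.call(rbind, out)
}

#' Precision and recall of a ranked retrieval
#'
#' At each rank r, precision is `correct(r) / r` and recall is
#' `correct(r) / min(r, n_group)` — the number of true matches one could
#' have retrieved by rank r is capped by the rank itself. The area under
#' the precision-recall curve is computed by the trapezoid rule over
#' recall-sorted points, prepending `(recall = 0, precision = precision[1])`.
#'
#' @inheritParams enrichment_curve
#' @return A `retrieval_eval`: data.frame (rank, correct, precision, recall)
#'   with attributes `auc`, `query_group`, `n_group`.
#' @export
precision_recall <- function(ranked, query_group, labels = NULL,
                             drop_self = FALSE) {
  stopifnot(inherits(ranked, "ranked_list"))
  grp <- ranked_groups(ranked, labels)
  if (drop_self) grp <- grp[-1L]
  if (!query_group %in% grp) stop_sp("group '%s' absent from labels", query_group)
  n_group <- sum(grp == query_group, na.rm = TRUE)
  r <- seq_along(grp)
  correct <- cumsum(!is.na(grp) & grp == query_group)
  precision <- correct / r
  recall <- correct / pmin(r, n_group)
  df <- data.frame(rank = r, correct = correct, precision = precision,
                   recall = recall)
  structure(df, class = c("retrieval_eval", "data.frame"),
            auc = pr_auc(recall, precision), query_group = query_group,
            n_group = n_group)
}

# Trapezoid area over recall-sorted PR points, anchored at recall 0.
pr_auc <- function(recall, precision) {
  ord <- order(recall, precision)
  x <- c(0, recall[ord])
  y <- c(precision[ord][1L], precision[ord])
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.retrieval_eval <- function(x, ...) {
  cat(sprintf("<retrieval_eval: group %s (size %d), PR AUC %.4f>\n",
              attr(x, "query_group"), attr(x, "n_group"), attr(x, "auc")))
  invisible(x)
}

#' Average precision-recall curves pointwise over ranks
#'
#' @param evals List of `retrieval_eval` objects over databases of equal
#'   size (ranks are aligned positionally).
#' @return A data.frame (rank, precision, recall) with attribute `auc`.
#' @export
average_precision_recall <- function(evals) {
  stopifnot(length(evals) > 0L)
  n <- nrow(evals[[1L]])
  for (e in evals) if (nrow(e) != n) stop_sp("rank lists of unequal length")
  precision <- Reduce(`+`, lapply(evals, `[[`, "precision")) / length(evals)
  recall <- Reduce(`+`, lapply(evals, `[[`, "recall")) / length(evals)
  structure(data.frame(rank = seq_len(n), precision = precision,
                       recall = recall),
            auc = pr_auc(recall, precision))
}
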