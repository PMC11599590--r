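## Knockout-response clustering: the retained-outcome x knockout-line log2
## fold-change matrix, its 2-D embedding, k-means clustering, and cluster
## composition / enrichment / directionality summaries.

#' Build the outcome x knockout LFC matrix
#'
#' Rows are (target, outcome) pairs that (1) are present in the control
#' profile of their target and (2) are present (count > 0) in at least
#' `min_lines` knockout lines; outcomes failing either filter are removed
#' and their total control-frequency mass is logged. Entries are
#' `log2((f_ko + pc) / (f_ctrl + pc))`, with absent frequencies taken as 0,
#' so the matrix has no missing entries.
#'
#' @inheritParams annotate_outcomes
#' @param control control line label.
#' @param pc pseudocount in frequency units.
#' @param min_lines knockout-presence filter (default 10; clipped with a
#'   warning when fewer knockout lines are available).
#' @return an `lfc_matrix`: list with `lfc` (numeric matrix, rows named
#'   `target|outcome`, columns knockout lines), `meta` (row metadata:
#'   `target`, `outcome`, `category`, `del_size`, `ins_size`, `mh_len`,
#'   `ctrl_freq`, `directionality`, `in_frame`), `control`, `pc` and
#'   attribute-like field `removed_mass` (mean control frequency removed
#'   per target).
#' @export
build_lfc_matrix <- function(profiles, library, control = "control",
                             pc = 0.001, min_lines = 10L, mh_min = 2L) {
  lines <- unique(profiles$line)
  ko_lines <- setdiff(lines, control)
  if (!control %in% lines) stop("control line not found: ", control)
  if (length(ko_lines) < 2L) stop("need at least 2 knockout lines")
  if (min_lines > length(ko_lines)) {
    warning(sprintf("min_lines clipped from %d to the %d available knockout lines",
                    min_lines, length(ko_lines)))
    min_lines <- length(ko_lines)
  }

  prof <- tibble::as_tibble(profiles)
  ctrl <- prof[prof$line == control & prof$count > 0, ]
  presence <- prof[prof$line %in% ko_lines & prof$count > 0, ] |>
    dplyr::group_by(.data$target, .data$outcome) |>
    dplyr::summarise(n_lines = dplyr::n_distinct(.data$line), .groups = "drop")
  keep <- dplyr::inner_join(
    ctrl[c("target", "outcome", "freq")],
    presence[presence$n_lines >= min_lines, c("target", "outcome")],
    by = c("target", "outcome")
  )
  if (!nrow(keep)) stop("no outcomes survive the presence filters")

  removed <- dplyr::anti_join(ctrl, keep, by = c("target", "outcome")) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(mass = sum(.data$freq), .groups = "drop")
  removed_mass <- if (nrow(removed)) mean(removed$mass) else 0
  message(sprintf("build_lfc_matrix: kept %d outcomes; removed control mass averages %.1f%% per target",
                  nrow(keep), 100 * removed_mass))

  wide <- prof[prof$line %in% ko_lines, c("target", "line", "outcome", "freq")] |>
    dplyr::right_join(keep[c("target", "outcome")], by = c("target", "outcome")) |>
    tidyr::pivot_wider(names_from = "line", values_from = "freq", values_fill = 0)
  for (ln in setdiff(ko_lines, names(wide))) wide[[ln]] <- 0
  wide <- dplyr::inner_join(wide, keep, by = c("target", "outcome"))
  m <- log2((as.matrix(wide[ko_lines]) + pc) / (wide$freq + pc))
  rownames(m) <- paste(wide$target, wide$outcome, sep = "|")

  ann <- annotate_outcomes(keep, library, mh_min = mh_min)
  meta <- dplyr::inner_join(wide[c("target", "outcome", "freq")], ann,
                            by = c("target", "outcome"))
  names(meta)[names(meta) == "freq"] <- "ctrl_freq"
  structure(
    list(lfc = m, meta = meta, control = control, pc = pc,
         min_lines = min_lines, removed_mass = removed_mass),
    class = "lfc_matrix"
  )
}

#' 2-D embedding of knockout response profiles
#'
#' Embeds LFC matrix rows in two dimensions. The default backend is a
#' spectral embedding (Laplacian eigenmap) of the symmetrized
#' `n_neighbors`-nearest-neighbour graph on Euclidean distances: the
#' eigenvectors of the symmetric normalized graph Laplacian for the two
#' smallest non-trivial eigenvalues. It is fully deterministic; `seed` is
#' recorded for provenance. A PCA backend (first two principal components)
#' is available via `method = "pca"`. Rows with non-finite entries are an
#' error; duplicated rows map to coincident points.
#'
#' @param x an [build_lfc_matrix()] result or a numeric matrix.
#' @param n_neighbors neighbourhood size (default 50; clipped with a
#'   warning when the matrix has fewer than `n_neighbors + 1` rows).
#' @param seed integer seed (recorded; the embedding is deterministic).
#' @param method `"spectral"` (default) or `"pca"`.
#' @return an `lfc_embedding`: list with `coords` (rows x 2 matrix),
#'   `method`, `n_neighbors`, `seed`.
#' @export
embed_lfc <- function(x, n_neighbors = 50L, seed = 1L,
                      method = c("spectral", "pca")) {
  method <- match.arg(method)
  m <- if (inherits(x, "lfc_matrix")) x$lfc else as.matrix(x)
  if (!all(is.finite(m))) stop("non-finite entries in the LFC matrix")
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 rows to embed")
  if (n_neighbors >= n) {
    warning(sprintf("n_neighbors clipped from %d to %d", n_neighbors, n - 1L))
    n_neighbors <- n - 1L
  }
  coords <- if (method == "pca") {
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(p$x))
    cc <- p$x[, seq_len(k), drop = FALSE]
    if (k < 2L) cc <- cbind(cc, 0)
    cc
  } else {
    .spectral_coords(m, n_neighbors, seed)
  }
  dimnames(coords) <- list(rownames(m), c("dim1", "dim2"))
  structure(
    list(coords = coords, method = method,
         n_neighbors = as.integer(n_neighbors), seed = as.integer(seed)),
    class = "lfc_embedding"
  )
}

## Laplacian-eigenmap coordinates: eigenvectors of the symmetric normalized
## Laplacian of the symmetrized kNN graph for the two smallest non-trivial
## eigenvalues. A weak (1e-8) ring through the rows guarantees a single
## connected component without perceptibly perturbing the geometry. Small
## problems use the exact dense eigendecomposition; larger ones use sparse
## orthogonal subspace iteration on the shifted operator S + I (S the
## normalized adjacency), which targets the same leading eigenspace.
.spectral_coords <- function(m, n_neighbors, seed, dense_limit = 1500L) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  nb <- apply(d, 1L, function(r) order(r)[2:(n_neighbors + 1L)])
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = n_neighbors), j = as.vector(nb), x = 1,
    dims = c(n, n)
  )
  adj <- adj + Matrix::t(adj)
  adj@x <- pmin(adj@x, 1)
  ring <- Matrix::sparseMatrix(i = seq_len(n), j = c(2:n, 1L), x = 1e-8,
                               dims = c(n, n))
  adj <- adj + ring + Matrix::t(ring)
  isq <- 1 / sqrt(Matrix::rowSums(adj))
  s <- Matrix::Diagonal(x = isq) %*% adj %*% Matrix::Diagonal(x = isq)
  s <- (s + Matrix::t(s)) / 2

  if (n <= dense_limit) {
    e <- eigen(as.matrix(s), symmetric = TRUE)
    cc <- e$vectors[, 2:3, drop = FALSE]  # largest of S = smallest of L
  } else {
    q <- 6L
    v <- with_seed(seed, matrix(stats::rnorm(n * q), n, q))
    v <- qr.Q(qr(v))
    for (i in seq_len(400L)) {
      v <- qr.Q(qr(as.matrix(s %*% v + v)))
    }
    t_small <- crossprod(v, as.matrix(s %*% v))
    e <- eigen((t_small + t(t_small)) / 2, symmetric = TRUE)
    w <- v %*% e$vectors
    cc <- w[, 2:3, drop = FALSE]
  }
  for (j in 1:2) {
    pivot <- which.max(abs(cc[, j]))
    if (cc[pivot, j] < 0) cc[, j] <- -cc[, j]
  }
  cc * sqrt(n)
}

#' Cluster embedded outcomes
#'
#' k-means on the 2-D embedding coordinates with `nstart` restarts;
#' deterministic given the seed and total (every row gets a label 1..k).
#'
#' @param embedding an [embed_lfc()] result or a coordinate matrix.
#' @param k number of clusters (default 7).
#' @param seed integer seed.
#' @param nstart k-means restarts (default 50).
#' @return integer vector of cluster labels, named by row.
#' @export
cluster_outcomes <- function(embedding, k = 7L, seed = 1L, nstart = 50L) {
  coords <- if (inherits(embedding, "lfc_embedding")) embedding$coords else as.matrix(embedding)
  if (!all(is.finite(coords))) stop("non-finite embedding coordinates")
  if (k > nrow(coords)) stop("k exceeds the number of rows")
  if (k == 1L) return(stats::setNames(rep(1L, nrow(coords)), rownames(coords)))
  km <- with_seed(seed, stats::kmeans(coords, centers = k, nstart = nstart,
                                      iter.max = 100L))
  stats::setNames(as.integer(km$cluster), rownames(coords))
}

#' Cluster composition tables
#'
#' Table E: the distribution of each outcome category over clusters
#' (columns, one per category, each summing to 100%). Table F: the category
#' make-up of each cluster (rows, one per cluster, each summing to 100%).
#' Both are weighted by control-line frequency by default (`weights = NULL`
#' uses `control_freqs`; pass `weights = rep(1, n)` for unweighted counts).
#'
#' @param labels cluster labels aligned to rows.
#' @param categories category label per row.
#' @param control_freqs control-line frequency per row.
#' @param weights optional explicit row weights.
#' @return list with matrices `e` (clusters x categories, columns sum to
#'   100) and `f` (clusters x categories, rows sum to 100); categories or
#'   clusters with zero weight give NA.
#' @export
cluster_composition <- function(labels, categories, control_freqs,
                                weights = NULL) {
  stopifnot(length(labels) == length(categories),
            length(labels) == length(control_freqs))
  w <- weights %||% control_freqs
  tot <- tapply(w, list(cluster = factor(labels),
                        category = factor(categories, levels = .CATEGORIES)),
                sum, default = 0)
  csum <- colSums(tot)
  rsum <- rowSums(tot)
  e <- sweep(tot, 2, ifelse(csum > 0, csum, NA), "/") * 100
  f <- sweep(tot, 1, ifelse(rsum > 0, rsum, NA), "/") * 100
  list(e = e, f = f)
}

#' Knockout enrichment of clusters
#'
#' Entry (cluster c, knockout g) is the mean LFC over rows of c minus the
#' mean LFC over all rows, both within column g, i.e. the within-knockout
#' normalized enrichment; size-weighted column means of the output are 0.
#'
#' @param labels cluster labels aligned to matrix rows.
#' @param x an [build_lfc_matrix()] result or LFC matrix.
#' @return matrix clusters x knockout lines.
#' @export
cluster_knockout_enrichment <- function(labels, x) {
  m <- if (inherits(x, "lfc_matrix")) x$lfc else as.matrix(x)
  stopifnot(length(labels) == nrow(m))
  overall <- colMeans(m)
  cl <- sort(unique(labels))
  out <- t(vapply(cl, function(c) colMeans(m[labels == c, , drop = FALSE]) - overall,
                  numeric(ncol(m))))
  rownames(out) <- as.character(cl)
  out
}

#' Directionality of non-homologous deletions by cluster
#'
#' Restricted to pure deletions with limited microhomology
#' (`mh_len < mh_min`): the per-cluster mean (and count) of deletion
#' directionality, with the library-wide average; clusters without
#' qualifying deletions are omitted with a message.
#'
#' @param x an [build_lfc_matrix()] result.
#' @param labels cluster labels aligned to matrix rows.
#' @param mh_min microhomology threshold.
#' @return list with `per_cluster` (tibble `cluster`, `n`,
#'   `mean_directionality`) and `overall` (library-wide mean).
#' @export
directionality_summary <- function(x, labels, mh_min = 2L) {
  stopifnot(inherits(x, "lfc_matrix"), length(labels) == nrow(x$lfc))
  meta <- x$meta
  qual <- meta$ins_size == 0L & meta$del_size > 0L & !is.na(meta$mh_len) &
    meta$mh_len < mh_min
  if (!any(qual)) stop("no non-homologous deletions among the rows")
  dirs <- meta$directionality[qual]
  labs <- labels[qual]
  missing_cl <- setdiff(sort(unique(labels)), unique(labs))
  if (length(missing_cl)) {
    message("clusters without non-homologous deletions omitted: ",
            paste(missing_cl, collapse = ", "))
  }
  per <- tibble::tibble(cluster = sort(unique(labs)))
  per$n <- vapply(per$cluster, function(c) sum(labs == c), 0L)
  per$mean_directionality <- vapply(per$cluster, function(c) mean(dirs[labs == c]), 0)
  list(per_cluster = per, overall = mean(dirs))
}

#' Synthetic LFC matrix with planted response archetypes
#'
#' Builds an outcome x knockout LFC matrix whose rows follow `n_groups`
#' archetypal knockout-response patterns plus Gaussian noise — the planted
#' ground truth for validating the embed/cluster recovery path. Archetypes
#' are distinct sign patterns of magnitude `effect` over the columns.
#'
#' @param n_per_group rows per archetype.
#' @param n_lines number of knockout columns (default 18).
#' @param n_groups number of archetypes (default 3).
#' @param noise_sd within-group Gaussian noise, in LFC units (default 0.3).
#' @param effect archetype magnitude in LFC units (default 2).
#' @param seed integer seed.
#' @return list with `lfc` (matrix) and `truth` (integer group per row).
#' @export
make_archetype_matrix <- function(n_per_group = 60L, n_lines = 18L,
                                  n_groups = 3L, noise_sd = 0.3,
                                  effect = 2, seed = 1L) {
  stopifnot(n_groups >= 2L, n_lines >= n_groups)
  with_seed(seed, {
    arch <- matrix(0, n_groups, n_lines)
    block <- floor(n_lines / n_groups)
    for (g in seq_len(n_groups)) {
      cols <- ((g - 1L) * block + 1L):(g * block)
      arch[g, cols] <- -effect
      arch[g, (cols - 1L) %% n_lines + 1L] <- arch[g, (cols - 1L) %% n_lines + 1L] + effect / 2
    }
    truth <- rep(seq_len(n_groups), each = n_per_group)
    m <- arch[truth, ] + matrix(stats::rnorm(length(truth) * n_lines, 0, noise_sd),
                                nrow = length(truth))
    rownames(m) <- sprintf("row%04d", seq_along(truth))
    colnames(m) <- sprintf("KO%02d", seq_len(n_lines))
    list(lfc = m, truth = truth)
  })
}
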