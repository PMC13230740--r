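# typing: gene-by-cell expression matrices from spot coordinates and
# nucleus labels, and cell-type calling by cosine distance to reference
# centroids with distance and count gates.

#' Assign spots to cells by nearest nucleus
#'
#' Each spot is assigned to the label whose nucleus (interior or boundary)
#' is nearest in (y, x), provided that distance is at most `max_dist_um`;
#' spots inside a nucleus have distance 0. Ties go to the lower label.
#' This is a deliberately simple baseline for cell attribution when no
#' membrane marker is available.
#'
#' @param spots Spot table (columns `gene`, `y`, `x`; registered frame).
#' @param label_mask 2D integer nucleus label mask in the same frame.
#' @param max_dist_um Maximum spot-to-nucleus distance (um).
#' @param pixel_size_nm Lateral pixel size (nm).
#' @param genes Optional gene universe for the matrix columns (defaults to
#'   the genes present in `spots`).
#' @return An `expression_matrix`: integer matrix cells x genes with
#'   rownames = cell labels; attributes `assignment` (per-spot cell label,
#'   `NA` = unassigned), `n_unassigned` and `flag`.
#' @export
assign_spots_to_cells <- function(spots, label_mask, max_dist_um = 5,
                                  pixel_size_nm = 100, genes = NULL) {
  stopifnot(is.matrix(label_mask))
  labels <- sort(unique(label_mask[label_mask > 0]))
  genes <- genes %||% sort(unique(spots$gene))
  flag <- ""
  max_dist_px <- max_dist_um * 1000 / pixel_size_nm
  n <- nrow(spots)
  assign_lab <- rep(NA_integer_, n)
  if (length(labels) == 0L) {
    flag <- "no_labels"
  } else if (n > 0L) {
    ny <- nrow(label_mask); nx <- ncol(label_mask)
    best_d <- rep(Inf, n)
    yi <- pmin(pmax(round(spots$y), 0), ny - 1) + 1L
    xi <- pmin(pmax(round(spots$x), 0), nx - 1) + 1L
    # per-label Euclidean distance transform; lowest label wins ties
    for (lab in labels) {
      # EBImage::distmap: distance of non-zero pixels to nearest zero pixel,
      # so feed the complement of this label's mask (x, y order)
      dm <- t(EBImage::imageData(EBImage::distmap(
        t(1 - (label_mask == lab)), metric = "euclidean")))
      d <- dm[cbind(yi, xi)]
      better <- d < best_d - 1e-9
      best_d[better] <- d[better]
      assign_lab[better] <- lab
    }
    assign_lab[best_d > max_dist_px] <- NA_integer_
  }
  mat <- matrix(0L, length(labels), length(genes),
                dimnames = list(as.character(labels), genes))
  ok <- !is.na(assign_lab) & spots$gene %in% genes
  if (any(ok)) {
    tab <- table(factor(assign_lab[ok], levels = labels),
                 factor(spots$gene[ok], levels = genes))
    mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
  }
  structure(mat, class = c("expression_matrix", class(mat)),
            assignment = assign_lab, n_unassigned = sum(is.na(assign_lab)),
            flag = flag)
}

#' Cosine distance between an expression vector and a centroid
#'
#' `1 - (x . c) / (||x|| ||c||)`; scale-invariant, in `[0, 1]` for
#' non-negative vectors. A zero expression vector has distance 1 by
#' definition (flagged via attribute).
#'
#' @param x Non-negative count vector.
#' @param centroid Non-negative, non-zero centroid vector.
#' @return Cosine distance (scalar).
#' @export
cosine_distance <- function(x, centroid) {
  if (any(is.na(x)) || any(is.na(centroid))) stop("NaN/NA input")
  stopifnot(length(x) == length(centroid))
  nc <- sqrt(sum(centroid^2))
  if (nc == 0) stop("zero-norm centroid")
  nx <- sqrt(sum(x^2))
  if (nx == 0) return(structure(1, flag = "zero_vector"))
  1 - sum(x * centroid) / (nx * nc)
}

#' Build cell-type centroids from reference expression profiles
#'
#' Computes the per-type median vector over reference cells (typically a
#' reference scRNA-seq dataset reduced to the panel's genes). Precomputed
#' centroids can also be supplied verbatim as a one-cell-per-type matrix.
#'
#' @param profiles Numeric matrix cells x genes (colnames = genes).
#' @param types Character vector of cell-type labels, one per row.
#' @return A `centroid_set`: matrix types x genes of medians.
#' @export
marker_centroids_from_reference <- function(profiles, types) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(types), !is.null(colnames(profiles)))
  u <- unique(types)
  if (any(table(types) == 0)) stop("type with zero cells")
  cen <- t(vapply(u, function(tt)
    apply(profiles[types == tt, , drop = FALSE], 2, median),
    numeric(ncol(profiles))))
  rownames(cen) <- u
  if (any(rowSums(cen^2) == 0)) stop("zero-norm centroid")
  structure(cen, class = c("centroid_set", class(cen)))
}

#' Call cell types by cosine distance to reference centroids
#'
#' Each cell is compared to every centroid; it is assigned to the nearest
#' type iff the cosine distance is strictly below `d_max` AND the cell's
#' total RNA count strictly exceeds `min_rna` (so >= 11 detected RNAs at
#' the default `min_rna = 10`). All other cells are retained as
#' `"unclassified"` with a reason code for auditability.
#'
#' @param matrix_ Expression matrix cells x genes (colnames = genes).
#' @param centroids A `centroid_set` (or matrix types x genes). Gene sets
#'   are intersected, with a warning if partial.
#' @param d_max Cosine-distance gate (strict `<`).
#' @param min_rna Count gate (strict `>`).
#' @return data.frame `(cell_id, type, cosine_distance, total_rna,
#'   reason)`; `reason` is `""` for assigned cells, else
#'   `"distance_gate"`, `"count_gate"` or both.
#' @export
call_cell_types <- function(matrix_, centroids, d_max = 0.8, min_rna = 10L) {
  matrix_ <- unclass(matrix_)
  centroids <- unclass(centroids)
  if (is.null(nrow(centroids)) || nrow(centroids) == 0L)
    stop("empty centroid set")
  common <- intersect(colnames(matrix_), colnames(centroids))
  if (length(common) == 0L) stop("no shared genes between matrix and centroids")
  if (length(common) < ncol(matrix_) || length(common) < ncol(centroids))
    warning("gene sets differ; using the intersection (",
            length(common), " genes)")
  X <- matrix_[, common, drop = FALSE]
  C <- centroids[, common, drop = FALSE]
  cells <- rownames(matrix_) %||% as.character(seq_len(nrow(X)))
  total <- rowSums(matrix_)        # total detected RNAs, all panel genes
  out <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- vapply(seq_len(nrow(C)), function(k) cosine_distance(X[i, ], C[k, ]),
                numeric(1))
    k <- which.min(d)
    pass_d <- d[k] < d_max
    pass_n <- total[i] > min_rna
    reason <- paste(c(if (!pass_d) "distance_gate",
                      if (!pass_n) "count_gate"), collapse = ";")
    out[[i]] <- data.frame(
      cell_id = cells[i],
      type = if (pass_d && pass_n) rownames(C)[k] else "unclassified",
      cosine_distance = d[k], total_rna = as.integer(total[i]),
      reason = reason, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
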