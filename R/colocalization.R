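# colocalization: optimal one-to-one matching of registered spots across
# rounds (Hungarian algorithm) and colocalization percentages, the
# round-to-round QC statistic of sequential smFISH.

#' Match spots across two rounds by optimal assignment
#'
#' Builds the rectangular (y, x) Euclidean cost matrix between the two
#' registered tables, gates it at a cost cap of `cost_cap_factor *
#' threshold` (pairs beyond the cap are all equally expensive, hence
#' effectively forbidden: none can enter the reported matches, and spots
#' without a near partner cannot displace genuine pairs), solves the
#' optimal one-to-one assignment (Hungarian algorithm via
#' `clue::solve_LSAP`), and THEN discards matched pairs at or beyond the
#' distance threshold. The colocalization percentage
#' uses the query round's spot count as denominator by default ("percentage
#' of total spots identified in that round"); `denominator = "reference"`
#' is available.
#'
#' @param reference,query Registered spot tables (columns `y`, `x` in px).
#' @param threshold_um Distance threshold in micrometres (strict `<`).
#' @param pixel_size_nm Lateral pixel size (nm) converting px to um.
#' @param cost_cap_factor Pairs beyond `cost_cap_factor * threshold` are
#'   treated as forbidden before solving. Must be >= 1.
#' @param denominator `"query"` (default) or `"reference"`.
#' @return A `match_result`: list with `pairs` (data.frame `ref_index`,
#'   `query_index`, `distance_px`, `distance_um`), `n_ref`, `n_query`,
#'   `n_matched`, `threshold_um`, `percent_colocalized` and `flags`.
#' @export
match_spots <- function(reference, query, threshold_um = 0.5,
                        pixel_size_nm = 100, cost_cap_factor = 4,
                        denominator = c("query", "reference")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold_um >= 0, cost_cap_factor >= 1)
  n_ref <- nrow(reference); n_query <- nrow(query)
  thr_px <- threshold_um * 1000 / pixel_size_nm
  empty_pairs <- data.frame(ref_index = integer(0), query_index = integer(0),
                            distance_px = numeric(0), distance_um = numeric(0))
  result <- function(pairs, flags = "") {
    n_matched <- nrow(pairs)
    pct <- if (denominator == "query") {
      if (n_query > 0) 100 * n_matched / n_query else NA_real_
    } else {
      if (n_ref > 0) 100 * n_matched / n_ref else NA_real_
    }
    if (n_query == 0 && denominator == "query")
      flags <- paste_flag(flags, "undefined_percent")
    structure(list(pairs = pairs, n_ref = n_ref, n_query = n_query,
                   n_matched = n_matched, threshold_um = threshold_um,
                   percent_colocalized = pct, flags = flags),
              class = "match_result")
  }
  if (n_ref == 0L || n_query == 0L) return(result(empty_pairs))

  dy <- outer(reference$y, query$y, "-")
  dx <- outer(reference$x, query$x, "-")
  D <- sqrt(dy^2 + dx^2)                     # n_ref x n_query, px
  cap_px <- cost_cap_factor * thr_px
  forbidden <- D > cap_px
  # gate costs at the cap: every pair beyond it is equally expensive, so a
  # spot without a near partner "spends" the cap instead of displacing
  # genuine sub-threshold pairs along augmenting chains (an unbounded
  # distance would have the same pathology as a huge forbidden cost:
  # the solver would sacrifice true pairs to shorten far ones)
  C <- pmin(D, cap_px)
  # solve_LSAP needs nrow <= ncol; transpose if reference is the larger side
  if (n_ref <= n_query) {
    sol <- clue::solve_LSAP(C)
    pairs <- data.frame(ref_index = seq_len(n_ref),
                        query_index = as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(C))
    pairs <- data.frame(ref_index = as.integer(sol),
                        query_index = seq_len(n_query))
  }
  pairs$distance_px <- D[cbind(pairs$ref_index, pairs$query_index)]
  pairs <- pairs[!forbidden[cbind(pairs$ref_index, pairs$query_index)], ,
                 drop = FALSE]
  # threshold applied AFTER assignment, strict inequality
  pairs <- pairs[pairs$distance_px < thr_px, , drop = FALSE]
  pairs$distance_um <- pairs$distance_px * pixel_size_nm / 1000
  rownames(pairs) <- NULL
  result(pairs)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d/%d query spots matched to %d reference spots (< %.3g um): %.1f%%\n",
              x$n_matched, x$n_query, x$n_ref, x$threshold_um,
              x$percent_colocalized))
  invisible(x)
}

#' Colocalization percentage of every round against a gene's first round
#'
#' For each round of one gene, matches its registered spots to the gene's
#' reference round and reports the percentage colocalized. The reference
#' round is reported as 100 by definition; missing rounds are flagged.
#'
#' @param spot_tables List of registered spot tables indexed by round
#'   (entries may be `NULL` for rounds not imaging this gene).
#' @param reference_round Index of the gene's first (reference) round.
#' @param threshold_um,pixel_size_nm,... Passed to [match_spots()].
#' @return data.frame `(round, n_query, n_matched, percent, flags)`.
#' @export
colocalization_series <- function(spot_tables, reference_round,
                                  threshold_um = 0.5, pixel_size_nm = 100,
                                  ...) {
  ref <- spot_tables[[reference_round]]
  if (is.null(ref)) stop("reference round missing")
  rows <- lapply(seq_along(spot_tables), function(r) {
    if (is.null(spot_tables[[r]]))
      return(data.frame(round = r, n_query = NA_integer_,
                        n_matched = NA_integer_, percent = NA_real_,
                        flags = "missing_round", stringsAsFactors = FALSE))
    if (r == reference_round)
      return(data.frame(round = r, n_query = nrow(ref),
                        n_matched = nrow(ref), percent = 100,
                        flags = "reference", stringsAsFactors = FALSE))
    m <- match_spots(ref, spot_tables[[r]], threshold_um, pixel_size_nm, ...)
    data.frame(round = r, n_query = m$n_query, n_matched = m$n_matched,
               percent = m$percent_colocalized, flags = m$flags,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-gene colocalization (specificity control)
#'
#' Matches the registered spots of two different genes with the same
#' machinery as same-gene colocalization. Because distinct transcripts
#' occupy independent positions, this percentage should be low; it serves
#' as a control against cross-detection between rounds.
#'
#' @param gene_a,gene_b Registered spot tables of the two genes.
#' @param threshold_um,pixel_size_nm,... Passed to [match_spots()].
#' @return A `match_result`.
#' @export
cross_gene_colocalization <- function(gene_a, gene_b, threshold_um = 0.2,
                                      pixel_size_nm = 100, ...) {
  match_spots(gene_a, gene_b, threshold_um, pixel_size_nm, ...)
}

# Exhaustive-permutation assignment optimum (test oracle; <= 8 per side).
brute_force_assignment_cost <- function(C) {
  n <- nrow(C); m <- ncol(C)
  stopifnot(min(n, m) <= 8)
  if (n <= m) {
    perms <- perm_enum(m, n)
    costs <- apply(perms, 1, function(p) sum(C[cbind(seq_len(n), p)]))
  } else {
    perms <- perm_enum(n, m)
    costs <- apply(perms, 1, function(p) sum(C[cbind(p, seq_len(m))]))
  }
  min(costs)
}

# All ordered k-permutations of 1..n as rows.
perm_enum <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (i in seq_len(k - 1L)) {
    rows <- lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(out[r, ], length(rest), i, byrow = TRUE), rest)
    })
    out <- do.call(rbind, rows)
  }
  unname(out)
}
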