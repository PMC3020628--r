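# Adjacent-locality pair construction, genetic-disjunction classification
# and the beach-length disjunction regression.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Adjacent locality pairs along the coast
#'
#' Builds one record per pair of consecutive localities in coastal order
#' (optionally restricted to a region), with the coastal distance between
#' them and, when a beach table is supplied, the maximum uninterrupted
#' beach length separating them.
#'
#' @param locality_table data.frame with `locality`,
#'   `coastal_position_km` and optionally `order_index` (used for
#'   ordering when present).
#' @param beach_table optional data.frame with `locality_a`, `locality_b`,
#'   `max_beach_km`; must cover every adjacent pair of the (filtered)
#'   region. When `NULL`, `max_beach_km` is `NA`.
#' @param region optional character vector of locality names; localities
#'   outside it are dropped and their neighbours re-paired.
#' @return data.frame with `pair_id`, `locality_a`, `locality_b`,
#'   `coastal_km`, `max_beach_km`.
#' @export
adjacent_pairs <- function(locality_table, beach_table = NULL,
                           region = NULL) {
  lt <- locality_table
  if (!is.null(lt$order_index)) lt <- lt[order(lt$order_index), , drop = FALSE]
  if (!is.null(region)) lt <- lt[lt$locality %in% region, , drop = FALSE]
  if (nrow(lt) < 2) {
    kelp_stop("kelp_parameter_error",
              "need >= 2 localities in the region (have %d)", nrow(lt))
  }
  if (is.unsorted(lt$coastal_position_km)) {
    kelp_stop("kelp_ordering_error",
              "coastal_position_km must be non-decreasing in coastal order")
  }
  n <- nrow(lt)
  a <- lt$locality[-n]
  b <- lt$locality[-1]
  pairs <- data.frame(
    pair_id = paste(a, b, sep = "--"),
    locality_a = a,
    locality_b = b,
    coastal_km = diff(lt$coastal_position_km),
    max_beach_km = NA_real_,
    stringsAsFactors = FALSE)
  if (any(pairs$coastal_km <= 0)) {
    kelp_warn("adjacent pair(s) with zero coastal separation: %s",
              paste(pairs$pair_id[pairs$coastal_km <= 0], collapse = ", "))
  }
  if (!is.null(beach_table)) {
    hit <- match(pair_key(a, b),
                 pair_key(beach_table$locality_a, beach_table$locality_b))
    if (anyNA(hit)) {
      kelp_stop("kelp_coverage_error",
                "beach table lacks adjacent pair(s): %s",
                paste(pairs$pair_id[is.na(hit)], collapse = ", "))
    }
    pairs$max_beach_km <- beach_table$max_beach_km[hit]
    over <- !is.na(pairs$max_beach_km) &
      pairs$max_beach_km > pairs$coastal_km
    if (any(over)) {
      kelp_warn("beach length exceeds coastal distance for: %s",
                paste(pairs$pair_id[over], collapse = ", "))
    }
  }
  pairs
}

#' Classify adjacent pairs as genetically disjunct
#'
#' A pair is disjunct when Nei's raw average pairwise difference between
#' the two localities meets the threshold (`D >= threshold`, inclusive;
#' default 1.0). Independently, `shares_haplotypes` records whether any
#' haplotype is observed in both localities; a pair that is disjunct yet
#' shares haplotypes is flagged in the `consistency` attribute and a
#' warning (in the field data motivating this convention, no disjunct
#' pair shared haplotypes).
#'
#' @param pairs data.frame from [adjacent_pairs()].
#' @param D_matrix `kelp_dist` genetic-D matrix covering all pair
#'   localities.
#' @param ht `haplotype_table` whose count matrix covers all pair
#'   localities.
#' @param threshold disjunction threshold on the raw-difference scale.
#' @return `pairs` with added columns `nei_D`, `shares_haplotypes`,
#'   `disjunct`, and attribute `consistency` (data.frame of flagged
#'   pairs).
#' @export
classify_disjunct <- function(pairs, D_matrix, ht, threshold = 1.0) {
  labs <- rownames(D_matrix)
  need <- unique(c(pairs$locality_a, pairs$locality_b))
  if (!all(need %in% labs)) {
    kelp_stop("kelp_label_error", "locality absent from D matrix: %s",
              paste(setdiff(need, labs), collapse = ", "))
  }
  if (!all(need %in% rownames(ht$counts))) {
    kelp_stop("kelp_label_error", "locality absent from haplotype table: %s",
              paste(setdiff(need, rownames(ht$counts)), collapse = ", "))
  }
  pairs$nei_D <- D_matrix[cbind(pairs$locality_a, pairs$locality_b)]
  pairs$shares_haplotypes <- vapply(seq_len(nrow(pairs)), function(i) {
    any(ht$counts[pairs$locality_a[i], ] > 0 &
          ht$counts[pairs$locality_b[i], ] > 0)
  }, logical(1))
  pairs$disjunct <- pairs$nei_D >= threshold
  flagged <- pairs[pairs$disjunct & pairs$shares_haplotypes, , drop = FALSE]
  if (nrow(flagged) > 0) {
    kelp_warn("disjunct pair(s) sharing haplotypes: %s",
              paste(flagged$pair_id, collapse = ", "))
  }
  attr(pairs, "consistency") <- flagged
  attr(pairs, "threshold") <- threshold
  pairs
}

#' Disjunction regression on beach length and coastal distance
#'
#' Fits the Firth-penalized logistic model
#' `disjunct ~ max_beach_km + coastal_km` over classified adjacent pairs,
#' and optionally a second fit with listed pairs excluded (e.g. an
#' outlier pair bridged by a stepping-stone island).
#'
#' @param pairs classified pair table from [classify_disjunct()] (columns
#'   `disjunct`, `max_beach_km`, `coastal_km`, `pair_id`).
#' @param exclude character vector of `pair_id`s to drop in the second
#'   fit.
#' @param tol,max_iter passed to [firth_logistic()].
#' @return a `disjunction_analysis`: `pair_table`, `fit_full`,
#'   `fit_excluded` (`NULL` when `exclude` is empty), `excluded`.
#'   A fit on an all-identical response is flagged `degenerate` with a
#'   warning.
#' @export
disjunction_analysis <- function(pairs, exclude = character(),
                                 tol = 1e-8, max_iter = 50) {
  need <- c("pair_id", "disjunct", "max_beach_km", "coastal_km")
  if (!all(need %in% names(pairs))) {
    kelp_stop("kelp_format_error", "pairs must carry columns: %s",
              paste(need, collapse = ", "))
  }
  if (anyNA(pairs$max_beach_km)) {
    kelp_stop("kelp_coverage_error",
              "max_beach_km is missing for pair(s): %s",
              paste(pairs$pair_id[is.na(pairs$max_beach_km)], collapse = ", "))
  }
  unknown <- setdiff(exclude, pairs$pair_id)
  if (length(unknown) > 0) {
    kelp_stop("kelp_label_error", "exclude lists unknown pair id(s): %s",
              paste(unknown, collapse = ", "))
  }
  fit_one <- function(df) {
    if (nrow(df) < 4) {
      kelp_stop("kelp_parameter_error",
                "need >= 4 pairs for the regression (have %d)", nrow(df))
    }
    y <- as.numeric(df$disjunct)
    X <- cbind("(Intercept)" = 1, max_beach_km = df$max_beach_km,
               coastal_km = df$coastal_km)
    fit <- firth_logistic(y, X, tol = tol, max_iter = max_iter)
    fit$degenerate <- length(unique(y)) == 1
    if (fit$degenerate) {
      kelp_warn("response is constant (all %s): degenerate fit",
                if (y[1] == 1) "disjunct" else "non-disjunct")
    }
    fit
  }
  structure(
    list(pair_table = pairs,
         fit_full = fit_one(pairs),
         fit_excluded = if (length(exclude) > 0)
           fit_one(pairs[!(pairs$pair_id %in% exclude), , drop = FALSE]),
         excluded = exclude),
    class = "disjunction_analysis")
}

#' @export
print.disjunction_analysis <- function(x, ...) {
  cat(sprintf("disjunction_analysis: %d adjacent pairs, %d disjunct\n",
              nrow(x$pair_table), sum(x$pair_table$disjunct)))
  cat("\nFull fit:\n")
  print(x$fit_full)
  if (!is.null(x$fit_excluded)) {
    cat(sprintf("\nExcluding %s:\n", paste(x$excluded, collapse = ", ")))
    print(x$fit_excluded)
  }
  invisible(x)
}
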