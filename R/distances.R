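# Raw pairwise differences, uncorrected p-distances, Nei's raw average
# pairwise difference D between populations, and the pi-based pairwise FST.
#
# D is deliberately left on the raw count scale (number of differing
# sites, not divided by length, no multiple-hit correction): the
# habitat-disjunction classification "D >= 1.0" is only meaningful on that
# scale. Sites where either sequence carries a gap or an ambiguity code
# are excluded from all comparisons.

ACGT_INT <- utf8ToInt("ACGT")

seq_ints <- function(s) utf8ToInt(toupper(s))

#' Raw pairwise differences between two aligned sequences
#'
#' Counts the positions where both sequences carry unambiguous bases
#' (A/C/G/T) and those bases differ.
#'
#' @param seq_a,seq_b equal-length DNA strings.
#' @return integer count of differing comparable sites.
#' @export
#' @examples
#' raw_differences("ACNT", "ACGA")  # 1: site 3 excluded, site 4 differs
raw_differences <- function(seq_a, seq_b) {
  a <- seq_ints(seq_a)
  b <- seq_ints(seq_b)
  if (length(a) != length(b)) {
    kelp_stop("kelp_alignment_error",
              "sequence lengths differ (%d vs %d)", length(a), length(b))
  }
  ok <- (a %in% ACGT_INT) & (b %in% ACGT_INT)
  sum(a[ok] != b[ok])
}

comparable_sites <- function(seq_a, seq_b) {
  a <- seq_ints(seq_a)
  b <- seq_ints(seq_b)
  sum((a %in% ACGT_INT) & (b %in% ACGT_INT))
}

#' Uncorrected p-distance
#'
#' Proportion of comparable (both-unambiguous) sites at which two aligned
#' sequences differ; no multiple-hit correction.
#'
#' @inheritParams raw_differences
#' @return fraction in \[0, 1\].
#' @export
p_distance <- function(seq_a, seq_b) {
  d <- raw_differences(seq_a, seq_b)
  n <- comparable_sites(seq_a, seq_b)
  if (n == 0) {
    kelp_stop("kelp_undefined_distance_error",
              "no comparable sites between sequences")
  }
  d / n
}

# pairwise raw-difference matrix over a set of sequences (small k)
raw_difference_matrix <- function(seqs) {
  k <- length(seqs)
  ints <- lapply(seqs, seq_ints)
  ok <- lapply(ints, function(v) v %in% ACGT_INT)
  m <- matrix(0, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        use <- ok[[i]] & ok[[j]]
        m[i, j] <- m[j, i] <- sum(ints[[i]][use] != ints[[j]][use])
      }
    }
  }
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

# unique sequences + multiplicities, for frequency-weighted sums
weighted_unique <- function(pop) {
  u <- unique(pop)
  list(seqs = u, w = tabulate(match(pop, u), nbins = length(u)))
}

#' Nei's raw average pairwise difference D between two populations
#'
#' Mean raw pairwise difference over all between-population sample pairs:
#' `D = (1 / (n_a * n_b)) * sum_{i in a, j in b} raw_differences(i, j)`.
#' Equivalent to the frequency-weighted sum over haplotype pairs.
#'
#' @param pop_a,pop_b non-empty character vectors of aligned sequences
#'   (one element per sampled individual).
#' @return non-negative real.
#' @export
nei_average_pairwise_D <- function(pop_a, pop_b) {
  if (length(pop_a) == 0 || length(pop_b) == 0) {
    kelp_stop("kelp_empty_input_error", "both populations must be non-empty")
  }
  ua <- weighted_unique(pop_a)
  ub <- weighted_unique(pop_b)
  m <- matrix(0, length(ua$seqs), length(ub$seqs))
  for (i in seq_along(ua$seqs)) {
    for (j in seq_along(ub$seqs)) {
      m[i, j] <- raw_differences(ua$seqs[i], ub$seqs[j])
    }
  }
  sum(ua$w * m %*% ub$w) / (length(pop_a) * length(pop_b))
}

# mean raw difference over distinct unordered within-population pairs,
# n(n-1)/2 denominator; a single-sequence population has pi = 0
pi_within <- function(pop) {
  n <- length(pop)
  if (n < 2) return(0)
  u <- weighted_unique(pop)
  m <- raw_difference_matrix(u$seqs)
  sum(u$w * m %*% u$w) / (n * (n - 1))  # w'Mw double-counts, /2 twice
}

#' Pairwise pi-based FST between two populations
#'
#' `FST = (pi_between - mean(pi_within_a, pi_within_b)) / pi_between`,
#' with `pi_between` Nei's raw D and the within terms the mean raw
#' difference over distinct sample pairs, clamped to \[0, 1\]. Two
#' populations fixed for different haplotypes give FST = 1; when
#' `pi_between = 0` FST is undefined and returned as `NA` with
#' `defined = FALSE`.
#'
#' @inheritParams nei_average_pairwise_D
#' @return a `pop_pair_stats` list: `pi_between`, `pi_within_a`,
#'   `pi_within_b`, `fst`, `defined`.
#' @export
pairwise_fst <- function(pop_a, pop_b) {
  if (length(pop_a) == 0 || length(pop_b) == 0) {
    kelp_stop("kelp_empty_input_error", "both populations must be non-empty")
  }
  d <- nei_average_pairwise_D(pop_a, pop_b)
  pa <- pi_within(pop_a)
  pb <- pi_within(pop_b)
  if (d == 0) {
    fst <- NA_real_
    defined <- FALSE
  } else {
    fst <- min(1, max(0, (d - mean(c(pa, pb))) / d))
    defined <- TRUE
  }
  structure(list(pi_between = d, pi_within_a = pa, pi_within_b = pb,
                 fst = fst, defined = defined),
            class = "pop_pair_stats")
}

#' @export
print.pop_pair_stats <- function(x, ...) {
  cat(sprintf("pi_between (D) = %.4g; pi_within = %.4g / %.4g; FST = %s\n",
              x$pi_between, x$pi_within_a, x$pi_within_b,
              if (x$defined) sprintf("%.4g", x$fst) else "undefined"))
  invisible(x)
}

# labeled symmetric matrix with a kind tag
distance_matrix <- function(values, kind) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(values < 0) || any(abs(diag(values)) > 1e-12) ||
      any(abs(values - t(values)) > 1e-9)) {
    kelp_stop("kelp_format_error",
              "distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  structure(values, kind = kind, class = c("kelp_dist", "matrix"))
}

#' Between-population distance matrix of Nei's raw D
#'
#' Computes `nei_average_pairwise_D` for every locality pair of a
#' haplotype table, weighting haplotypes by their per-locality counts.
#' Localities with zero samples are dropped with a warning.
#'
#' @param ht a `haplotype_table` covering at least 2 localities.
#' @param kind matrix kind tag; `"genetic_D"`.
#' @return a `kelp_dist` labeled symmetric matrix.
#' @export
population_distance_matrix <- function(ht, kind = "genetic_D") {
  stopifnot(inherits(ht, "haplotype_table"))
  kind <- match.arg(kind)
  counts <- ht$counts
  n <- rowSums(counts)
  if (any(n == 0)) {
    kelp_warn("dropping zero-sample localities: %s",
              paste(rownames(counts)[n == 0], collapse = ", "))
    counts <- counts[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  if (nrow(counts) < 2) {
    kelp_stop("kelp_parameter_error",
              "need >= 2 localities with samples (have %d)", nrow(counts))
  }
  m <- raw_difference_matrix(ht$haplotype_seqs)
  d <- (counts %*% m %*% t(counts)) / outer(n, n)
  diag(d) <- 0
  distance_matrix(unclass(d), kind)
}

#' Coastal distance matrix from a locality table
#'
#' Entry (i, j) is the absolute difference of the cumulative coastal
#' positions. Positions must be non-decreasing in coastal order.
#'
#' @param locality_table data.frame with `locality` and
#'   `coastal_position_km`, ordered along the coast (or carrying
#'   `order_index`).
#' @return a `kelp_dist` matrix of kind `"coastal_km"`, labels in coastal
#'   order.
#' @export
coastal_distance_matrix <- function(locality_table) {
  lt <- locality_table
  if (!is.null(lt$order_index)) lt <- lt[order(lt$order_index), , drop = FALSE]
  pos <- lt$coastal_position_km
  if (is.unsorted(pos)) {
    kelp_stop("kelp_ordering_error",
              "coastal_position_km must be non-decreasing in coastal order")
  }
  d <- abs(outer(pos, pos, "-"))
  dimnames(d) <- list(lt$locality, lt$locality)
  distance_matrix(d, "coastal_km")
}

#' Write a labeled distance matrix
#'
#' @param mat a `kelp_dist` or plain labeled square matrix.
#' @param path output path.
#' @param format `"tsv"` (labeled, with a leading label column) or
#'   `"phylip"` (square PHYLIP).
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(mat, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(label = rownames(mat), as.data.frame(unclass(mat),
                                                          check.names = FALSE))
    write_tsv(df, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(mat)), con)
    for (i in seq_len(nrow(mat))) {
      writeLines(paste(formatC(rownames(mat)[i], width = -10),
                       paste(formatC(mat[i, ], format = "f", digits = 6),
                             collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a labeled distance matrix written by [write_distance_matrix()]
#' @param path TSV path.
#' @param kind kind tag to attach.
#' @return a `kelp_dist` matrix.
#' @export
read_distance_matrix <- function(path, kind = "genetic_D") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  distance_matrix(m, kind)
}
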