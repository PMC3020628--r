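# Statistical-parsimony haplotype networks: the confidence-based
# connection limit and greedy network assembly with hypothetical
# intermediate nodes.
#
# The connection limit follows the statistical-parsimony idea of
# Templeton, Crandall & Sing: haplotype pairs are joined only when the
# probability that their observed differences arose without superimposed
# or parallel change (i.e. that the minimal connection is the true one) is
# at least the stated confidence. The probability is operationalized with
# a finite-sites Jukes-Cantor model: per-site change counts are Poisson,
# the divergence parameter is calibrated so the expected proportion of
# differing sites matches the observed j/m, and a connection is
# parsimonious when every differing site changed exactly once and every
# identical site never changed.

#' Probability of a parsimonious connection
#'
#' For two sequences of length `seq_length` differing at `j` sites,
#' the probability (under the finite-sites calibration described in the
#' package vignette) that the `j` observed differences reflect exactly
#' `j` substitutions, i.e. that a minimal `j`-step connection is correct.
#'
#' @param j integer vector of observed differences (>= 0).
#' @param seq_length alignment length in bp.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
parsimony_probability <- function(j, seq_length) {
  if (seq_length < 1) {
    kelp_stop("kelp_parameter_error", "seq_length must be >= 1")
  }
  m <- as.numeric(seq_length)
  vapply(as.numeric(j), function(jj) {
    if (jj == 0) return(1)
    if (jj < 0 || jj > m) return(0)
    q <- jj / m
    if (q >= 3 / 4) return(0)
    # q = (3/4)(1 - exp(-4*lambda/3))  =>  per-site expected changes
    lam <- -(3 / 4) * log(1 - 4 * q / 3)
    # differing site changed exactly once; identical site never changed
    lp <- jj * (log(lam) - lam - log(q)) + (m - jj) * (-lam - log1p(-q))
    exp(min(0, lp))
  }, numeric(1))
}

#' Connection limit at a stated confidence
#'
#' The largest number of mutational steps `j` such that
#' `parsimony_probability(j, seq_length) >= confidence`. Haplotype pairs
#' farther apart than this limit are not joined in the network.
#'
#' @param seq_length alignment length in bp (>= 1).
#' @param confidence in (0, 1); the conventional values are 0.95 and 0.90.
#' @return integer number of steps (possibly 0 for extreme inputs).
#' @export
#' @examples
#' connection_limit(629, 0.90)
connection_limit <- function(seq_length, confidence = 0.95) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    kelp_stop("kelp_parameter_error", "confidence must be in (0, 1)")
  }
  if (seq_length < 1) {
    kelp_stop("kelp_parameter_error", "seq_length must be >= 1")
  }
  p <- parsimony_probability(seq_len(seq_length), seq_length)
  ok <- which(p >= confidence)
  if (length(ok) == 0) 0L else max(ok)
}

# breadth-first graph distance over an adjacency list; Inf if unreachable
bfs_distance <- function(adj, from, to) {
  if (from == to) return(0L)
  dist <- rep(NA_integer_, length(adj))
  dist[from] <- 0L
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          if (w == to) return(dist[w])
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

#' Build a statistical-parsimony haplotype network
#'
#' Greedy agglomeration: haplotype pairs are considered in order of
#' increasing raw pairwise differences (ties: higher combined frequency
#' first, then lexicographic IDs). A pair at distance `d <= limit` joining
#' two different components is connected through `d - 1` new hypothetical
#' intermediate nodes (`x1, x2, ...`, unlabeled single steps). A pair
#' already connected whose minimal path equals `d` is recorded as an
#' ambiguous (alternative equal-length) link rather than added as an edge.
#' Pairs beyond the limit never connect.
#'
#' @param ht a `haplotype_table`.
#' @param limit connection limit in mutational steps (>= 1), e.g. from
#'   [connection_limit()].
#' @param confidence optional confidence used to derive `limit`, recorded
#'   on the result.
#' @return a `parsimony_network`: `graph` (igraph, node attributes
#'   `observed` and `frequency`), `nodes`, `edges`, `components` (list of
#'   observed-haplotype ID vectors, ordered by total frequency),
#'   `ambiguous_links`, `connection_limit`, `confidence`.
#' @export
build_network <- function(ht, limit, confidence = NA_real_) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (length(ht$haplotype_ids) < 1) {
    kelp_stop("kelp_empty_input_error", "no haplotypes")
  }
  if (limit < 1) {
    kelp_stop("kelp_parameter_error", "limit must be >= 1")
  }
  ids <- ht$haplotype_ids
  freq <- colSums(ht$counts)[ids]
  k <- length(ids)
  dmat <- raw_difference_matrix(ht$haplotype_seqs)

  # node bookkeeping: observed haplotypes first, hypotheticals appended
  node_id <- ids
  node_obs <- rep(TRUE, k)
  node_freq <- as.numeric(freq)
  comp <- seq_len(k)            # union-find, path-compressed on the fly
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  adj <- vector("list", k)
  edges_a <- character(0)
  edges_b <- character(0)
  amb <- list()
  n_hyp <- 0L

  add_edge <- function(i, j) {
    adj[[i]] <<- c(adj[[i]], j)
    adj[[j]] <<- c(adj[[j]], i)
    edges_a <<- c(edges_a, node_id[i])
    edges_b <<- c(edges_b, node_id[j])
  }

  if (k >= 2) {
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    d <- dmat[pr]
    cf <- freq[pr[, 1]] + freq[pr[, 2]]
    pa <- pmin(ids[pr[, 1]], ids[pr[, 2]])
    pb <- pmax(ids[pr[, 1]], ids[pr[, 2]])
    ord <- order(d, -cf, pa, pb)
    for (row in ord) {
      dd <- d[row]
      if (dd > limit) break
      i <- pr[row, 1]
      j <- pr[row, 2]
      if (dd == 0) next  # cannot occur for a valid haplotype table
      if (find(i) != find(j)) {
        prev <- i
        if (dd > 1) {
          for (s in seq_len(dd - 1)) {
            n_hyp <- n_hyp + 1L
            node_id <- c(node_id, paste0("x", n_hyp))
            node_obs <- c(node_obs, FALSE)
            node_freq <- c(node_freq, 0)
            comp <- c(comp, length(node_id))
            adj[[length(node_id)]] <- integer(0)
            add_edge(prev, length(node_id))
            comp[find(length(node_id))] <- find(prev)
            prev <- length(node_id)
          }
        }
        add_edge(prev, j)
        comp[find(j)] <- find(prev)
      } else {
        gd <- bfs_distance(adj, i, j)
        if (is.finite(gd) && gd == dd) {
          amb[[length(amb) + 1]] <- data.frame(
            haplotype_a = ids[i], haplotype_b = ids[j], steps = dd)
        }
      }
    }
  }

  nodes <- data.frame(id = node_id, observed = node_obs,
                      frequency = node_freq, stringsAsFactors = FALSE)
  edges <- data.frame(a = edges_a, b = edges_b, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  memb <- igraph::components(g)$membership[node_id]
  obs_comp <- split(ids, memb[ids])
  comp_freq <- vapply(obs_comp, function(h) sum(freq[h]), numeric(1))
  obs_comp <- obs_comp[order(-comp_freq)]
  names(obs_comp) <- NULL

  structure(
    list(graph = g,
         nodes = nodes,
         edges = edges,
         components = obs_comp,
         ambiguous_links = if (length(amb)) do.call(rbind, amb) else
           data.frame(haplotype_a = character(0), haplotype_b = character(0),
                      steps = integer(0)),
         connection_limit = as.integer(limit),
         confidence = confidence),
    class = "parsimony_network")
}

#' Build a network at a stated confidence limit
#'
#' Convenience wrapper deriving the connection limit from the alignment
#' length of the haplotype table.
#'
#' @param ht a `haplotype_table`.
#' @param confidence connection confidence in (0, 1); default 0.95.
#' @return a `parsimony_network` (see [build_network()]).
#' @export
parsimony_network <- function(ht, confidence = 0.95) {
  lim <- connection_limit(ht$seq_length, confidence)
  if (lim < 1) {
    kelp_stop("kelp_parameter_error",
              "connection limit is 0 at confidence %.3g", confidence)
  }
  build_network(ht, lim, confidence = confidence)
}

#' Observed-haplotype subnetworks
#'
#' Connected components of the network restricted to observed haplotypes,
#' ordered by total haplotype frequency (descending).
#'
#' @param net a `parsimony_network`.
#' @return list of character vectors of haplotype IDs.
#' @export
subnetworks <- function(net) {
  stopifnot(inherits(net, "parsimony_network"))
  net$components
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat(sprintf(
    "parsimony_network: %d observed + %d hypothetical nodes, %d edges\n",
    sum(x$nodes$observed), sum(!x$nodes$observed), nrow(x$edges)))
  cat(sprintf("  connection limit %d steps%s; %d subnetwork(s)\n",
              x$connection_limit,
              if (is.na(x$confidence)) "" else
                sprintf(" (%.0f%% confidence)", 100 * x$confidence),
              length(x$components)))
  invisible(x)
}

#' Export a parsimony network
#'
#' Writes GraphML, a node table, an edge table and a components JSON into
#' a directory.
#'
#' @param net a `parsimony_network`.
#' @param dir output directory (created if absent).
#' @param basename file stem, default `"network"`.
#' @return named character vector of the four paths, invisibly.
#' @export
write_network <- function(net, dir, basename = "network") {
  stopifnot(inherits(net, "parsimony_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    graphml = file.path(dir, paste0(basename, ".graphml")),
    nodes = file.path(dir, paste0(basename, "_nodes.tsv")),
    edges = file.path(dir, paste0(basename, "_edges.tsv")),
    components = file.path(dir, paste0(basename, "_components.json")))
  igraph::write_graph(net$graph, paths[["graphml"]], format = "graphml")
  write_tsv(net$nodes, paths[["nodes"]])
  write_tsv(net$edges, paths[["edges"]])
  jsonlite::write_json(net$components, paths[["components"]])
  invisible(paths)
}
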