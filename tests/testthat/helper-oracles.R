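# Independent oracles, deliberately coded from first principles with
# different numerics than the package (loops instead of matrix algebra,
# root-finding instead of closed forms, exhaustive enumeration instead of
# sampling).

# --- raw-difference / D / pi / FST oracles: direct pair enumeration ----

oracle_diff <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[keep] != cb[keep])
}

oracle_D <- function(pop_a, pop_b) {
  tot <- 0
  for (a in pop_a) for (b in pop_b) tot <- tot + oracle_diff(a, b)
  tot / (length(pop_a) * length(pop_b))
}

oracle_pi <- function(pop) {
  n <- length(pop)
  if (n < 2) return(0)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + oracle_diff(pop[i], pop[j])
  }
  tot / (n * (n - 1) / 2)
}

oracle_fst <- function(pop_a, pop_b) {
  D <- oracle_D(pop_a, pop_b)
  if (D == 0) return(NA_real_)
  max(0, min(1, (D - (oracle_pi(pop_a) + oracle_pi(pop_b)) / 2) / D))
}

# --- exhaustive permutation enumeration for the Mantel test -----------

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# exact upper-tail p over all joint row/column permutations of `gen`
oracle_mantel_exact_p <- function(gen, geo) {
  ut <- upper.tri(gen)
  y <- geo[ut]
  r_obs <- cor(gen[ut], y)
  rs <- vapply(all_perms(seq_len(nrow(gen))),
               function(idx) cor(gen[idx, idx][ut], y), numeric(1))
  mean(rs >= r_obs)
}

# --- parsimony-probability recursion oracle (root-finding route) ------

oracle_parsimony_prob <- function(j, m) {
  if (j == 0) return(1)
  qobs <- j / m
  if (qobs >= 0.75) return(0)
  lam <- uniroot(function(l) (3 / 4) * (1 - exp(-4 * l / 3)) - qobs,
                 c(1e-12, 60), tol = 1e-14)$root
  p_diff_once <- dpois(1, lam) / qobs
  p_same_none <- dpois(0, lam) / (1 - qobs)
  exp(j * log(p_diff_once) + (m - j) * log(p_same_none))
}

oracle_connection_limit <- function(m, conf) {
  j <- 0
  while (j < m && oracle_parsimony_prob(j + 1, m) >= conf) j <- j + 1
  j
}

# --- Firth penalized-likelihood grid-search oracle (2 parameters) -----

oracle_firth_pll <- function(b0, b1, y, x) {
  eta <- b0 + b1 * x
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  a11 <- sum(w)
  a12 <- sum(w * x)
  a22 <- sum(w * x^2)
  sum(y * eta - log(1 + exp(eta))) + 0.5 * log(a11 * a22 - a12^2)
}

oracle_firth_grid <- function(y, x) {
  center <- c(0, 0)
  for (step in c(0.5, 0.05, 0.005, 5e-4, 5e-5)) {
    reach <- if (step == 0.5) 16 else 12   # first level spans +/- 8
    g0 <- center[1] + step * (-reach:reach)
    g1 <- center[2] + step * (-reach:reach)
    best <- -Inf
    for (b0 in g0) for (b1 in g1) {
      v <- oracle_firth_pll(b0, b1, y, x)
      if (v > best) {
        best <- v
        center <- c(b0, b1)
      }
    }
  }
  center
}

# --- network component oracle: transitive closure over the limit ------

oracle_components <- function(seqs, ids, limit) {
  k <- length(seqs)
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (oracle_diff(seqs[i], seqs[j]) <= limit && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonical_partition(split(ids, comp))
}

# canonical form of a partition (sorted members, sorted blocks)
canonical_partition <- function(blocks) {
  blocks <- lapply(blocks, sort)
  names(blocks) <- NULL
  blocks[order(vapply(blocks, `[`, "", 1))]
}
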