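# Seeded synthetic-coast generator.
#
# A forward haplotype-pool model (not a coalescent): it plants exactly
# the three signals the pipeline is meant to recover -- a deeply
# divergent, monomorphic southern clade; an isolation-by-distance
# gradient among northern localities (a stepping-stone mutation walk);
# and beach-length barriers across which haplotype pools are disjoint.
# All mutations are placed at previously untouched sites, so raw
# distances are additive along the walk and every planted signal has a
# closed-form expectation.

#' Synthetic-coast simulation configuration
#'
#' Defaults describe the emulated study system: a 629 bp mitochondrial
#' fragment, 16 northern (structured) and 5 southern (monomorphic)
#' localities 90 km apart with 8 samples each, ~5% between-clade
#' divergence, at most 8 isolation-by-distance mutation steps across the
#' northern walk, beach lengths drawn from a short/long mixture
#' (U(0, 15) km with probability `1 - long_beach_prob`, U(25, 70) km
#' otherwise), and a 20 km barrier threshold beyond which adjacent
#' localities draw from disjoint haplotype pools.
#'
#' @param seq_length fragment length, bp.
#' @param n_localities_north,n_localities_south locality counts.
#' @param samples_per_locality samples per locality.
#' @param between_clade_divergence expected per-site divergence between
#'   the clade ancestors; the realized step count is Binomial(seq_length,
#'   this).
#' @param max_within_clade_steps cap on isolation-by-distance mutation
#'   steps accumulated along the northern walk (barrier jumps are
#'   separate).
#' @param locality_spacing_km mean coastal spacing between consecutive
#'   localities.
#' @param spacing_jitter_km half-width of the uniform jitter on each
#'   spacing, so coastal distance varies between pairs; the jittered
#'   minimum must still exceed the longest possible beach.
#' @param long_beach_prob mixture weight of long beaches.
#' @param short_beach_range,long_beach_range uniform ranges (km) of the
#'   beach-length mixture components.
#' @param barrier_threshold_km beaches longer than this act as barriers.
#' @param barrier_steps fixed mutations planted across each barrier
#'   (guarantees cross-barrier D of at least this many steps).
#' @param ibd_step_prob per-boundary probability that one new mutation
#'   enters the next locality's pool.
#' @param carryover_prob per-sample probability of carrying the previous
#'   locality's haplotype across a non-barrier boundary (shared
#'   haplotypes between neighbours).
#' @param private_mutation_prob per-sample probability of one private
#'   mutation.
#' @param transition_prob probability a mutation is a transition
#'   (default 0.9, i.e. ts:tv 9:1).
#' @param seed integer seed; generation is deterministic given the
#'   config.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seq_length = 629,
                       n_localities_north = 16,
                       n_localities_south = 5,
                       samples_per_locality = 8,
                       between_clade_divergence = 0.05,
                       max_within_clade_steps = 8,
                       locality_spacing_km = 90,
                       spacing_jitter_km = 15,
                       long_beach_prob = 0.3,
                       short_beach_range = c(0, 15),
                       long_beach_range = c(25, 70),
                       barrier_threshold_km = 20,
                       barrier_steps = 3,
                       ibd_step_prob = 0.5,
                       carryover_prob = 0.3,
                       private_mutation_prob = 0.1,
                       transition_prob = 0.9,
                       seed = 1) {
  cfg <- list(seq_length = as.integer(seq_length),
              n_localities_north = as.integer(n_localities_north),
              n_localities_south = as.integer(n_localities_south),
              samples_per_locality = as.integer(samples_per_locality),
              between_clade_divergence = between_clade_divergence,
              max_within_clade_steps = as.integer(max_within_clade_steps),
              locality_spacing_km = locality_spacing_km,
              spacing_jitter_km = spacing_jitter_km,
              long_beach_prob = long_beach_prob,
              short_beach_range = short_beach_range,
              long_beach_range = long_beach_range,
              barrier_threshold_km = barrier_threshold_km,
              barrier_steps = as.integer(barrier_steps),
              ibd_step_prob = ibd_step_prob,
              carryover_prob = carryover_prob,
              private_mutation_prob = private_mutation_prob,
              transition_prob = transition_prob,
              seed = as.integer(seed))
  if (cfg$seq_length < 1 ||
      cfg$between_clade_divergence <= 0 || cfg$between_clade_divergence >= 1 ||
      cfg$max_within_clade_steps > cfg$seq_length ||
      cfg$max_within_clade_steps < 0 ||
      cfg$n_localities_north < 2 || cfg$n_localities_south < 1 ||
      cfg$samples_per_locality < 1 ||
      cfg$long_beach_prob < 0 || cfg$long_beach_prob > 1 ||
      cfg$ibd_step_prob < 0 || cfg$ibd_step_prob > 1 ||
      cfg$carryover_prob < 0 || cfg$carryover_prob > 1 ||
      cfg$private_mutation_prob < 0 || cfg$private_mutation_prob > 1 ||
      cfg$transition_prob < 0 || cfg$transition_prob > 1 ||
      cfg$barrier_steps < 1 || cfg$spacing_jitter_km < 0 ||
      max(cfg$long_beach_range) >
        cfg$locality_spacing_km - cfg$spacing_jitter_km) {
    kelp_stop("kelp_config_error", "invalid simulation configuration")
  }
  # worst-case distinct mutated sites must fit in the fragment
  worst <- ceiling(cfg$seq_length * cfg$between_clade_divergence + 6 *
                     sqrt(cfg$seq_length * cfg$between_clade_divergence)) +
    cfg$max_within_clade_steps +
    cfg$barrier_steps * (cfg$n_localities_north - 1) +
    cfg$samples_per_locality * cfg$n_localities_north
  if (worst > cfg$seq_length) {
    kelp_stop("kelp_config_error",
              "seq_length too short for the configured mutation load")
  }
  structure(cfg, class = "sim_config")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# substitute the bases at `positions` (vector of distinct sites)
mutate_at <- function(chars, positions, transition_prob) {
  for (p in positions) {
    base <- chars[p]
    chars[p] <- if (stats::runif(1) < transition_prob) {
      TRANSITION_OF[[base]]
    } else {
      sample(TRANSVERSIONS_OF[[base]], 1)
    }
  }
  chars
}

#' Mutate a sequence by exactly n distinct steps
#'
#' Changes exactly `n_steps` positions, drawn without replacement, each
#' to a different base (transition with probability `transition_prob`,
#' otherwise a uniformly chosen transversion). Uses the current RNG
#' stream.
#'
#' @param seq DNA string (A/C/G/T).
#' @param n_steps number of positions to change (0..nchar(seq)).
#' @param transition_prob transition probability per change.
#' @return mutated string with `raw_differences(seq, result) == n_steps`.
#' @export
mutate_sequence <- function(seq, n_steps, transition_prob = 0.9) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (n_steps > length(chars)) {
    kelp_stop("kelp_config_error", "n_steps (%d) exceeds sequence length (%d)",
              n_steps, length(chars))
  }
  if (n_steps == 0) return(seq)
  pos <- sample.int(length(chars), n_steps)
  paste0(mutate_at(chars, pos, transition_prob), collapse = "")
}

# draw the two clade ancestors; returns char vectors and the realized
# between-clade step count (uses current RNG stream)
draw_ancestors <- function(cfg, site_pool) {
  north <- sample(UNAMBIG, cfg$seq_length, replace = TRUE)
  steps <- stats::rbinom(1, cfg$seq_length, cfg$between_clade_divergence)
  pos <- site_pool$take(steps)
  south <- mutate_at(north, pos, cfg$transition_prob)
  list(north = north, south = south, divergence_steps = steps)
}

# allocator of never-before-mutated sites (keeps the walk additive)
new_site_pool <- function(n_sites) {
  avail <- sample.int(n_sites)   # pre-shuffled so take() is O(k)
  used <- 0L
  list(take = function(k) {
    if (k == 0) return(integer(0))
    if (used + k > n_sites) {
      kelp_stop("kelp_config_error", "mutation site pool exhausted")
    }
    out <- avail[(used + 1L):(used + k)]
    used <<- used + k
    out
  })
}

#' Generate a synthetic coastal dataset
#'
#' Deterministic given `cfg$seed`. Produces an aligned FASTA-equivalent
#' labeled alignment, sample/locality/beach tables, and a truth record of
#' the planted quantities (clade membership, barrier pairs, divergence
#' steps) for recovery tests. When `dir` is given the five files
#' (`alignment.fasta`, `samples.tsv`, `localities.tsv`, `beaches.tsv`,
#' `truth.json`) are also written, byte-identically for identical seeds.
#'
#' @param cfg a `sim_config`.
#' @param dir optional output directory.
#' @return list with `alignment` (a `labeled_alignment`), `sample_table`,
#'   `locality_table`, `beach_table`, `truth`, and `files` (named paths
#'   or `NULL`).
#' @export
generate_dataset <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- with_seed(cfg$seed, generate_dataset_impl(cfg))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(alignment = file.path(dir, "alignment.fasta"),
               samples = file.path(dir, "samples.tsv"),
               localities = file.path(dir, "localities.tsv"),
               beaches = file.path(dir, "beaches.tsv"),
               truth = file.path(dir, "truth.json"))
    aln_mat <- do.call(rbind, strsplit(unname(out$alignment$sequences), ""))
    rownames(aln_mat) <- out$alignment$sample_ids
    ape::write.FASTA(ape::as.DNAbin(aln_mat), files[["alignment"]])
    write_tsv(out$sample_table, files[["samples"]])
    write_tsv(out$locality_table, files[["localities"]])
    write_tsv(out$beach_table, files[["beaches"]])
    jsonlite::write_json(out$truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}

generate_dataset_impl <- function(cfg) {
  nN <- cfg$n_localities_north
  nS <- cfg$n_localities_south
  S <- cfg$samples_per_locality
  pool <- new_site_pool(cfg$seq_length)
  anc <- draw_ancestors(cfg, pool)

  north_names <- sprintf("N%02d", seq_len(nN))
  south_names <- sprintf("S%02d", seq_len(nS))
  localities <- c(north_names, south_names)
  spacing <- cfg$locality_spacing_km +
    stats::runif(length(localities) - 1, -cfg$spacing_jitter_km,
                 cfg$spacing_jitter_km)
  positions <- round(c(0, cumsum(spacing)), 3)

  # beaches between consecutive northern localities; long => barrier
  is_long <- stats::runif(nN - 1) < cfg$long_beach_prob
  beach <- ifelse(is_long,
                  stats::runif(nN - 1, cfg$long_beach_range[1],
                               cfg$long_beach_range[2]),
                  stats::runif(nN - 1, cfg$short_beach_range[1],
                               cfg$short_beach_range[2]))
  barrier <- beach > cfg$barrier_threshold_km

  # stepping-stone walk of locality haplotypes
  hap <- vector("list", nN)
  hap[[1]] <- anc$north
  drift_used <- 0L
  for (i in 2:nN) {
    if (barrier[i - 1]) {
      hap[[i]] <- mutate_at(hap[[i - 1]], pool$take(cfg$barrier_steps),
                            cfg$transition_prob)
    } else if (drift_used < cfg$max_within_clade_steps &&
               stats::runif(1) < cfg$ibd_step_prob) {
      hap[[i]] <- mutate_at(hap[[i - 1]], pool$take(1L), cfg$transition_prob)
      drift_used <- drift_used + 1L
    } else {
      hap[[i]] <- hap[[i - 1]]
    }
  }

  seqs <- character(0)
  ids <- character(0)
  locs <- character(0)
  for (i in seq_len(nN)) {
    for (s in seq_len(S)) {
      carry <- i > 1 && !barrier[i - 1] &&
        stats::runif(1) < cfg$carryover_prob
      chars <- if (carry) hap[[i - 1]] else hap[[i]]
      if (stats::runif(1) < cfg$private_mutation_prob) {
        chars <- mutate_at(chars, pool$take(1L), cfg$transition_prob)
      }
      seqs <- c(seqs, paste0(chars, collapse = ""))
      ids <- c(ids, sprintf("%s_s%02d", north_names[i], s))
      locs <- c(locs, north_names[i])
    }
  }
  south_seq <- paste0(anc$south, collapse = "")
  for (i in seq_len(nS)) {
    seqs <- c(seqs, rep(south_seq, S))
    ids <- c(ids, sprintf("%s_s%02d", south_names[i], seq_len(S)))
    locs <- c(locs, rep(south_names[i], S))
  }

  sample_table <- data.frame(sample_id = ids, locality = locs,
                             stringsAsFactors = FALSE)
  locality_table <- data.frame(
    locality = localities,
    order_index = seq_along(localities),
    coastal_position_km = positions,
    region = c(rep("north", nN), rep("south", nS)),
    stringsAsFactors = FALSE)
  beach_table <- data.frame(
    locality_a = north_names[-nN],
    locality_b = north_names[-1],
    max_beach_km = round(beach, 3),
    stringsAsFactors = FALSE)

  barrier_ids <- paste(north_names[-nN], north_names[-1],
                       sep = "--")[barrier]
  truth <- list(
    seed = cfg$seed,
    divergence_steps = anc$divergence_steps,
    drift_steps = drift_used,
    clade_of = stats::setNames(c(rep("north", nN), rep("south", nS)),
                               localities),
    north_localities = north_names,
    south_localities = south_names,
    barrier_pairs = barrier_ids,
    planted_disjunct = stats::setNames(
      barrier, paste(north_names[-nN], north_names[-1], sep = "--")))

  aln <- labeled_alignment(
    gene_name = "COI_sim",
    sample_ids = ids,
    sequences = seqs,
    locality_of = stats::setNames(locs, ids))

  list(alignment = aln, sample_table = sample_table,
       locality_table = locality_table, beach_table = beach_table,
       truth = truth, files = NULL)
}
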