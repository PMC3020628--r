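# End-to-end orchestration: haplotypes -> distances -> Mantel ->
# parsimony network -> disjunction regression, with all stage outputs
# written to disk and a single machine-readable report.

#' Pipeline run configuration
#'
#' @param fasta,sample_table,locality_table paths to the aligned FASTA,
#'   sample TSV and locality TSV.
#' @param beach_table optional path to the adjacent-pair beach TSV;
#'   required when the disjunction stage is enabled.
#' @param gene_name fragment name.
#' @param frame_offset reading-frame offset (0/1/2) for codon positions.
#' @param mantel_permutations,seed Mantel permutation count and seed.
#' @param network_confidence confidence for the connection limit.
#' @param disjunction_threshold raw-D disjunction threshold.
#' @param exclude pair IDs excluded in the secondary disjunction fit.
#' @param region optional character vector of locality names restricting
#'   the Mantel and disjunction stages (e.g. the unglaciated part of a
#'   coast); `NULL` uses all localities.
#' @param out_dir output directory, created if absent.
#' @param run_disjunction set `FALSE` to skip the disjunction stage when
#'   no beach data exist.
#' @return a validated `run_config`.
#' @export
run_config <- function(fasta, sample_table, locality_table,
                       beach_table = NULL, gene_name = "COI",
                       frame_offset = 0, mantel_permutations = 999,
                       seed = 1, network_confidence = 0.90,
                       disjunction_threshold = 1.0,
                       exclude = character(), region = NULL,
                       out_dir = tempfile("kelpcoast_run_"),
                       run_disjunction = TRUE) {
  cfg <- list(fasta = fasta, sample_table = sample_table,
              locality_table = locality_table, beach_table = beach_table,
              gene_name = gene_name, frame_offset = frame_offset,
              mantel_permutations = mantel_permutations,
              seed = as.integer(seed),
              network_confidence = network_confidence,
              disjunction_threshold = disjunction_threshold,
              exclude = exclude, region = region, out_dir = out_dir,
              run_disjunction = isTRUE(run_disjunction))
  for (p in c(cfg$fasta, cfg$sample_table, cfg$locality_table,
              cfg$beach_table)) {
    if (!is.null(p) && !file.exists(p)) {
      kelp_stop("kelp_config_error", "input file does not exist: %s", p)
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys are the arguments of [run_config()].
#'
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    kelp_stop("kelp_stage_error", "[%s] %s", stage, conditionMessage(e))
  })
}

#' Run the full phylogeographic pipeline
#'
#' Executes sequence input -> haplotype collapsing and site summary ->
#' genetic-D and coastal distance matrices -> Mantel isolation-by-distance
#' test -> statistical-parsimony network -> disjunction classification
#' and Firth regression, writing every stage's output plus a single
#' `report.json` (timestamp-free: identical configs give byte-identical
#' reports) and a `log.txt` with versions and seeds. Any stage failure
#' aborts with a stage-tagged `kelp_stage_error`.
#'
#' @param cfg a `run_config`.
#' @return the report, invisibly (class `kelp_report`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  aln <- stage_call("seqio", read_alignment(cfg$fasta, cfg$sample_table,
                                            cfg$gene_name))
  ht <- stage_call("seqio", collapse_haplotypes(aln))
  ss <- stage_call("seqio", site_summary(ht, cfg$frame_offset))
  write_haplotype_table(ht, file.path(cfg$out_dir, "haplotypes.tsv"))
  write_site_summary(ss, file.path(cfg$out_dir, "site_summary.tsv"))

  lt <- stage_call("distances", read_locality_table(cfg$locality_table))
  d_all <- stage_call("distances", population_distance_matrix(ht))
  write_distance_matrix(d_all, file.path(cfg$out_dir, "genetic_D.tsv"))

  region <- cfg$region %||% lt$locality
  lt_region <- lt[lt$locality %in% region, , drop = FALSE]
  geo <- stage_call("distances", coastal_distance_matrix(lt_region))
  write_distance_matrix(geo, file.path(cfg$out_dir, "coastal_km.tsv"))
  d_region <- d_all[lt_region$locality, lt_region$locality]
  mant <- stage_call("mantel",
                     mantel_test(distance_matrix(d_region, "genetic_D"), geo,
                                 n_permutations = cfg$mantel_permutations,
                                 seed = cfg$seed))

  net <- stage_call("network", parsimony_network(ht, cfg$network_confidence))
  write_network(net, cfg$out_dir)

  hap_p <- raw_difference_matrix(ht$haplotype_seqs) / ht$seq_length
  divergence <- if (length(ht$haplotype_ids) >= 2) {
    up <- hap_p[upper.tri(hap_p)]
    c(min = round_half_up(100 * min(up), 1),
      max = round_half_up(100 * max(up), 1))
  } else c(min = 0, max = 0)

  disj <- NULL
  if (cfg$run_disjunction) {
    if (is.null(cfg$beach_table)) {
      kelp_stop("kelp_stage_error",
                "[disjunction] beach table required but not configured")
    }
    beaches <- stage_call("disjunction", read_beach_table(cfg$beach_table))
    pairs <- stage_call("disjunction",
                        adjacent_pairs(lt, beaches, region = region))
    pairs <- stage_call("disjunction",
                        classify_disjunct(pairs, d_all, ht,
                                          cfg$disjunction_threshold))
    disj <- stage_call("disjunction",
                       disjunction_analysis(pairs, exclude = cfg$exclude))
    write_tsv(pairs, file.path(cfg$out_dir, "pairs.tsv"))
  }

  fit_block <- function(f) if (is.null(f)) NULL else list(
    coefficients = as.list(f$coefficients),
    standard_errors = as.list(f$standard_errors),
    p_values = as.list(f$p_values),
    n = f$n, converged = f$converged,
    degenerate = isTRUE(f$degenerate))

  report <- list(
    gene = cfg$gene_name,
    seqio = list(n_samples = length(aln$sample_ids),
                 n_localities = nrow(ht$counts),
                 alignment_length = aln$length,
                 n_haplotypes = length(ht$haplotype_ids),
                 n_variable_sites = ss$n_variable),
    distances = list(divergence_percent = as.list(divergence),
                     n_localities_region = nrow(lt_region)),
    mantel = list(r = mant$r, p_value = mant$p_value,
                  n_permutations = mant$n_permutations, seed = cfg$seed),
    network = list(connection_limit = net$connection_limit,
                   confidence = cfg$network_confidence,
                   n_subnetworks = length(net$components),
                   components = net$components),
    disjunction = if (is.null(disj)) NULL else list(
      n_pairs = nrow(disj$pair_table),
      n_disjunct = sum(disj$pair_table$disjunct),
      threshold = cfg$disjunction_threshold,
      fit_full = fit_block(disj$fit_full),
      fit_excluded = fit_block(disj$fit_excluded),
      excluded = cfg$exclude))

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("kelpcoast %s on R %s.%s",
                       as.character(utils::packageVersion("kelpcoast")),
                       R.version$major, R.version$minor),
               sprintf("seed: %d", cfg$seed),
               sprintf("inputs: %s", paste(c(cfg$fasta, cfg$sample_table,
                                             cfg$locality_table,
                                             cfg$beach_table),
                                           collapse = ", "))),
             file.path(cfg$out_dir, "log.txt"))
  invisible(structure(report, class = "kelp_report"))
}

#' @export
print.kelp_report <- function(x, ...) {
  cat(sprintf("kelpcoast report: %s\n", x$gene))
  cat(sprintf("  %d samples, %d haplotypes, %d variable sites / %d bp\n",
              x$seqio$n_samples, x$seqio$n_haplotypes,
              x$seqio$n_variable_sites, x$seqio$alignment_length))
  cat(sprintf("  haplotype divergence %.1f - %.1f%%\n",
              x$distances$divergence_percent$min,
              x$distances$divergence_percent$max))
  cat(sprintf("  Mantel r = %.3f, P = %.4g (%d permutations)\n",
              x$mantel$r, x$mantel$p_value, x$mantel$n_permutations))
  cat(sprintf("  network: %d subnetwork(s) at limit %d steps\n",
              x$network$n_subnetworks, x$network$connection_limit))
  if (!is.null(x$disjunction)) {
    cat(sprintf("  disjunction: %d of %d adjacent pairs (beach beta = %.3g, P = %.3g)\n",
                x$disjunction$n_disjunct, x$disjunction$n_pairs,
                x$disjunction$fit_full$coefficients$max_beach_km,
                x$disjunction$fit_full$p_values$max_beach_km))
  }
  invisible(x)
}
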