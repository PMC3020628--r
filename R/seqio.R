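# Alignment input, haplotype collapsing and variable-site summaries.
#
# Sequences are handled as uppercase character strings over the IUPAC
# nucleotide alphabet plus '-' (gap) and 'N'. Positions are 1-based on the
# trimmed fragment. Only unambiguous A/C/G/T states carry information:
# positions where any haplotype holds a gap or an ambiguity code are
# excluded from variable-site and distance computations (the conservative
# convention for clean Sanger haplotype data).

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")
UNAMBIG <- c("A", "C", "G", "T")

#' Read a labeled alignment from FASTA plus a sample table
#'
#' Reads a pre-aligned FASTA file (equal-length IUPAC DNA) and a
#' tab-separated sample table with columns `sample_id` and `locality`, and
#' returns a validated `labeled_alignment`. Every FASTA record ID must
#' appear in the sample table.
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param sample_table_path path to a TSV with columns `sample_id`,
#'   `locality`.
#' @param gene_name name of the gene/fragment (e.g. `"COI"`).
#' @return A `labeled_alignment`: list with `gene_name`, `sample_ids`,
#'   `sequences` (named uppercase strings), `locality_of` (named character)
#'   and `length` (alignment length in bp).
#' @export
read_alignment <- function(fasta_path, sample_table_path, gene_name) {
  if (!file.exists(fasta_path)) {
    kelp_stop("kelp_format_error", "FASTA file not found: %s", fasta_path)
  }
  recs <- ape::read.FASTA(fasta_path)
  if (length(recs) == 0) {
    kelp_stop("kelp_empty_input_error", "no sequences in %s", fasta_path)
  }
  seqs <- toupper(vapply(as.character(recs), paste0, collapse = "",
                         FUN.VALUE = character(1)))
  tab <- read_tsv_checked(sample_table_path, c("sample_id", "locality"),
                          "sample")
  locality_of <- stats::setNames(as.character(tab$locality),
                                 as.character(tab$sample_id))
  labeled_alignment(gene_name, names(seqs), unname(seqs), locality_of)
}

#' Construct and validate a labeled alignment
#'
#' @param gene_name fragment name.
#' @param sample_ids unique sample identifiers.
#' @param sequences character vector of equal-length IUPAC DNA strings,
#'   parallel to `sample_ids`.
#' @param locality_of named character vector mapping sample IDs to locality
#'   names; must cover every sample.
#' @return a `labeled_alignment` object.
#' @export
labeled_alignment <- function(gene_name, sample_ids, sequences, locality_of) {
  sample_ids <- as.character(sample_ids)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0) {
    kelp_stop("kelp_empty_input_error", "alignment has no sequences")
  }
  if (length(sample_ids) != length(sequences)) {
    kelp_stop("kelp_mapping_error", "%d sample ids for %d sequences",
              length(sample_ids), length(sequences))
  }
  if (anyDuplicated(sample_ids)) {
    kelp_stop("kelp_mapping_error", "duplicate sample ids: %s",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1 || lens[1] == 0) {
    kelp_stop("kelp_alignment_error",
              "sequences are not a single non-zero length (lengths %s)",
              paste(sort(unique(lens)), collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", paste0(IUPAC_CHARS, collapse = "")), sequences)
  if (any(bad)) {
    kelp_stop("kelp_format_error",
              "illegal character in sequence(s): %s",
              paste(sample_ids[bad], collapse = ", "))
  }
  unmapped <- setdiff(sample_ids, names(locality_of))
  if (length(unmapped) > 0) {
    kelp_stop("kelp_mapping_error",
              "sample id(s) missing from sample table: %s",
              paste(unmapped, collapse = ", "))
  }
  structure(
    list(gene_name = gene_name,
         sample_ids = sample_ids,
         sequences = stats::setNames(sequences, sample_ids),
         locality_of = locality_of[sample_ids],
         length = unname(lens[1])),
    class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("labeled_alignment: %s, %d samples x %d bp, %d localities\n",
              x$gene_name, length(x$sample_ids), x$length,
              length(unique(x$locality_of))))
  invisible(x)
}

#' Collapse samples to haplotypes
#'
#' Samples with identical sequences (exact string match after uppercasing)
#' share one haplotype. Haplotype IDs `H1..Hk` are assigned by descending
#' total count, ties broken by first occurrence in the input; IDs are
#' therefore deterministic for a fixed input order, while haplotype
#' membership and counts are order-invariant.
#'
#' @param aln a `labeled_alignment`.
#' @return a `haplotype_table`: `haplotype_ids`, `haplotype_seqs` (named
#'   character), `counts` (locality x haplotype integer matrix),
#'   `gene_name`, `seq_length`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  seqs <- unname(aln$sequences)
  if (length(seqs) == 0) {
    kelp_stop("kelp_empty_input_error", "empty alignment")
  }
  uniq <- unique(seqs)
  idx <- match(seqs, uniq)
  totals <- tabulate(idx, nbins = length(uniq))
  ord <- order(-totals, seq_along(uniq))
  uniq <- uniq[ord]
  idx <- match(seqs, uniq)
  ids <- paste0("H", seq_along(uniq))
  locs <- unname(aln$locality_of)
  loc_levels <- unique(locs)
  counts <- table(factor(locs, levels = loc_levels),
                  factor(idx, levels = seq_along(uniq)))
  counts <- matrix(as.integer(counts), nrow = length(loc_levels),
                   dimnames = list(loc_levels, ids))
  structure(
    list(haplotype_ids = ids,
         haplotype_seqs = stats::setNames(uniq, ids),
         counts = counts,
         gene_name = aln$gene_name,
         seq_length = aln$length),
    class = "haplotype_table")
}

#' Attach custom haplotype names
#'
#' Renames haplotypes via a sidecar map, e.g. to attach field-style labels
#' such as `C-I..C-XIV` to the rank-based defaults.
#'
#' @param ht a `haplotype_table`.
#' @param new_names named character vector, `old_id = new_id`; must rename
#'   every haplotype to a unique name.
#' @return the renamed `haplotype_table`.
#' @export
rename_haplotypes <- function(ht, new_names) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (!setequal(names(new_names), ht$haplotype_ids) ||
      anyDuplicated(new_names)) {
    kelp_stop("kelp_mapping_error",
              "new_names must be a one-to-one map over all haplotype ids")
  }
  ids <- unname(new_names[ht$haplotype_ids])
  ht$haplotype_ids <- ids
  names(ht$haplotype_seqs) <- ids
  colnames(ht$counts) <- ids
  ht
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %s, %d haplotypes, %d samples, %d localities\n",
              x$gene_name, length(x$haplotype_ids), sum(x$counts),
              nrow(x$counts)))
  invisible(x)
}

# character matrix (haplotype x position) from a haplotype table
hap_char_matrix <- function(ht) {
  m <- do.call(rbind, strsplit(unname(ht$haplotype_seqs), ""))
  rownames(m) <- ht$haplotype_ids
  m
}

#' Summarize variable sites across haplotypes
#'
#' A site is variable when at least two distinct unambiguous bases occur
#' among the haplotypes; positions where any haplotype carries a gap or an
#' ambiguity code are excluded. Each variable site is classified as a
#' transition (A<->G or C<->T), a transversion, or `complex` when more than
#' two bases occur. Codon positions are `((pos - 1 + frame_offset) mod 3) +
#' 1`; the reading-frame offset is a user input because a trimmed fragment
#' does not carry its frame.
#'
#' @param ht a `haplotype_table` with at least 2 haplotypes.
#' @param frame_offset 0, 1 or 2.
#' @return a `site_summary`: `variable_positions` (1-based),
#'   `codon_position_of`, `substitution_class_of`, `n_variable`,
#'   `frame_offset`, `seq_length`. With fewer than two haplotypes an empty
#'   summary is returned with a warning.
#' @export
site_summary <- function(ht, frame_offset = 0) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (!frame_offset %in% 0:2) {
    kelp_stop("kelp_parameter_error", "frame_offset must be 0, 1 or 2")
  }
  empty <- structure(
    list(variable_positions = integer(0),
         codon_position_of = stats::setNames(integer(0), character(0)),
         substitution_class_of = stats::setNames(character(0), character(0)),
         n_variable = 0L, frame_offset = as.integer(frame_offset),
         seq_length = ht$seq_length),
    class = "site_summary")
  if (length(ht$haplotype_ids) < 2) {
    kelp_warn("fewer than 2 haplotypes; empty site summary")
    return(empty)
  }
  m <- hap_char_matrix(ht)
  usable <- apply(m, 2, function(col) all(col %in% UNAMBIG))
  n_distinct <- integer(ncol(m))
  n_distinct[usable] <- apply(m[, usable, drop = FALSE], 2,
                              function(col) length(unique(col)))
  pos <- which(usable & n_distinct >= 2)
  if (length(pos) == 0) return(empty)
  cls <- vapply(pos, function(p) {
    bases <- sort(unique(m[, p]))
    if (length(bases) > 2) return("complex")
    pair <- paste(bases, collapse = "")
    if (pair %in% c("AG", "CT")) "transition" else "transversion"
  }, character(1))
  codon <- ((pos - 1 + frame_offset) %% 3) + 1
  structure(
    list(variable_positions = pos,
         codon_position_of = stats::setNames(as.integer(codon), pos),
         substitution_class_of = stats::setNames(cls, pos),
         n_variable = length(pos),
         frame_offset = as.integer(frame_offset),
         seq_length = ht$seq_length),
    class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("site_summary: %d variable sites / %d bp (frame offset %d)\n",
              x$n_variable, x$seq_length, x$frame_offset))
  if (x$n_variable > 0) {
    cat("  classes:", paste(names(table(x$substitution_class_of)),
                            table(x$substitution_class_of),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname site_summary
#' @param x a `site_summary`.
#' @param ... unused.
#' @export
as.data.frame.site_summary <- function(x, ...) {
  data.frame(position = x$variable_positions,
             codon_position = unname(x$codon_position_of),
             substitution_class = unname(x$substitution_class_of))
}

#' Write a haplotype table as TSV
#'
#' One row per haplotype: id, sequence, total count, per-locality counts.
#'
#' @param ht a `haplotype_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  df <- data.frame(haplotype_id = ht$haplotype_ids,
                   sequence = unname(ht$haplotype_seqs),
                   total = colSums(ht$counts))
  df <- cbind(df, as.data.frame(t(ht$counts), check.names = FALSE))
  write_tsv(df, path)
}

#' Write a site summary as TSV
#' @param ss a `site_summary`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_site_summary <- function(ss, path) {
  write_tsv(as.data.frame(ss), path)
}

#' Read a locality table
#'
#' Columns `locality`, `order_index` (position along the coast, 1 =
#' northernmost) and `coastal_position_km` (cumulative along-coast
#' distance).
#'
#' @param path TSV path.
#' @return a data.frame ordered by `order_index`.
#' @export
read_locality_table <- function(path) {
  df <- read_tsv_checked(path, c("locality", "order_index",
                                 "coastal_position_km"), "locality")
  df[order(df$order_index), , drop = FALSE]
}

#' Read an adjacent-pair beach table
#'
#' Columns `locality_a`, `locality_b`, `max_beach_km` (maximum
#' uninterrupted beach length between the pair).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_beach_table <- function(path) {
  read_tsv_checked(path, c("locality_a", "locality_b", "max_beach_km"),
                   "beach")
}
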