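# In-code fixtures: tiny alignments, haplotype tables and on-disk files
# built at test time.

rand_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a pair of sequences of length `len` differing at exactly `ndiff` sites
seq_pair_with_diffs <- function(len, ndiff) {
  a <- rand_seq(len)
  b <- mutate_sequence(a, ndiff)
  c(a, b)
}

make_alignment <- function(seqs, locs, gene = "test") {
  ids <- sprintf("s%02d", seq_along(seqs))
  labeled_alignment(gene, ids, seqs, stats::setNames(locs, ids))
}

make_ht <- function(seqs, locs, gene = "test") {
  collapse_haplotypes(make_alignment(seqs, locs, gene))
}

write_fasta_file <- function(seqs, ids, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_sample_table <- function(ids, locs, path) {
  write.table(data.frame(sample_id = ids, locality = locs),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small valid labeled symmetric distance matrix from 1-D positions
dist_from_positions <- function(pos, labels = sprintf("L%d", seq_along(pos))) {
  m <- abs(outer(pos, pos, "-"))
  dimnames(m) <- list(labels, labels)
  m
}

# random symmetric zero-diagonal matrix with the same labels
rand_sym_matrix <- function(n, labels = sprintf("L%d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  m
}
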