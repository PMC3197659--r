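# Shared fixtures: tiny alignments and metadata built in code.

chars <- function(s) strsplit(s, "")[[1]]

# Build a locus_alignment from named sequence strings.
aln_from_strings <- function(seqs, locus = "L1") {
  mat <- do.call(rbind, lapply(seqs, chars))
  rownames(mat) <- names(seqs)
  locus_alignment(locus, mat)
}

md_from_samples <- function(sample_id, species,
                            group = rep("G1", length(sample_id)),
                            individual = NULL) {
  if (is.null(individual)) {
    individual <- stats::ave(seq_along(species), species,
                             FUN = seq_along)
    individual <- sprintf("i%d", individual)
  }
  data.frame(sample_id = sample_id, species = species, group = group,
             individual = individual, stringsAsFactors = FALSE)
}

write_fasta_text <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

# Random aligned pair / alignment generators used across tests.
random_seq <- function(len, gap_prob = 0, ambig_prob = 0,
                       missing_prob = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, len, replace = TRUE)
  if (ambig_prob > 0) {
    amb <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")
    hit <- runif(len) < ambig_prob
    s[hit] <- sample(amb, sum(hit), replace = TRUE)
  }
  if (missing_prob > 0) {
    hit <- runif(len) < missing_prob
    s[hit] <- sample(c("N", "?", "X"), sum(hit), replace = TRUE)
  }
  if (gap_prob > 0) {
    hit <- runif(len) < gap_prob
    s[hit] <- "-"
  }
  s
}

random_alignment <- function(n, len, locus = "L1", ...) {
  mat <- do.call(rbind, lapply(seq_len(n), function(i) random_seq(len, ...)))
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  locus_alignment(locus, mat)
}
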