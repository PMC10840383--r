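# Shared fixtures, built in code at test time.

# brute-force codon expectation oracle built on Biostrings translation,
# independent of the package's own genetic-code table
oracle_codon_expectations <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  mis <- 0L; syn <- 0L
  for (pos in 1:3) for (b in setdiff(bases, substr(codon, pos, pos))) {
    alt <- codon; substr(alt, pos, pos) <- b
    alt_aa <- code[[alt]]
    if (alt_aa == "*") next
    if (alt_aa == aa) syn <- syn + 1L else mis <- mis + 1L
  }
  c(exp_missense = mis, exp_synonymous = syn)
}

# O(n^2) nearest-neighbor oracle over a full distance matrix
oracle_knn <- function(sites, focal_chain, focal_residue, k) {
  fi <- which(sites$chain_id == focal_chain &
                sites$residue_number == focal_residue)
  dm <- as.matrix(dist(sites[, c("x", "y", "z")]))
  d <- dm[fi, ]
  o <- order(d, sites$chain_id, sites$residue_number)
  sites[o[seq_len(min(k, nrow(sites)))], ]
}

# uniform counts exactly proportional to expectations (MTR identically 1)
uniform_counts <- function(cds, mult = 4L) {
  skel <- enumerate_codon_expectations(cds)
  skel$obs_missense <- mult * skel$exp_missense
  skel$obs_synonymous <- mult * skel$exp_synonymous
  skel
}

track_key <- function(s) paste(s$chain_id, s$residue_number, sep = "/")
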