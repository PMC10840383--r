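# Codon-level expected/observed variant accounting and the missense
# tolerance ratio (MTR) over an arbitrary residue set.

#' Standard genetic code
#'
#' Named character vector mapping the 64 codons (DNA alphabet) to one-letter
#' amino-acid codes, with `"*"` for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  # canonical TCAG ordering: first base slowest, third base fastest
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), times = 4),
                   rep(bases, times = 16))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aas, codons)
}

#' Load a coding sequence from FASTA
#'
#' Reads a single-record FASTA file holding an in-frame coding sequence
#' (CDS). A terminal stop codon, if present, is trimmed before codon
#' accounting so that `protein_length` counts amino acids only.
#'
#' @param path Path to a FASTA file with exactly one DNA record.
#' @param gene_id Optional gene identifier; defaults to the FASTA record name.
#' @return A `transcript_cds` object: list with `gene_id`, `sequence`
#'   (stop-trimmed, uppercase), and `protein_length` (codons).
#' @export
read_cds_fasta <- function(path, gene_id = NULL) {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) != 1L)
    stop("expected exactly one FASTA record, found ", length(recs))
  if (is.null(gene_id)) gene_id <- sub("\\s.*$", "", names(recs)[1])
  transcript_cds(gene_id, as.character(recs[[1]]))
}

#' Construct a transcript CDS
#'
#' @param gene_id Gene identifier.
#' @param sequence In-frame DNA coding sequence (A/C/G/T only; a trailing
#'   stop codon is trimmed). Length must be divisible by 3.
#' @return A `transcript_cds` object.
#' @export
transcript_cds <- function(gene_id, sequence) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L)
    stop("non-ACGT character at position ", bad, " in CDS for ", gene_id)
  if (nchar(sequence) %% 3L != 0L)
    stop("CDS length ", nchar(sequence), " not divisible by 3 for ", gene_id)
  code <- genetic_code()
  n_codon <- nchar(sequence) %/% 3L
  if (n_codon == 0L) stop("empty CDS for ", gene_id)
  last <- substr(sequence, 3L * n_codon - 2L, 3L * n_codon)
  if (code[[last]] == "*") {
    sequence <- substr(sequence, 1L, 3L * (n_codon - 1L))
    n_codon <- n_codon - 1L
    if (n_codon == 0L) stop("CDS for ", gene_id, " is a bare stop codon")
  }
  structure(
    list(gene_id = gene_id, sequence = sequence, protein_length = n_codon),
    class = "transcript_cds"
  )
}

#' @export
print.transcript_cds <- function(x, ...) {
  cat("<transcript_cds> ", x$gene_id, ": ", x$protein_length,
      " codons\n", sep = "")
  invisible(x)
}

codon_at <- function(cds, i) substr(cds$sequence, 3L * i - 2L, 3L * i)

#' Enumerate per-codon expected missense/synonymous substitution counts
#'
#' For each codon of a CDS, classifies all nine single-nucleotide
#' substitutions against the standard genetic code. Stop-gaining changes are
#' excluded from both classes; a change away from an encoded amino acid to a
#' different amino acid is missense (this includes stop-loss, were the codon
#' a stop, but stops are trimmed upstream).
#'
#' @param cds A `transcript_cds` object.
#' @return A `codon_counts` data frame with columns `gene_id`, `codon_index`,
#'   `codon`, `aa`, `obs_missense`, `obs_synonymous` (zeroed),
#'   `exp_missense`, `exp_synonymous`.
#' @export
enumerate_codon_expectations <- function(cds) {
  stopifnot(inherits(cds, "transcript_cds"))
  code <- genetic_code()
  tab <- codon_expectation_table(code)
  codons <- substring(cds$sequence,
                      seq(1L, nchar(cds$sequence), by = 3L),
                      seq(3L, nchar(cds$sequence), by = 3L))
  out <- data.frame(
    gene_id = cds$gene_id,
    codon_index = seq_along(codons),
    codon = codons,
    aa = unname(code[codons]),
    obs_missense = 0L,
    obs_synonymous = 0L,
    exp_missense = tab[codons, "exp_missense"],
    exp_synonymous = tab[codons, "exp_synonymous"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("codon_counts", "data.frame")
  out
}

# 64 x 2 matrix of expected missense/synonymous counts per codon
codon_expectation_table <- function(code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  m <- matrix(0L, nrow = length(codons), ncol = 2L,
              dimnames = list(codons, c("exp_missense", "exp_synonymous")))
  for (cd in codons) {
    aa <- code[[cd]]
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- b
        alt_aa <- code[[alt]]
        if (alt_aa == "*") next            # stop-gained: excluded
        if (alt_aa == aa) {
          m[cd, "exp_synonymous"] <- m[cd, "exp_synonymous"] + 1L
        } else {
          m[cd, "exp_missense"] <- m[cd, "exp_missense"] + 1L
        }
      }
    }
  }
  m
}

#' Merge observed variant counts onto the codon expectation skeleton
#'
#' @param table A data frame (or path to a TSV with header) with columns
#'   `gene_id`, `codon_index`, `obs_missense`, `obs_synonymous`.
#' @param cds A `transcript_cds`; codons absent from the table get zero
#'   observed counts.
#' @return A `codon_counts` data frame as from
#'   [enumerate_codon_expectations()] with observed columns filled in.
#' @export
load_observed_counts <- function(table, cds) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.table(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  need <- c("gene_id", "codon_index", "obs_missense", "obs_synonymous")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("variant count table missing columns: ", paste(miss, collapse = ", "))
  skel <- enumerate_codon_expectations(cds)
  table <- table[table$gene_id == cds$gene_id, , drop = FALSE]
  if (nrow(table)) {
    if (any(table$codon_index < 1L | table$codon_index > cds$protein_length))
      stop("codon_index out of range [1, ", cds$protein_length, "] for ",
           cds$gene_id)
    if (anyDuplicated(table$codon_index))
      stop("duplicate codon_index rows for ", cds$gene_id,
           " (no silent summing)")
    if (any(table$obs_missense < 0 | table$obs_synonymous < 0))
      stop("negative observed counts")
    idx <- match(table$codon_index, skel$codon_index)
    skel$obs_missense[idx] <- as.integer(table$obs_missense)
    skel$obs_synonymous[idx] <- as.integer(table$obs_synonymous)
  }
  skel
}

#' Missense tolerance ratio over a residue set
#'
#' MTR = \[observed missense / (observed missense + observed synonymous)\]
#' divided by \[expected missense / (expected missense + expected
#' synonymous)\], with sums taken over the supplied residue set. The score is
#' undefined (`NA`) when no variants are observed or when the expected
#' missense proportion is zero; undefinedness propagates as missing, never as
#' zero (zero means full missense depletion).
#'
#' @param counts A `codon_counts` data frame (any subset of rows; rows may
#'   repeat when windows revisit positions through multiple chains).
#' @return List with `value` (ratio or `NA`), `n_obs` (total observed
#'   variants) and `n_residues` (rows in the set).
#' @export
mtr_over_set <- function(counts) {
  if (NROW(counts) == 0L) stop("empty residue set")
  obs_mis <- sum(counts$obs_missense)
  obs_syn <- sum(counts$obs_synonymous)
  exp_mis <- sum(counts$exp_missense)
  exp_syn <- sum(counts$exp_synonymous)
  n_obs <- obs_mis + obs_syn
  value <- NA_real_
  if (n_obs > 0 && exp_mis > 0) {
    value <- (obs_mis / n_obs) / (exp_mis / (exp_mis + exp_syn))
  }
  list(value = value, n_obs = n_obs, n_residues = NROW(counts))
}
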