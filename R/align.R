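# Global protein alignment (Needleman-Wunsch, affine gaps) and projection
# of gene coding positions onto structure residues, including through a
# homolog alignment.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties under
#' BLOSUM62 (gap open 11, gap extend 1, Gotoh three-state recursion).
#' Traceback ties are broken deterministically: diagonal, then up (gap in
#' `seq_b`), then left.
#'
#' @param seq_a,seq_b Protein sequences (standard 20-letter alphabet plus X).
#' @param gap_open,gap_extend Positive gap penalties; opening a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param submat Substitution matrix; defaults to BLOSUM62 from Biostrings.
#' @return A `pairwise_alignment` object: list with `pairs` (two-column
#'   matrix of aligned 1-based positions, strictly increasing in both),
#'   `score`, and `identity` (matches / aligned pairs).
#' @export
align_proteins <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1,
                           submat = NULL) {
  if (is.null(submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (!length(a) || !length(b)) stop("empty sequence")
  for (nm in list(c("seq_a", "a"), c("seq_b", "b"))) {
    s <- get(nm[2])
    bad <- which(!(s %in% rownames(submat)))
    if (length(bad))
      stop("unknown residue letter '", s[bad[1]], "' at position ", bad[1],
           " in ", nm[1])
  }
  n <- length(a); m <- length(b)
  NEG <- -1e9
  # Gotoh: M = match state, X = gap in b (vertical), Y = gap in a (horizontal)
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  sub <- submat[a, b, drop = FALSE]
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best + sub[i - 1, j - 1]
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback, tie preference: diagonal (M), up (X), left (Y)
  i <- n; j <- m
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                        Y[n + 1, m + 1]))]
  pa <- integer(0); pb <- integer(0)
  while (i > 0 || j > 0) {
    if (i == 0) { state <- "Y" } else if (j == 0) { state <- "X" }
    if (state == "M") {
      pa <- c(i, pa); pb <- c(j, pb)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      from_m <- M[i, j + 1] - gap_open - gap_extend
      from_x <- X[i, j + 1] - gap_extend
      state <- if (from_m >= from_x) "M" else "X"
      i <- i - 1
    } else {
      from_m <- M[i + 1, j] - gap_open - gap_extend
      from_y <- Y[i + 1, j] - gap_extend
      state <- if (from_m >= from_y) "M" else "Y"
      j <- j - 1
    }
  }
  pairs <- cbind(pos_a = pa, pos_b = pb)
  identity <- if (nrow(pairs)) mean(a[pa] == b[pb]) else 0
  structure(list(pairs = pairs, score = score, identity = identity),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", nrow(x$pairs), " aligned pairs, score ",
      x$score, ", identity ", round(x$identity, 3), "\n", sep = "")
  invisible(x)
}

#' Map gene coding positions onto structure residues
#'
#' Projects 1-based protein positions of a gene onto the resolved residues
#' of every chain of a structure. With `alignment = "identity"` a gene
#' position maps to the residue bearing that author number (the convention
#' when structure numbering follows the construct). Otherwise the gene
#' sequence is globally aligned ([align_proteins()]) to each chain's
#' resolved-residue sequence and positions map through aligned pairs;
#' gap columns and unresolved residues yield no entry.
#'
#' @param gene_id Gene identifier carried into the map.
#' @param gene_seq Protein sequence of the gene (needed unless
#'   `alignment = "identity"`).
#' @param sites A `residue_sites` data frame (possibly multi-chain).
#' @param alignment `"identity"`, `"align"`, or a precomputed
#'   `pairwise_alignment` from the gene to a chain sequence (applied to all
#'   chains; only valid for single-chain or identical-chain structures).
#' @param chains Optional character vector restricting which chains to map.
#' @return A `residue_alignment_map`: data frame with columns `gene_id`,
#'   `protein_position`, `chain_id`, `residue_number`; attribute `coverage`
#'   = fraction of gene positions mapped to at least one residue.
#' @export
map_gene_to_structure <- function(gene_id, gene_seq = NULL, sites,
                                  alignment = c("align", "identity"),
                                  chains = NULL) {
  if (!is.null(chains)) sites <- sites[sites$chain_id %in% chains, ]
  if (!nrow(sites)) stop("no sites in requested chains")
  per_chain <- split(sites, sites$chain_id)
  entries <- list()
  for (ch in names(per_chain)) {
    s <- per_chain[[ch]][order(per_chain[[ch]]$residue_number), ]
    if (identical(alignment, "identity") ||
        (is.character(alignment) && alignment[1] == "identity")) {
      if (is.null(gene_seq))
        stop("gene_seq required to bound identity mapping")
      gp <- seq_len(nchar(gene_seq))
      hit <- match(gp, s$residue_number)
      ok <- !is.na(hit)
      entries[[ch]] <- data.frame(
        gene_id = gene_id, protein_position = gp[ok],
        chain_id = ch, residue_number = s$residue_number[hit[ok]],
        stringsAsFactors = FALSE)
    } else {
      aln <- if (inherits(alignment, "pairwise_alignment")) alignment
             else {
               if (is.null(gene_seq)) stop("gene_seq required for alignment mapping")
               align_proteins(gene_seq, paste(s$amino_acid, collapse = ""))
             }
      entries[[ch]] <- data.frame(
        gene_id = gene_id,
        protein_position = aln$pairs[, 1],
        chain_id = ch,
        residue_number = s$residue_number[aln$pairs[, 2]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, entries)
  rownames(out) <- NULL
  if (!nrow(out)) stop("zero mapped positions: wrong sequence?")
  n_pos <- if (!is.null(gene_seq)) nchar(gene_seq) else max(out$protein_position)
  attr(out, "coverage") <- length(unique(out$protein_position)) / n_pos
  class(out) <- c("residue_alignment_map", "data.frame")
  out
}
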