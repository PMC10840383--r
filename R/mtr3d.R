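# Per-residue 3D MTR scoring, chain averaging, intra-complex scoring and
# blue-white-red color assignment.

#' Score every mapped residue of a structure with a 3D MTR
#'
#' For each residue of the structure that is mapped to a gene position, a
#' spatial window of the `k` nearest mapped residues (focal included,
#' [knn_window()]) is taken over all mapped residues of the structure -
#' windows may span chains - and the MTR of the pooled codon tallies of the
#' window's member positions is computed ([mtr_over_set()]). Residues
#' without density neither score nor serve as neighbors.
#'
#' @param counts A `codon_counts` data frame for the gene.
#' @param amap A `residue_alignment_map` from [map_gene_to_structure()].
#' @param sites A `residue_sites` data frame.
#' @param k Window size (focal + k-1 neighbors); the headline analyses use
#'   31 for single structures and 21 for complexes.
#' @return An `mtr_track` data frame with columns `gene_id`, `chain_id`,
#'   `residue_number`, `protein_position`, `score`, `n_obs`; attributes `k`
#'   and `structure_id`.
#' @export
score_structure <- function(counts, amap, sites, k = 31) {
  if (k < 1) stop("window size k must be >= 1")
  cov <- attr(amap, "coverage")
  if (!is.null(cov) && cov == 0) stop("alignment map covers no positions")
  key_sites <- paste(sites$chain_id, sites$residue_number, sep = "\r")
  key_map <- paste(amap$chain_id, amap$residue_number, sep = "\r")
  mapped <- sites[key_sites %in% key_map, , drop = FALSE]
  if (!nrow(mapped)) stop("no structure residue is mapped to a gene position")
  pos_of <- amap$protein_position[match(paste(mapped$chain_id,
                                              mapped$residue_number,
                                              sep = "\r"), key_map)]
  crow <- match(pos_of, counts$codon_index)
  if (anyNA(crow))
    stop("mapped gene positions missing from codon counts: ",
         paste(utils::head(pos_of[is.na(crow)]), collapse = ", "))
  scores <- numeric(nrow(mapped)); nobs <- integer(nrow(mapped))
  for (i in seq_len(nrow(mapped))) {
    win <- knn_window(mapped, mapped$chain_id[i], mapped$residue_number[i], k)
    wi <- match(paste(win$chain_id, win$residue_number, sep = "\r"),
                paste(mapped$chain_id, mapped$residue_number, sep = "\r"))
    s <- mtr_over_set(counts[crow[wi], , drop = FALSE])
    scores[i] <- s$value
    nobs[i] <- s$n_obs
  }
  out <- data.frame(
    gene_id = counts$gene_id[1],
    chain_id = mapped$chain_id,
    residue_number = mapped$residue_number,
    protein_position = pos_of,
    score = scores,
    n_obs = nobs,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "structure_id") <- mapped$structure_id[1]
  class(out) <- c("mtr_track", "data.frame")
  out
}

#' Average per-chain 3D MTR scores into a single per-position track
#'
#' Arithmetic mean over the chains with a defined score at each protein
#' position (a tetrameric structure carries four copies of each position);
#' positions undefined in every chain stay missing. The result is invariant
#' to chain order.
#'
#' @param track An `mtr_track` from [score_structure()] or [score_complex()].
#' @return Data frame `gene_id`, `protein_position`, `score`, `n_chains`
#'   (chains contributing a defined score), sorted by position.
#' @export
average_chains <- function(track) {
  sp <- split(track, track$protein_position)
  out <- do.call(rbind, lapply(sp, function(g) {
    ok <- !is.na(g$score)
    data.frame(gene_id = g$gene_id[1],
               protein_position = g$protein_position[1],
               score = if (any(ok)) mean(g$score[ok]) else NA_real_,
               n_chains = sum(ok),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$protein_position), ]
  rownames(out) <- NULL
  attr(out, "k") <- attr(track, "k")
  class(out) <- c("mtr_avg_track", "data.frame")
  out
}

#' Intra-complex 3D MTR across two or more interacting proteins
#'
#' Windows are taken over the pooled residue cloud of all genes' mapped
#' residues, so a window centered near an interface mixes residues from both
#' proteins. By default the observed/expected tallies of a window are pooled
#' across member residues regardless of source gene (a single joint
#' intolerance surface); `pool = FALSE` restricts tallies to residues of the
#' focal residue's own gene while keeping the spatial window.
#'
#' @param gene_inputs Named list (one entry per gene) of
#'   `list(counts = <codon_counts>, amap = <residue_alignment_map>)`.
#' @param sites Pooled `residue_sites` of the whole complex.
#' @param k Window size; the interface analyses use 21.
#' @param pool Pool tallies across genes within a window (default `TRUE`).
#' @return Named list of `mtr_track` objects, one per gene.
#' @export
score_complex <- function(gene_inputs, sites, k = 21, pool = TRUE) {
  if (length(gene_inputs) < 2) stop("score_complex needs >= 2 genes")
  maps <- lapply(gene_inputs, `[[`, "amap")
  keys <- lapply(maps, function(m) paste(m$chain_id, m$residue_number, sep = "\r"))
  allk <- unlist(keys)
  if (anyDuplicated(allk)) stop("residue mapped to two genes")
  key_sites <- paste(sites$chain_id, sites$residue_number, sep = "\r")
  mapped <- sites[key_sites %in% allk, , drop = FALSE]
  mkey <- paste(mapped$chain_id, mapped$residue_number, sep = "\r")
  gene_of <- rep(names(gene_inputs), lengths(keys))[match(mkey, allk)]
  # pooled counts row for each mapped residue
  count_row <- lapply(seq_along(mkey), function(i) {
    g <- gene_of[i]
    m <- maps[[g]]
    pos <- m$protein_position[match(mkey[i], keys[[g]])]
    gene_inputs[[g]]$counts[match(pos, gene_inputs[[g]]$counts$codon_index), ,
                            drop = FALSE]
  })
  pos_of <- vapply(count_row, function(r) r$codon_index[1], numeric(1))
  tracks <- lapply(names(gene_inputs), function(g) {
    idx <- which(gene_of == g)
    scores <- numeric(length(idx)); nobs <- integer(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      win <- knn_window(mapped, mapped$chain_id[i], mapped$residue_number[i], k)
      wi <- match(paste(win$chain_id, win$residue_number, sep = "\r"), mkey)
      if (!pool) wi <- wi[gene_of[wi] == g]
      tallies <- do.call(rbind, count_row[wi])
      s <- mtr_over_set(tallies)
      scores[j] <- s$value
      nobs[j] <- s$n_obs
    }
    out <- data.frame(
      gene_id = g,
      chain_id = mapped$chain_id[idx],
      residue_number = mapped$residue_number[idx],
      protein_position = pos_of[idx],
      score = scores,
      n_obs = nobs,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "k") <- k
    attr(out, "structure_id") <- mapped$structure_id[1]
    class(out) <- c("mtr_track", "data.frame")
    out
  })
  stats::setNames(tracks, names(gene_inputs))
}

#' Assign blue-white-red colors to an averaged MTR track
#'
#' Piecewise-linear, monotone mapping: blue at the low anchor through white
#' at the mid anchor to red at the high anchor. Anchors default to the track
#' minimum / median / maximum (the per-structure scaling used for display);
#' `mid = "fixed"` pins the mid anchor at score 1 (neutral tolerance).
#' Missing scores are colored grey.
#'
#' @param avg_track An `mtr_avg_track` from [average_chains()] (any data
#'   frame with `protein_position` and `score` works).
#' @param mid `"median"` (default) or `"fixed"` (mid anchor at 1.0).
#' @return The track with columns `r`, `g`, `b` (0-255) and `hex` appended;
#'   attribute `color_scale` = list(min, mid, max, policy).
#' @export
assign_colors <- function(avg_track, mid = c("median", "fixed")) {
  mid <- match.arg(mid)
  sc <- avg_track$score
  if (all(is.na(sc))) stop("all scores missing; nothing to color")
  lo <- min(sc, na.rm = TRUE)
  hi <- max(sc, na.rm = TRUE)
  md <- if (mid == "median") stats::median(sc, na.rm = TRUE) else 1.0
  md <- min(max(md, lo), hi)
  blue <- c(0, 0, 255); white <- c(255, 255, 255); red <- c(255, 0, 0)
  rgb_of <- function(v) {
    if (is.na(v)) return(c(128, 128, 128))
    if (v <= md) {
      t <- if (md > lo) (v - lo) / (md - lo) else 1
      round(blue + t * (white - blue))
    } else {
      t <- if (hi > md) (v - md) / (hi - md) else 0
      round(white + t * (red - white))
    }
  }
  cols <- t(vapply(sc, rgb_of, numeric(3)))
  avg_track$r <- cols[, 1]; avg_track$g <- cols[, 2]; avg_track$b <- cols[, 3]
  avg_track$hex <- grDevices::rgb(cols[, 1], cols[, 2], cols[, 3],
                                  maxColorValue = 255)
  attr(avg_track, "color_scale") <- list(min = lo, mid = md, max = hi,
                                         policy = mid)
  avg_track
}

#' Write an MTR score track to TSV
#'
#' @param track An `mtr_track` or `mtr_avg_track`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_track_tsv <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
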