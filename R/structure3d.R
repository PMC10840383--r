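# PDB parsing, representative residue coordinates, k-nearest-residue
# windows, and score-colored PDB output.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

# Fixed-column fields of a PDB ATOM/HETATM record (1-based, inclusive)
pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Parse residue sites from a PDB file
#'
#' Reads ATOM records of the first model and returns one representative
#' coordinate per residue: the C-alpha by default, or the side-chain centroid
#' (mean over non-backbone heavy atoms; glycine falls back to C-alpha).
#' Alternate locations are resolved to the highest-occupancy conformer;
#' residues lacking the representative atom are dropped with a warning.
#' HETATM records are ignored.
#'
#' @param file Path to a PDB file.
#' @param representative `"CA"` (default) or `"sidechain_centroid"`.
#' @return A `residue_sites` data frame with columns `structure_id`,
#'   `chain_id`, `residue_number`, `amino_acid` (one-letter), `x`, `y`, `z`.
#' @export
parse_structure <- function(file, representative = c("CA", "sidechain_centroid")) {
  representative <- match.arg(representative)
  lines <- readLines(file, warn = FALSE)
  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  at <- lines[startsWith(lines, "ATOM  ")]
  if (!length(at)) stop("no ATOM records in ", file)

  atom_name <- trimws(pdb_field(at, 13, 16))
  altloc <- pdb_field(at, 17, 17)
  resname <- trimws(pdb_field(at, 18, 20))
  chain <- pdb_field(at, 22, 22)
  resnum <- as.integer(pdb_field(at, 23, 26))
  x <- as.numeric(pdb_field(at, 31, 38))
  y <- as.numeric(pdb_field(at, 39, 46))
  z <- as.numeric(pdb_field(at, 47, 54))
  occ <- suppressWarnings(as.numeric(pdb_field(at, 55, 60)))
  occ[is.na(occ)] <- 1

  df <- data.frame(atom_name, altloc, resname, chain, resnum, x, y, z, occ,
                   stringsAsFactors = FALSE)
  # occupancy-major altloc rule: keep the highest-occupancy conformer of
  # each (residue, atom); ties resolved alphabetically by altloc id
  o <- order(df$chain, df$resnum, df$atom_name, -df$occ, df$altloc)
  df <- df[o, ]
  key <- paste(df$chain, df$resnum, df$atom_name, sep = "\r")
  df <- df[!duplicated(key), ]

  res_key <- paste(df$chain, df$resnum, sep = "\r")
  reps <- lapply(split(df, factor(res_key, levels = unique(res_key))),
    function(r) {
      if (representative == "CA") {
        hit <- r[r$atom_name == "CA", , drop = FALSE]
        if (!nrow(hit)) return(NULL)
        c(x = hit$x[1], y = hit$y[1], z = hit$z[1])
      } else {
        side <- r[!(r$atom_name %in% c("N", "CA", "C", "O", "OXT")) &
                    !grepl("^[0-9]*H", r$atom_name), , drop = FALSE]
        if (nrow(side)) {
          c(x = mean(side$x), y = mean(side$y), z = mean(side$z))
        } else {
          hit <- r[r$atom_name == "CA", , drop = FALSE]   # glycine fallback
          if (!nrow(hit)) return(NULL)
          c(x = hit$x[1], y = hit$y[1], z = hit$z[1])
        }
      }
    })
  dropped <- vapply(reps, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " residue(s) lacked a representative atom and were dropped")
  keep <- names(reps)[!dropped]
  first <- df[!duplicated(res_key), ]
  rownames(first) <- paste(first$chain, first$resnum, sep = "\r")
  first <- first[keep, ]
  coords <- do.call(rbind, reps[!dropped])

  structure_id <- sub("\\.pdb$", "", basename(file))
  hdr <- lines[startsWith(lines, "HEADER")]
  if (length(hdr)) {
    idcode <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(idcode)) structure_id <- idcode
  }
  aa1 <- AA3TO1[first$resname]
  aa1[is.na(aa1)] <- "X"
  out <- data.frame(
    structure_id = structure_id,
    chain_id = first$chain,
    residue_number = first$resnum,
    amino_acid = unname(aa1),
    x = coords[, "x"], y = coords[, "y"], z = coords[, "z"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  o <- order(out$chain_id, out$residue_number)
  out <- out[o, ]
  rownames(out) <- NULL
  class(out) <- c("residue_sites", "data.frame")
  out
}

#' k-nearest-residue window around a focal residue
#'
#' Returns the focal residue plus its `k - 1` nearest neighbors by Euclidean
#' distance between representative coordinates. Distance ties are broken by
#' ascending `(chain_id, residue_number)`. When a multi-chain site list is
#' passed the window may span chains.
#'
#' @param sites A `residue_sites` data frame.
#' @param focal_chain,focal_residue Chain id and residue number of the focal
#'   residue (must be present in `sites`).
#' @param k Window size (focal included); `k >= 1`.
#' @return Subset of `sites` of size `min(k, nrow(sites))` containing the
#'   focal residue, ordered by distance.
#' @export
knn_window <- function(sites, focal_chain, focal_residue, k) {
  if (k < 1) stop("window size k must be >= 1")
  fi <- which(sites$chain_id == focal_chain &
                sites$residue_number == focal_residue)
  if (length(fi) != 1L) stop("focal residue not found (or not unique) in sites")
  d <- sqrt((sites$x - sites$x[fi])^2 +
              (sites$y - sites$y[fi])^2 +
              (sites$z - sites$z[fi])^2)
  o <- order(d, sites$chain_id, sites$residue_number)
  sel <- o[seq_len(min(k, nrow(sites)))]
  if (!(fi %in% sel)) sel[1] <- fi  # focal always included (zero distance)
  out <- sites[sel, ]
  rownames(out) <- NULL
  out
}

#' Replace PDB B-factors with scaled scores
#'
#' Writes a copy of a PDB file in which the B-factor column (columns 61-66)
#' of every ATOM/HETATM record is replaced by `100 * score` of its residue,
#' rounded to two decimals; residues without a score get the sentinel
#' `999.00`. All other columns are byte-identical to the input.
#'
#' @param file_in Input PDB path.
#' @param scores Data frame with columns `chain_id`, `residue_number`,
#'   `score` (dimensionless; `100 * score` must fit the `%6.2f` field, i.e.
#'   lie in (-100, 1000)). `NA` scores are treated as unscored.
#' @param file_out Output PDB path.
#' @return Invisibly, `file_out`.
#' @export
write_bfactor_pdb <- function(file_in, scores, file_out) {
  stopifnot(all(c("chain_id", "residue_number", "score") %in% names(scores)))
  sc <- scores$score[!is.na(scores$score)]
  if (length(sc) && any(100 * sc >= 1000 | 100 * sc <= -100))
    stop("score outside representable B-factor field (needs 100*score in (-100, 1000))")
  lines <- readLines(file_in, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  at <- lines[is_atom]
  key <- paste(pdb_field(at, 22, 22), as.integer(pdb_field(at, 23, 26)),
               sep = "\r")
  skey <- paste(scores$chain_id, scores$residue_number, sep = "\r")
  val <- scores$score[match(key, skey)] * 100
  val[is.na(val)] <- 999
  field <- sprintf("%6.2f", val)
  # records shorter than 66 columns are padded so the field exists
  at <- formatC(at, width = -66)
  substr(at, 61, 66) <- field
  lines[is_atom] <- at
  writeLines(lines, file_out)
  invisible(file_out)
}

#' Protein sequence of each chain in a site list
#'
#' @param sites A `residue_sites` data frame.
#' @return Named character vector, one sequence per chain in residue-number
#'   order (resolved residues only).
#' @export
chain_sequences <- function(sites) {
  vapply(split(sites, sites$chain_id), function(s) {
    paste(s$amino_acid[order(s$residue_number)], collapse = "")
  }, character(1))
}
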