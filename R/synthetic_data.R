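# Deterministic generators for every input the pipeline consumes:
# synthetic structures, per-codon variant counts, concentration-response
# curves, plate-reader kinetics, and adhesion contact logs.

# run fn with a private RNG stream; leaves the caller's RNG untouched
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  fn()
}

# codons for an amino-acid sequence (first codon of each in a fixed table),
# used to give synthetic proteins a definite CDS
aa_to_codon <- function(aa) {
  code <- genetic_code()
  pick <- tapply(names(code), code, function(x) sort(x)[1])
  unname(pick[aa])
}

format_atom <- function(serial, name, resname, chain, resnum, x, y, z,
                        b = 0, element = "C") {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), resname, chain, resnum, x, y, z, 1.00, b,
          element)
}

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

helix_coords <- function(n, rise = 1.5, radius = 2.3, twist = 100,
                         origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  th <- i * twist * pi / 180
  cbind(x = origin[1] + radius * cos(th),
        y = origin[2] + radius * sin(th),
        z = origin[3] + i * rise)
}

lattice_coords <- function(n, spacing = 3.8) {
  side <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  as.matrix(g[seq_len(n), ]) * spacing
}

#' Generate a synthetic protein structure (PDB + FASTA)
#'
#' C-alpha traces in one of four geometries: an ideal alpha-helix (rise
#' 1.5 A, radius 2.3 A, 100 degrees per residue), a cubic lattice, two
#' parallel helices in one structure (`"two-chain"`), or a two-protein
#' `"complex"` whose chains approach within a contact patch (minimum
#' inter-protein C-alpha distance <= 8 A). Optional residue dropouts
#' emulate missing electron density. Residue identities are drawn uniformly
#' from the 20 standard amino acids under the seed.
#'
#' @param n_residues Residues per chain (>= 2).
#' @param geometry `"helix"`, `"lattice"`, `"two-chain"`, or `"complex"`.
#' @param spacing Lattice spacing in Angstrom (lattice geometry only).
#' @param dropout Integer residue numbers to omit from the PDB (missing
#'   density); applies to chain A.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return List with paths `pdb`, `fasta`, and `sequences` (named character
#'   vector per chain).
#' @export
make_structure <- function(n_residues, geometry = c("helix", "lattice",
                                                    "two-chain", "complex"),
                           spacing = 3.8, dropout = integer(0), seed = 1,
                           dir = tempdir(), prefix = "synthetic") {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stop("n_residues must be >= 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- with_seed(seed, function() {
    n_chain <- if (geometry %in% c("two-chain", "complex")) 2L else 1L
    lapply(seq_len(n_chain), function(i)
      sample(names(AA1TO3), n_residues, replace = TRUE))
  })
  chains <- LETTERS[seq_along(seqs)]
  coords <- switch(geometry,
    helix = list(helix_coords(n_residues)),
    lattice = list(lattice_coords(n_residues, spacing)),
    # parallel helices far apart: no spatial mixing between chains
    "two-chain" = list(helix_coords(n_residues),
                       helix_coords(n_residues, origin = c(50, 0, 0))),
    # antiparallel-offset helices whose first turns touch (< 8 A)
    complex = list(helix_coords(n_residues),
                   helix_coords(n_residues, origin = c(7, 0, 0)))
  )
  lines <- c("HEADER    SYNTHETIC STRUCTURE                     01-JAN-26   SYN1")
  serial <- 0L
  for (ci in seq_along(seqs)) {
    for (ri in seq_len(n_residues)) {
      if (ci == 1L && ri %in% dropout) next
      serial <- serial + 1L
      lines <- c(lines, format_atom(
        serial, "CA", AA1TO3[seqs[[ci]][ri]], chains[ci], ri,
        coords[[ci]][ri, 1], coords[[ci]][ri, 2], coords[[ci]][ri, 3]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  pdb <- file.path(dir, paste0(prefix, ".pdb"))
  writeLines(lines, pdb)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  fa <- unlist(lapply(seq_along(seqs), function(ci)
    c(paste0(">", prefix, "_", chains[ci]),
      paste(seqs[[ci]], collapse = ""))))
  writeLines(fa, fasta)
  list(pdb = pdb, fasta = fasta,
       sequences = stats::setNames(vapply(seqs, paste, character(1),
                                          collapse = ""), chains))
}

#' Synthetic CDS for a protein sequence
#'
#' Deterministically back-translates a protein sequence (first codon of each
#' amino acid in alphabetical codon order) into a `transcript_cds`.
#'
#' @param gene_id Gene identifier.
#' @param protein_seq Protein sequence (standard 20 letters).
#' @return A `transcript_cds` object.
#' @export
make_cds <- function(gene_id, protein_seq) {
  aa <- strsplit(protein_seq, "")[[1]]
  transcript_cds(gene_id, paste(aa_to_codon(aa), collapse = ""))
}

#' Simulate per-codon observed variant counts
#'
#' Observation model: `obs_synonymous ~ Poisson(rate * exp_synonymous)` and
#' `obs_missense ~ Poisson(rate * exp_missense * f)` with `f = depletion
#' factor` at depleted positions and 1 elsewhere. `depletion = 1` gives the
#' null (window MTRs distributed around 1); `depletion = 0` fully removes
#' missense observation pressure in the patch.
#'
#' @param cds A `transcript_cds`.
#' @param baseline_rate Expected observations per possible substitution
#'   (default 0.5, i.e. roughly one observed variant per two substitution
#'   opportunities, a rate at which k = 31 windows carry stable tallies).
#' @param depleted_positions Integer codon positions under missense
#'   depletion.
#' @param depletion Missense depletion factor d in \[0, 1\].
#' @param seed Integer seed.
#' @param path Optional TSV output path; written deterministically.
#' @return A data frame `gene_id`, `codon_index`, `obs_missense`,
#'   `obs_synonymous` (the TSV dialect of [load_observed_counts()]).
#' @export
make_variant_counts <- function(cds, baseline_rate = 0.5,
                                depleted_positions = integer(0),
                                depletion = 1, seed = 1, path = NULL) {
  if (depletion < 0 || depletion > 1) stop("depletion must be in [0, 1]")
  skel <- enumerate_codon_expectations(cds)
  f <- ifelse(skel$codon_index %in% depleted_positions, depletion, 1)
  obs <- with_seed(seed, function() {
    list(mis = stats::rpois(nrow(skel), baseline_rate * skel$exp_missense * f),
         syn = stats::rpois(nrow(skel), baseline_rate * skel$exp_synonymous))
  })
  out <- data.frame(gene_id = skel$gene_id, codon_index = skel$codon_index,
                    obs_missense = obs$mis, obs_synonymous = obs$syn,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Simulate concentration-response curves from the Hill forward models
#'
#' Per-cell responses are the activation or inhibition Hill model value plus
#' Gaussian noise (SD in percent of the maximal response). Reference
#' currents consistent with a chosen difference current are emitted
#' alongside, so normalization machinery can be exercised end to end.
#'
#' @param model `"activation"` or `"inhibition"`.
#' @param midpoint_M Generating midpoint (EC50/IC50) in molar.
#' @param nH Hill slope.
#' @param minimum Residual response at saturation in percent (inhibition
#'   model only).
#' @param concentrations_M Tested concentrations (molar), spanning the
#'   midpoint.
#' @param noise_sd Gaussian noise SD in percent of maximum (default 3).
#' @param n_cells Replicate cells (default 3).
#' @param difference_nA Difference current used to synthesize reference
#'   currents (default 1300 nA, the scale of a strongly constitutive
#'   variant).
#' @param seed Integer seed.
#' @return List of data frames `curves` (`cell_id`, `concentration_M`,
#'   `response_pct`, `current_nA`) and `refs` (`cell_id`, `I_baseline_nA`,
#'   `I_NMDG_nA`).
#' @export
make_dose_response <- function(model = c("activation", "inhibition"),
                               midpoint_M, nH = 1, minimum = 5,
                               concentrations_M, noise_sd = 3, n_cells = 3,
                               difference_nA = 1300, seed = 1) {
  model <- match.arg(model)
  if (min(concentrations_M) > midpoint_M || max(concentrations_M) < midpoint_M)
    stop("tested concentrations must span the midpoint")
  mu <- if (model == "activation")
    hill_activation(concentrations_M, log10(midpoint_M), nH)
  else
    hill_inhibition(concentrations_M, log10(midpoint_M), nH, minimum)
  curves <- with_seed(seed, function() {
    do.call(rbind, lapply(seq_len(n_cells), function(cl) {
      resp <- mu + stats::rnorm(length(mu), sd = noise_sd)
      data.frame(cell_id = sprintf("cell%02d", cl),
                 concentration_M = concentrations_M,
                 response_pct = resp,
                 stringsAsFactors = FALSE)
    }))
  })
  I_NMDG <- -50
  I_base <- I_NMDG - difference_nA
  curves$current_nA <- I_base + (curves$response_pct / 100) * difference_nA
  refs <- data.frame(cell_id = sprintf("cell%02d", seq_len(n_cells)),
                     I_baseline_nA = I_base, I_NMDG_nA = I_NMDG,
                     stringsAsFactors = FALSE)
  list(curves = curves, refs = refs)
}

#' Log-spaced concentration ladder
#'
#' @param from,to Endpoints in molar.
#' @param n Number of concentrations.
#' @return Numeric vector, log10-equally spaced, ascending.
#' @export
conc_ladder <- function(from, to, n) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Simulate plate-reader kinetic traces
#'
#' Linear absorbance ramps (one read per minute for 30 minutes) with
#' Gaussian noise, one trace per well.
#'
#' @param slopes Named numeric vector of true slopes (AU/min), one per well;
#'   names become well ids.
#' @param intercept Baseline absorbance (AU).
#' @param noise_sd Gaussian noise SD (AU).
#' @param t_min Time points (default 0:30 minutes).
#' @param seed Integer seed.
#' @return Data frame `well`, `t_min`, `absorbance`.
#' @export
make_plate <- function(slopes, intercept = 0.1, noise_sd = 0.005,
                       t_min = 0:30, seed = 1) {
  with_seed(seed, function() {
    do.call(rbind, lapply(names(slopes), function(w) {
      data.frame(well = w, t_min = t_min,
                 absorbance = intercept + slopes[[w]] * t_min +
                   stats::rnorm(length(t_min), sd = noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate adhesion contact logs
#'
#' Bernoulli contacts: each bead-cell pair makes `n_contacts` touches, each
#' independently producing a binding event with probability `p_adhesion`.
#'
#' @param p_adhesion Per-contact binding probability in \[0, 1\].
#' @param n_contacts Contacts per pair (nominally 50-100).
#' @param n_pairs Number of bead-cell pairs.
#' @param condition Condition label carried into the output.
#' @param seed Integer seed.
#' @return Data frame `pair_id`, `condition`, `n_contacts`, `n_adhesions`.
#' @export
make_adhesion <- function(p_adhesion, n_contacts = 50, n_pairs = 10,
                          condition = "cond", seed = 1) {
  if (p_adhesion < 0 || p_adhesion > 1) stop("p_adhesion must be in [0, 1]")
  with_seed(seed, function() {
    data.frame(pair_id = sprintf("pair%04d", seq_len(n_pairs)),
               condition = condition,
               n_contacts = n_contacts,
               n_adhesions = stats::rbinom(n_pairs, n_contacts, p_adhesion),
               stringsAsFactors = FALSE)
  })
}
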