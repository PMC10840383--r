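# 3D MTR orchestration: scoring, chain averaging, complexes, colors.

make_line_sites <- function(n, chain = "A", x0 = 0) {
  data.frame(structure_id = "s", chain_id = chain, residue_number = seq_len(n),
             amino_acid = "A", x = x0 + seq_len(n) * 3.8, y = 0, z = 0,
             stringsAsFactors = FALSE)
}

random_gene_fixture <- function(n = 40, seed = 1, rate = 2,
                                depleted = integer(0), depletion = 1) {
  cds <- make_cds("g", paste(sample(c("A","C","D","E","F","G","H","I","K","L"),
                                    n, replace = TRUE), collapse = ""))
  cnt <- make_variant_counts(cds, baseline_rate = rate,
                             depleted_positions = depleted,
                             depletion = depletion, seed = seed)
  load_observed_counts(cnt, cds)
}

test_that("uniform counts matched to expectations score exactly 1", {
  sites <- make_line_sites(20)
  cds <- transcript_cds("g", strrep("CTGGAA", 10))
  counts <- uniform_counts(cds)
  amap <- map_gene_to_structure("g", strrep("LE", 10), sites,
                                alignment = "identity")
  tr <- score_structure(counts, amap, sites, k = 7)
  expect_true(all(tr$score == 1))
})

test_that("3D window on a collinear structure equals the 1D sliding window", {
  n <- 31
  set.seed(11)
  counts <- random_gene_fixture(n, seed = 4, rate = 3)
  gene_seq <- strrep("A", n)
  sites <- make_line_sites(n)
  k <- 7
  amap <- map_gene_to_structure("g", gene_seq, sites, alignment = "identity")
  tr <- score_structure(counts, amap, sites, k = k)
  # independent 1D sliding-window computation (nearest k by sequence
  # distance, which equals spatial distance on a uniform line)
  half <- (k - 1) / 2
  for (i in seq_len(n)) {
    lo <- min(max(1, i - half), n - k + 1)
    win <- lo:(lo + k - 1)
    expect_equal(tr$score[tr$residue_number == i],
                 mtr_over_set(counts[win, ])$value, info = paste("pos", i))
  }
})

test_that("window saturation gives the whole-protein MTR everywhere", {
  set.seed(2)
  counts <- random_gene_fixture(15, seed = 8)
  sites <- make_line_sites(15)
  amap <- map_gene_to_structure("g", strrep("A", 15), sites,
                                alignment = "identity")
  tr <- score_structure(counts, amap, sites, k = 100)
  expect_equal(length(unique(tr$score)), 1)
  expect_equal(tr$score[1], mtr_over_set(counts)$value)
})

test_that("chain averaging is the mean over defined scores, order-invariant", {
  tr <- data.frame(
    gene_id = "g",
    chain_id = c("A", "B", "C", "D", "A", "B"),
    residue_number = c(5, 5, 5, 5, 6, 6),
    protein_position = c(5, 5, 5, 5, 6, 6),
    score = c(0.8, 1.2, NA, NA, NA, NA),
    n_obs = 1L, stringsAsFactors = FALSE)
  class(tr) <- c("mtr_track", "data.frame")
  avg <- average_chains(tr)
  expect_equal(avg$score[avg$protein_position == 5], 1.0)
  expect_equal(avg$n_chains[avg$protein_position == 5], 2)
  expect_true(is.na(avg$score[avg$protein_position == 6]))
  # permutation invariance in chain order
  avg2 <- average_chains(tr[sample(nrow(tr)), ])
  expect_equal(avg, avg2, ignore_attr = TRUE)
})

test_that("four identical chains average to any single chain", {
  dir <- withr::local_tempdir()
  st <- make_structure(20, "two-chain", seed = 6, dir = dir)
  sites <- parse_structure(st$pdb)
  # force both chains to carry the gene sequence of chain A
  sites$amino_acid <- rep(strsplit(st$sequences[["A"]], "")[[1]], 2)
  counts <- random_gene_fixture(20, seed = 3)
  amap <- map_gene_to_structure("g", st$sequences[["A"]], sites,
                                alignment = "identity")
  tr <- score_structure(counts, amap, sites, k = 5)
  avg <- average_chains(tr)
  one <- tr[tr$chain_id == "A", ]
  # chains are 50 A apart: windows never mix, scores per chain identical
  expect_equal(avg$score, one$score[order(one$protein_position)])
})

test_that("missense-depleted 3D patch is the track minimum", {
  for (s in c(21, 22, 23)) {
    dir <- withr::local_tempdir()
    st <- make_structure(80, "helix", seed = s, dir = dir)
    sites <- parse_structure(st$pdb)
    cds <- make_cds("g", st$sequences[["A"]])
    # helix turn: residues 35..45 are 3D-contiguous
    patch <- 35:45
    cnt <- make_variant_counts(cds, baseline_rate = 4,
                               depleted_positions = patch, depletion = 0,
                               seed = s * 100)
    counts <- load_observed_counts(cnt, cds)
    amap <- map_gene_to_structure("g", st$sequences[["A"]], sites,
                                  alignment = "identity")
    tr <- score_structure(counts, amap, sites, k = 11)
    avg <- average_chains(tr)
    expect_true(avg$protein_position[which.min(avg$score)] %in% patch,
                info = paste("seed", s))
    expect_lt(mean(avg$score[avg$protein_position %in% patch], na.rm = TRUE),
              mean(avg$score[!avg$protein_position %in% patch], na.rm = TRUE))
  }
})

test_that("depletion ordering follows the depletion factor", {
  dir <- withr::local_tempdir()
  st <- make_structure(60, "helix", seed = 31, dir = dir)
  sites <- parse_structure(st$pdb)
  cds <- make_cds("g", st$sequences[["A"]])
  amap <- map_gene_to_structure("g", st$sequences[["A"]], sites,
                                alignment = "identity")
  patch <- 25:35
  patch_mean <- vapply(c(0, 0.25, 0.5), function(d) {
    cnt <- make_variant_counts(cds, baseline_rate = 6,
                               depleted_positions = patch, depletion = d,
                               seed = 77)
    counts <- load_observed_counts(cnt, cds)
    avg <- average_chains(score_structure(counts, amap, sites, k = 11))
    mean(avg$score[avg$protein_position %in% patch], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(patch_mean) > 0))
})

test_that("far-apart complex partners score as independent runs", {
  dir <- withr::local_tempdir()
  st <- make_structure(30, "two-chain", seed = 13, dir = dir)
  sites <- parse_structure(st$pdb)
  seqA <- st$sequences[["A"]]; seqB <- st$sequences[["B"]]
  cdsA <- make_cds("gA", seqA); cdsB <- make_cds("gB", seqB)
  cntA <- load_observed_counts(
    make_variant_counts(cdsA, baseline_rate = 3, seed = 1), cdsA)
  cntB <- load_observed_counts(
    make_variant_counts(cdsB, baseline_rate = 3, seed = 2), cdsB)
  amapA <- map_gene_to_structure("gA", seqA, sites, alignment = "identity",
                                 chains = "A")
  amapB <- map_gene_to_structure("gB", seqB, sites, alignment = "identity",
                                 chains = "B")
  cx <- score_complex(list(gA = list(counts = cntA, amap = amapA),
                           gB = list(counts = cntB, amap = amapB)),
                      sites, k = 9)
  soloA <- score_structure(cntA, amapA, sites[sites$chain_id == "A", ], k = 9)
  soloB <- score_structure(cntB, amapB, sites[sites$chain_id == "B", ], k = 9)
  expect_equal(cx$gA$score, soloA$score)
  expect_equal(cx$gB$score, soloB$score)
})

test_that("interface windows pool tallies across genes", {
  dir <- withr::local_tempdir()
  st <- make_structure(20, "complex", seed = 17, dir = dir)
  sites <- parse_structure(st$pdb)
  seqA <- st$sequences[["A"]]; seqB <- st$sequences[["B"]]
  cdsA <- make_cds("gA", seqA); cdsB <- make_cds("gB", seqB)
  cntA <- load_observed_counts(
    make_variant_counts(cdsA, baseline_rate = 3, seed = 5), cdsA)
  cntB <- load_observed_counts(
    make_variant_counts(cdsB, baseline_rate = 3, seed = 6), cdsB)
  amapA <- map_gene_to_structure("gA", seqA, sites, alignment = "identity",
                                 chains = "A")
  amapB <- map_gene_to_structure("gB", seqB, sites, alignment = "identity",
                                 chains = "B")
  cx <- score_complex(list(gA = list(counts = cntA, amap = amapA),
                           gB = list(counts = cntB, amap = amapB)),
                      sites, k = 9)
  # brute-force pooling oracle for one interface residue
  focal <- 1
  win <- knn_window(sites, "A", focal, 9)
  expect_true(any(win$chain_id == "B"))  # the window crosses the interface
  pooled <- rbind(cntA[win$residue_number[win$chain_id == "A"], ],
                  cntB[win$residue_number[win$chain_id == "B"], ])
  expect_equal(cx$gA$score[cx$gA$chain_id == "A" &
                             cx$gA$residue_number == focal],
               mtr_over_set(pooled)$value)
  # partner gene with zero observations leaves focal windows defined
  cntB0 <- cntB; cntB0$obs_missense <- 0L; cntB0$obs_synonymous <- 0L
  cx0 <- score_complex(list(gA = list(counts = cntA, amap = amapA),
                            gB = list(counts = cntB0, amap = amapB)),
                       sites, k = 9)
  expect_false(anyNA(cx0$gA$score))
  # residue mapped to two genes is rejected
  expect_error(score_complex(list(gA = list(counts = cntA, amap = amapA),
                                  gB = list(counts = cntB, amap = amapA)),
                             sites, k = 9), "two genes")
})

test_that("color assignment anchors and interpolation behave as stated", {
  tr <- data.frame(protein_position = 1:3, score = c(0, 1, 2))
  col <- assign_colors(tr, mid = "fixed")
  expect_equal(unlist(col[1, c("r", "g", "b")], use.names = FALSE),
               c(0, 0, 255))      # pure blue at min
  expect_equal(unlist(col[2, c("r", "g", "b")], use.names = FALSE),
               c(255, 255, 255))  # white at mid
  expect_equal(unlist(col[3, c("r", "g", "b")], use.names = FALSE),
               c(255, 0, 0))      # pure red at max

  # constant track collapses to white
  cst <- assign_colors(data.frame(protein_position = 1:3, score = rep(1, 3)))
  expect_true(all(cst$hex == "#FFFFFF"))

  # asymmetric track, median mid: 0.95 interpolates in the blue half
  tr2 <- data.frame(protein_position = 1:5, score = c(0.5, 0.9, 1.0, 1.1, 0.95))
  col2 <- assign_colors(tr2, mid = "median")
  sc <- attr(col2, "color_scale")
  expect_equal(sc$mid, 0.95)
  expect_true(col2$b[5] == 255 && col2$r[5] == 255)  # exactly at median: white
  expect_true(col2$r[2] < 255 && col2$b[2] == 255)   # 0.9 in the blue half

  # missing scores are grey; all-missing rejected
  colna <- assign_colors(data.frame(protein_position = 1:2, score = c(1, NA)))
  expect_equal(colna$hex[2], "#808080")
  expect_error(assign_colors(data.frame(protein_position = 1, score = NA_real_)),
               "missing")
})
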