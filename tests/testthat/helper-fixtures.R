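# Shared fixtures and independent oracles, all built in code.

# Small handcrafted dataset: 2 samples x 3 segments, 2 clusters.
toySegExperiment <- function(seed = 42, nGenes = 40, cellsPerStratum = 6) {
  set.seed(seed)
  genes <- c("mt-Nd1", "mt-Cytb", "Hba-a1", sprintf("g%02d", seq_len(nGenes - 3)))
  cells <- expand.grid(sample_id = c("S1", "S2"),
                       segment = c("caput", "corpus", "cauda"),
                       cluster = c("principal", "basal"),
                       idx = seq_len(cellsPerStratum),
                       stringsAsFactors = FALSE)
  cells$age <- ifelse(cells$sample_id == "S1", "P42", "P56")
  cells$barcode <- sprintf("bc%04d", seq_len(nrow(cells)))
  cnt <- matrix(rnbinom(length(genes) * nrow(cells), mu = 3, size = 2),
                nrow = length(genes),
                dimnames = list(genes, cells$barcode))
  SegExperiment(cnt, cells)
}

# Exhaustive two-sided Wilcoxon p by enumeration of all equally likely
# rank assignments (no ties assumed). Independent of the implementation.
enumWilcoxP <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(N, m)
  wAll <- colSums(matrix(seq_len(N)[subsets], nrow = m)) - m * (m + 1) / 2
  pLo <- mean(wAll <= wObs)
  pHi <- mean(wAll >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# All assignments of ranks 1..n to groups of the given sizes; returns the
# vector of Kruskal-Wallis H values (no ties).
enumKWH <- function(sizes) {
  n <- sum(sizes)
  assignGroups <- function(remaining, sizes) {
    if (length(sizes) == 1L) return(list(list(remaining)))
    first <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      for (rest in assignGroups(setdiff(remaining, f), sizes[-1]))
        out[[length(out) + 1L]] <- c(list(f), rest)
    }
    out
  }
  parts <- assignGroups(seq_len(n), sizes)
  vapply(parts, function(gs) {
    S <- vapply(gs, sum, numeric(1))
    12 / (n * (n + 1)) * sum(S^2 / sizes) - 3 * (n + 1)
  }, numeric(1))
}

# Exhaustive permutation p for a Kruskal-Wallis H observed on no-tie data.
enumKWP <- function(groups) {
  sizes <- lengths(groups)
  hObs <- kruskalWallis(groups)$statistic
  hAll <- enumKWH(sizes)
  mean(hAll >= hObs - 1e-9)
}

# Fast design for module tests.
tinyDesign <- function(..., seed = 1L) {
  simDesign(nGenes = 120L, cellsPerSegment = 60L,
            clusterProportions = c(principal = 0.5, basal = 0.5),
            rngSeed = as.integer(seed), ...)
}

# Printed toy matrix used for exact filter accounting (5 genes x 6 cells):
#            c1 c2 c3 c4 c5 c6
# Aqp9        5  2  3  1  0  0   expressed in 4 cells
# Lcn5        4  0  0  2  1  0   expressed in 3 cells (at the floor)
# Hba-a1      1  0  1  1  1  0   globin, expressed in 4 cells
# mt-Cytb     2  3  1  2  4  6   expressed in 6 cells
# Rare1       7  0  0  0  3  0   expressed in 2 cells (below the floor)
toyQcMatrix <- function() {
  m <- matrix(c(5, 2, 3, 1, 0, 0,
                4, 0, 0, 2, 1, 0,
                1, 0, 1, 1, 1, 0,
                2, 3, 1, 2, 4, 6,
                7, 0, 0, 0, 3, 0),
              nrow = 5, byrow = TRUE,
              dimnames = list(c("Aqp9", "Lcn5", "Hba-a1", "mt-Cytb", "Rare1"),
                              paste0("c", 1:6)))
  cells <- data.frame(barcode = paste0("c", 1:6), sample_id = "S1",
                      segment = rep(c("caput", "corpus", "cauda"), 2),
                      age = "P42")
  SegExperiment(m, cells)
}

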