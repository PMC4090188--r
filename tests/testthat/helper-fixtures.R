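# Small fixture builders shared across test files.

# 2-individual, 3-marker PED/MAP pair with known dosage coding.
write_toy_pedmap <- function(dir = NULL) {
  if (is.null(dir)) { dir <- tempfile("pedmap"); dir.create(dir) }
  ped <- c("FAM ind1 0 0 1 -9 A A A G G G",
           "FAM ind2 0 0 2 -9 A G G G 0 0")
  map <- c("5\tm1\t0\t1000\tA\tG",
           "5\tm2\t0\t2000\tA\tG",
           "5\tm3\t0\t3000\tA\tG")
  ped_path <- file.path(dir, "toy.ped")
  map_path <- file.path(dir, "toy.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  list(ped = ped_path, map = map_path,
       # dosage of G: ind1 (0, 1, 2); ind2 (1, 2, NA)
       expected = matrix(c(0L, 1L, 1L, 2L, 2L, NA),
                         nrow = 2, dimnames = list(c("ind1", "ind2"), NULL)))
}

toy_map <- function(m, chr = "5", spacing = 1000L) {
  data.frame(marker_id = sprintf("m%03d", seq_len(m)), chromosome = chr,
             position_bp = spacing * seq_len(m), allele1 = "A",
             allele2 = "G", stringsAsFactors = FALSE)
}

random_geno <- function(n, m, miss = 0.05, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2L, runif(m, 0.2, 0.8)[rep(seq_len(m),
                                                       each = n)]), n, m)
  d[matrix(runif(n * m) < miss, n, m)] <- NA
  rownames(d) <- sprintf("i%03d", seq_len(n))
  geno_matrix(d, toy_map(m))
}

# Pedigree: two founder pairs, two full sibs from pair 1, one half sib
# (shared sire, dam from pair 2), and an inbred offspring of the full sibs.
toy_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("s1", "d1", "d2", "o1", "o2", "o3", "inb"),
    sire = c(NA, NA, NA, "s1", "s1", "s1", "o1"),
    dam = c(NA, NA, NA, "d1", "d1", "d2", "o2"),
    sex = c("M", "F", "F", "M", "F", "F", "M"),
    generation = c("F0", "F0", "F0", "F1", "F1", "F1", "F2"),
    stringsAsFactors = FALSE))
}

# Population of n unphased individuals built from k haplotypes drawn with
# the given frequencies (HWE random union); returns geno_matrix.
pop_from_haps <- function(haps, freq, n, map = NULL, seed = 1) {
  set.seed(seed)
  k <- nrow(haps)
  i1 <- sample(k, n, replace = TRUE, prob = freq)
  i2 <- sample(k, n, replace = TRUE, prob = freq)
  d <- haps[i1, , drop = FALSE] + haps[i2, , drop = FALSE]
  rownames(d) <- sprintf("i%04d", seq_len(n))
  geno_matrix(d, map %||% toy_map(ncol(haps)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
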