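# Fixture builders shared across the suite. Everything is generated in code;
# no binary or stored data.

tiny_variants <- function(n = 3, chrom = "1", pos = NULL,
                          alleleA = NULL, alleleB = NULL) {
  pos <- pos %||% seq(100, by = 100, length.out = n)
  alleleA <- alleleA %||% rep_len(c("A", "C", "G", "T"), n)
  alleleB <- alleleB %||% rep_len(c("G", "T", "A", "C"), n)
  variant_tbl(paste0("rs", seq_len(n)), chrom, pos, alleleA, alleleB)
}

`%||%` <- rlang::`%||%`

# Random small panel straight from matrices (no simulator), for IO tests.
random_panel <- function(n_samples = 5, n_variants = 10, seed = 1) {
  set.seed(seed)
  v <- tiny_variants(n_variants, pos = sort(sample.int(1e6, n_variants)))
  h <- matrix(rbinom(2 * n_samples * n_variants, 1, 0.4),
              nrow = 2 * n_samples)
  haplotype_panel(v, paste0("S", seq_len(n_samples)), h)
}

random_manifest <- function(n = 20, seed = 1, chrom = "1") {
  set.seed(seed)
  v <- variant_tbl(paste0("m", seq_len(n)), chrom,
                   sort(sample.int(5e6, n)),
                   rep_len(c("A", "C"), n), rep_len(c("G", "T"), n))
  cats <- lapply(seq_len(n), function(i)
    sample(c("tag", "functional", "interest:gwascat"),
           sample(1:2, 1)))
  array_manifest(v, cats, provenance = "test")
}

# Write a small VCF by hand (independent of the package's writer).
write_raw_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# Independent HWE oracle: direct enumeration of the exact conditional
# distribution from first principles (multinomial over genotype configs).
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Independent LD r2 oracle: direct haplotype counting.
ld_r2_oracle <- function(hap_i, hap_j) {
  pA <- mean(hap_i); pB <- mean(hap_j)
  pAB <- mean(hap_i == 1 & hap_j == 1)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Exhaustive-path oracle for the haploid copying HMM: sums over all K^S
# copying paths; emission only at observed sites; transitions
# (1-r) stay + r/K switch-to-any (self included).
ls_path_oracle <- function(A, pos, obs, rho, eps) {
  K <- ncol(A); S <- nrow(A)
  r <- 1 - exp(-rho * diff(pos))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))
  emit <- function(j, h) {
    if (is.na(obs[j])) 1 else if (A[j, h] == obs[j]) 1 - eps else eps
  }
  w <- apply(paths, 1, function(pth) {
    lp <- log(1 / K) + log(emit(1, pth[1]))
    for (j in 2:S) {
      tr <- r[j - 1] / K + if (pth[j] == pth[j - 1]) 1 - r[j - 1] else 0
      lp <- lp + log(tr) + log(emit(j, pth[j]))
    }
    exp(lp)
  })
  w <- w / sum(w)
  # marginal P(copied allele = 1) per site
  vapply(seq_len(S), function(j) {
    sum(w[A[j, paths[, j]] == 1])
  }, numeric(1))
}
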