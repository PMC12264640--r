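# Independent oracles, coded separately from the package internals, used
# to cross-check the estimators on seeded random instances.

# step-by-step Wright-style ENC estimator over explicit family loops
oracle_enc <- function(counts) {
  code <- cpcub::genetic_code()
  fam_list <- split(code$codon, code$family)
  fam_list[["*"]] <- NULL
  fam_list <- fam_list[vapply(fam_list, length, 1L) >= 2]
  f_vals <- list("2" = c(), "3" = c(), "4" = c(), "6" = c())
  for (f in names(fam_list)) {
    cods <- fam_list[[f]]
    x <- as.numeric(counts[cods])
    n <- sum(x)
    if (n < 2) next
    sum_p2 <- 0
    for (xx in x) sum_p2 <- sum_p2 + (xx / n)^2
    f_hat <- (n * sum_p2 - 1) / (n - 1)
    if (f_hat <= 0) next
    k <- as.character(length(cods))
    f_vals[[k]] <- c(f_vals[[k]], f_hat)
  }
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  f2 <- mean_or_na(f_vals[["2"]])
  f3 <- mean_or_na(f_vals[["3"]])
  f4 <- mean_or_na(f_vals[["4"]])
  f6 <- mean_or_na(f_vals[["6"]])
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- f4
  enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  if (enc > 61) 61 else enc
}

# closed-form OLS from the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# closed-form Pearson correlation from sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# random codon-count table (named over the 64 codons)
random_counts <- function(seed, lambda = 8) {
  set.seed(seed)
  cods <- cpcub::genetic_code()$codon
  x <- stats::rpois(64, lambda)
  names(x) <- cods
  x
}

# substring-multiset check for an inverted repeat of length >= min_len:
# any min_len-mer shared between S and revcomp(S) at disjoint loci
oracle_has_inverted_repeat <- function(s, min_len) {
  L <- nchar(s)
  r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ks <- substring(s, 1:(L - min_len + 1), min_len:L)
  kr <- substring(r, 1:(L - min_len + 1), min_len:L)
  common <- intersect(ks, kr)
  for (km in common) {
    i <- which(ks == km)
    j_r <- which(kr == km)
    j <- L - (j_r + min_len - 1) + 1  # start of the partner copy in s
    for (a in i) for (b in j) {
      if (a + min_len - 1 < b || b + min_len - 1 < a) return(TRUE)
    }
  }
  FALSE
}

# the 14-codon preferred set used in planted-recovery tests (RNA labels)
planted_codon_set <- function() {
  c("UUA", "AUU", "GUA", "UCC", "CCU", "ACU", "GCU", "UAA", "CAA",
    "AAA", "CGU", "AGU", "AGA", "GGU")
}

# a gene whose counts use exactly one codon per multi-codon family,
# every family observed at least twice -> ENC exactly 20
one_codon_per_family_gene <- function(reps = 3) {
  code <- cpcub::genetic_code()
  fams <- split(code$codon, code$family)
  fams[["*"]] <- NULL
  picks <- vapply(fams, function(x) x[[1]], "")
  paste0(paste(rep(picks, each = reps), collapse = ""), "TAA")
}
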