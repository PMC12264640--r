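#' Count codons in a coding sequence
#'
#' Tallies frame-0 codons over the 64-codon table. Codons containing N are
#' skipped (their counts stay zero and the total shrinks accordingly).
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param label Optional label stored on the result.
#' @return An object of class `codon_counts`: named integer vector of
#'   length 64 (TCAG codon order) with attributes `label` and `total`.
#' @examples
#' count_codons("ATGAAATAA")
#' @export
count_codons <- function(cds, label = NULL) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("coding sequence length must be a multiple of 3")
  cods <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  lev <- genetic_code()$codon
  cnt <- table(factor(cods, levels = lev))
  out <- as.integer(cnt)
  names(out) <- lev
  structure(out, label = label, total = sum(out), class = "codon_counts")
}

#' Pool codon counts across genes
#' @param counts_list List of `codon_counts`.
#' @param label Label for the pooled result.
#' @return A `codon_counts` with summed counts.
#' @export
pool_counts <- function(counts_list, label = "pooled") {
  m <- do.call(cbind, lapply(counts_list, unclass))
  out <- as.integer(rowSums(m))
  names(out) <- rownames(m)
  structure(out, label = label, total = sum(out), class = "codon_counts")
}

#' Positional GC content of a coding sequence
#'
#' G+C fraction at codon positions 1, 2 and 3, and their mean GC12 =
#' (GC1+GC2)/2, computed over all codons of the sequence. By default the
#' terminal stop codon is included (whole-sequence convention, as produced
#' by EMBOSS-style codon-usage tools); set `include_stop = FALSE` to drop
#' the final codon.
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param include_stop Include the final codon (default TRUE).
#' @return Named numeric vector `c(gc1, gc2, gc3, gc12)`, fractions in
#'   \eqn{[0, 1]}. Codons containing N are excluded.
#' @export
positional_gc <- function(cds, include_stop = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("coding sequence length must be a multiple of 3")
  cods <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  if (!include_stop) cods <- cods[-length(cods)]
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  if (!length(cods)) stop("no countable codons (all contain N or empty)")
  gc_at <- function(p) mean(substr(cods, p, p) %in% c("G", "C"))
  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2)
}

#' Synonymous third-position GC (GC3s)
#'
#' GC fraction at the third position of synonymous codons only: codons of
#' single-codon families (Met, Trp) and stop codons are excluded. This is
#' the GC3 definition used on the abscissa of the ENC-plot.
#'
#' @param counts A [count_codons()] result.
#' @param code A [genetic_code()].
#' @return Fraction in \eqn{[0, 1]}, or `NA` if no synonymous codons.
#' @export
synonymous_gc3 <- function(counts, code = genetic_code()) {
  keep <- code$family != "*" & code$family_size >= 2
  x <- unclass(counts)[code$codon[keep]]
  if (sum(x) == 0) return(NA_real_)
  third <- substr(code$codon[keep], 3, 3)
  sum(x[third %in% c("G", "C")]) / sum(x)
}

#' Relative synonymous codon usage
#'
#' For codon *j* in a synonymous family of size *n* with counts
#' \eqn{x_{ij}}, RSCU = \eqn{x_{ij} / (\frac{1}{n}\sum_j x_{ij})}: the
#' observed count divided by the count expected under uniform usage within
#' the family. Values of 1 indicate no bias. The stop triplet is treated
#' as a family of 3; single-codon families (Met, Trp) score 1 when the
#' amino acid is present. A family with zero total yields RSCU 0 for all
#' its codons and is flagged `absent`.
#'
#' @param counts A [count_codons()] result (gene or pooled).
#' @param code A [genetic_code()].
#' @return Data frame of class `rscu_table` with columns `codon`, `aa`,
#'   `family_size`, `count`, `rscu`, `absent`.
#' @export
rscu <- function(counts, code = genetic_code()) {
  x <- unclass(counts)[code$codon]
  fam_tot <- tapply(x, code$family, sum)[code$family]
  expected <- fam_tot / code$family_size
  val <- ifelse(fam_tot > 0, x / expected, 0)
  out <- data.frame(codon = code$codon, aa = code$aa,
                    family_size = code$family_size,
                    count = as.integer(x), rscu = as.numeric(val),
                    absent = fam_tot == 0, stringsAsFactors = FALSE)
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Observed effective number of codons (ENC)
#'
#' Wright-style estimator of the effective number of codons. Per
#' multi-codon amino-acid family with \eqn{n \ge 2} codons observed,
#' homozygosity is estimated as \eqn{\hat F = (n \sum \hat p^2 - 1)/(n-1)};
#' class means \eqn{\bar F_2, \bar F_3, \bar F_4, \bar F_6} are taken over
#' usable families (those with \eqn{n \ge 2} and \eqn{\hat F > 0}), and
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' Stop codons and single-codon families are excluded. If the 3-fold class
#' (Ile) is unusable, \eqn{\bar F_3 = (\bar F_2 + \bar F_4)/2}; if the
#' 6-fold class is unusable, \eqn{\bar F_6 = \bar F_4}. The result is
#' capped at 61; values range from 20 (one codon per amino acid) to 61
#' (uniform synonymous usage).
#'
#' @param counts A [count_codons()] result.
#' @param code A [genetic_code()].
#' @return ENC in \eqn{[20, 61]}, or `NA` when no usable 2-fold or 4-fold
#'   family exists.
#' @export
enc_observed <- function(counts, code = genetic_code()) {
  x <- unclass(counts)
  fams <- enc_families(code)
  fhat <- numeric(0)
  fclass <- integer(0)
  for (fam in fams) {
    cods <- code$codon[code$family == fam]
    n <- sum(x[cods])
    if (n < 2) next
    p <- x[cods] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    fhat <- c(fhat, f)
    fclass <- c(fclass, length(cods))
  }
  fbar <- function(k) {
    v <- fhat[fclass == k]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- f4
  enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(enc, 61)
}

#' Expected ENC under pure mutation pressure
#'
#' Closed form for the ENC expected from third-position GC alone:
#' \deqn{ENC_{exp} = 2 + GC3 + 29 / (GC3^2 + (1 - GC3)^2).}
#'
#' @param gc3 Third-position GC as a fraction in \eqn{[0, 1]} (vectorised).
#' @return Expected ENC.
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(gc3) {
  if (any(is.na(gc3)) || any(gc3 < 0 | gc3 > 1)) {
    stop("gc3 must be a fraction in [0, 1]")
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' ENC ratio
#'
#' Relative deviation of observed from expected ENC:
#' (ENCexp - ENCobs) / ENCexp. Values near 0 indicate mutation-dominated
#' codon usage; negative values (observed above expected) are allowed.
#'
#' @param enc_exp Expected ENC (> 0).
#' @param enc_obs Observed ENC.
#' @return Dimensionless ratio.
#' @export
enc_ratio <- function(enc_exp, enc_obs) {
  if (any(enc_exp <= 0, na.rm = TRUE)) stop("enc_exp must be positive")
  (enc_exp - enc_obs) / enc_exp
}

#' Relative-adaptiveness weights for CAI
#'
#' Derives per-codon weights from a reference set of (pooled) codon
#' counts: within each synonymous family, \eqn{w_j = RSCU_j / \max RSCU}.
#' Stop codons and single-codon families carry `NA` (they never enter the
#' CAI), as do codons unobserved in the reference (their weight is
#' undefined rather than zero, so scoring stays in \eqn{(0, 1]}).
#'
#' @param ref_counts A [count_codons()] result for the reference set.
#' @param code A [genetic_code()].
#' @return Named numeric vector of 64 weights in \eqn{(0, 1]} or `NA`.
#' @export
cai_weights <- function(ref_counts, code = genetic_code()) {
  rs <- rscu(ref_counts, code)
  w <- rep(NA_real_, nrow(rs))
  names(w) <- rs$codon
  for (fam in enc_families(code)) {
    idx <- which(code$family == fam)
    mx <- max(rs$rscu[idx])
    if (mx <= 0) next
    w[idx] <- rs$rscu[idx] / mx
  }
  w[w == 0] <- NA_real_
  w
}

#' Codon adaptation index
#'
#' Geometric mean of relative-adaptiveness weights over all counted
#' codons, excluding stop codons, single-codon families, and codons whose
#' weight is undefined in the reference.
#'
#' @param counts A [count_codons()] result for the gene.
#' @param weights Weights from [cai_weights()] (or an external table,
#'   named by codon).
#' @return CAI in \eqn{(0, 1]}, or `NA` when no codon is scorable.
#' @export
cai <- function(counts, weights) {
  x <- unclass(counts)[names(weights)]
  ok <- !is.na(weights) & x > 0
  if (!any(ok)) return(NA_real_)
  exp(sum(x[ok] * log(weights[ok])) / sum(x[ok]))
}

#' PR2 (parity rule 2) coordinates
#'
#' Base parity at the third position of the five strictly fourfold-
#' degenerate families (Val, Pro, Thr, Ala, Gly); the fourfold subsets of
#' the sixfold families are excluded. Returns the plot coordinates
#' x = G3/(G3+C3) and y = A3/(A3+T3); the centre (0.5, 0.5) corresponds
#' to A = T and G = C.
#'
#' @param counts A [count_codons()] result.
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(pr2_x, pr2_y, a3, t3, g3, c3)`;
#'   coordinates are `NA` when their denominator is zero.
#' @export
pr2_point <- function(counts, code = genetic_code()) {
  x <- unclass(counts)
  four <- code$family_size == 4 & code$family != "*"
  cods <- code$codon[four]
  third <- substr(cods, 3, 3)
  tot <- tapply(x[cods], third, sum)
  g3 <- tot[["G"]]; c3 <- tot[["C"]]; a3 <- tot[["A"]]; t3 <- tot[["T"]]
  c(pr2_x = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
    pr2_y = if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_,
    a3 = a3, t3 = t3, g3 = g3, c3 = c3)
}
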