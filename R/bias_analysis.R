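#' Classify a plastid gene by functional category
#'
#' Prefix-based map of the standard plastome functional groups:
#' photosynthesis (psa, psb, ndh, pet, atp, rbcL), self-replication
#' (rpl, rps, rpo, rrn, trn), other (matK, clpP, cemA, accD, ccsA, infA)
#' and unknown (ycf, lhba, anything unrecognised). Matching is
#' case-insensitive on the prefix before the locus suffix.
#'
#' @param gene_name Character vector of gene names.
#' @return Character vector over
#'   `{photosynthesis, self-replication, other, unknown}`.
#' @examples
#' classify_gene_function(c("psbA", "rpoC2", "matK", "ycf3", "fooX"))
#' @export
classify_gene_function <- function(gene_name) {
  nm <- tolower(gene_name)
  pref <- list(
    photosynthesis = c("psa", "psb", "ndh", "pet", "atp", "rbc"),
    `self-replication` = c("rpl", "rps", "rpo", "rrn", "trn"),
    other = c("matk", "clpp", "cema", "accd", "ccsa", "infa"),
    unknown = c("ycf", "lhba")
  )
  out <- rep("unknown", length(nm))
  for (i in seq_along(nm)) {
    for (cat in names(pref)) {
      if (any(startsWith(nm[[i]], pref[[cat]]))) { out[[i]] <- cat; break }
    }
  }
  out
}

#' Per-gene codon-usage metrics table
#'
#' Computes, for every gene in a CDS set: positional GC (GC1/GC2/GC3/GC12,
#' whole-sequence convention), synonymous GC3s, observed ENC, expected ENC
#' (evaluated at GC3s), the ENC ratio, CAI, PR2 third-position counts and
#' coordinates, and the functional category. Genes with undefined ENC are
#' flagged and excluded from the species-level summary means.
#'
#' By default CAI weights are derived from the pooled counts of the
#' strong-bias (lowest-ENC) 10% library of the same set; supply
#' `cai_ref_weights` (a [cai_weights()]-style vector) to override.
#'
#' @param cds_set A [cds_set()] / [extract_cds()] result.
#' @param code A [genetic_code()].
#' @param cai_ref_weights Optional named weight vector.
#' @param include_stop Passed to [positional_gc()].
#' @return Data frame of class `gene_metrics` with one row per gene and a
#'   `summary` attribute holding the species means (GC1, GC2, GC3, ENC,
#'   CAI, over genes with defined ENC).
#' @export
gene_metrics_table <- function(cds_set, code = genetic_code(),
                               cai_ref_weights = NULL,
                               include_stop = TRUE) {
  stopifnot(inherits(cds_set, "cds_set"))
  genes <- cds_set$genes
  if (nrow(genes) == 0L) stop("empty CDS set")
  counts <- lapply(genes$sequence, count_codons)
  names(counts) <- genes$gene
  gc <- t(vapply(genes$sequence, positional_gc, numeric(4),
                 include_stop = include_stop))
  gc3s <- vapply(counts, synonymous_gc3, numeric(1), code = code)
  enc_obs <- vapply(counts, enc_observed, numeric(1), code = code)
  enc_exp <- rep(NA_real_, length(gc3s))
  ok3 <- !is.na(gc3s)
  enc_exp[ok3] <- enc_expected(gc3s[ok3])
  pr2 <- t(vapply(counts, pr2_point, numeric(6), code = code))

  if (is.null(cai_ref_weights)) {
    ok <- which(!is.na(enc_obs))
    ord <- ok[order(enc_obs[ok], genes$gene[ok])]
    tail_n <- max(1L, floor(0.10 * length(ord)))
    ref <- pool_counts(counts[ord[seq_len(tail_n)]], label = "low-ENC 10%")
    cai_ref_weights <- cai_weights(ref, code)
  }
  cai_v <- vapply(counts, cai, numeric(1), weights = cai_ref_weights)

  out <- data.frame(
    gene = genes$gene,
    category = classify_gene_function(genes$gene),
    n_codons = vapply(counts, function(x) attr(x, "total"), numeric(1)),
    gc1 = gc[, "gc1"], gc2 = gc[, "gc2"], gc3 = gc[, "gc3"],
    gc12 = gc[, "gc12"], gc3s = gc3s,
    enc_obs = enc_obs, enc_exp = enc_exp,
    enc_ratio = enc_ratio(enc_exp, enc_obs),
    cai = cai_v,
    a3 = pr2[, "a3"], t3 = pr2[, "t3"], g3 = pr2[, "g3"], c3 = pr2[, "c3"],
    pr2_x = pr2[, "pr2_x"], pr2_y = pr2[, "pr2_y"],
    enc_defined = !is.na(enc_obs),
    stringsAsFactors = FALSE, row.names = NULL
  )
  def <- out$enc_defined
  attr(out, "summary") <- c(
    gc1 = mean(out$gc1[def]), gc2 = mean(out$gc2[def]),
    gc3 = mean(out$gc3[def]), enc = mean(out$enc_obs[def]),
    cai = mean(out$cai[def], na.rm = TRUE)
  )
  attr(out, "species_label") <- cds_set$species_label
  class(out) <- c("gene_metrics", "data.frame")
  out
}

#' Pairwise Pearson correlations between codon-usage metrics
#'
#' Pearson r and raw two-sided p for every pair among the requested
#' metrics (default GC1, GC2, GC3, ENC, CAI), with significance tiers at
#' 0.05 and 0.01 (no multiplicity correction, mirroring the usual starred
#' correlation display). A metric with zero variance yields `NA` for its
#' pairs, flagged in the output.
#'
#' @param table A [gene_metrics_table()] result.
#' @param metrics Column names to correlate.
#' @return Data frame of class `metric_correlations` with columns
#'   `metric1`, `metric2`, `r`, `p`, `tier` (one of `ns`, `0.05`, `0.01`)
#'   and attributes `r_matrix`, `p_matrix`.
#' @export
correlate_metrics <- function(table,
                              metrics = c("gc1", "gc2", "gc3",
                                          "enc_obs", "cai")) {
  dat <- table[table$enc_defined, metrics, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3) stop("need at least 3 genes with defined metrics")
  k <- length(metrics)
  rmat <- matrix(NA_real_, k, k, dimnames = list(metrics, metrics))
  pmat <- rmat
  diag(rmat) <- 1
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- dat[[metrics[i]]]; y <- dat[[metrics[j]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    rmat[i, j] <- rmat[j, i] <- r
    pmat[i, j] <- pmat[j, i] <- p
    tier <- if (is.na(p)) "ns" else if (p < 0.01) "0.01" else
      if (p < 0.05) "0.05" else "ns"
    rows[[length(rows) + 1L]] <- data.frame(
      metric1 = metrics[i], metric2 = metrics[j], r = r, p = p,
      tier = tier, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "r_matrix") <- rmat
  attr(out, "p_matrix") <- pmat
  attr(out, "n") <- nrow(dat)
  class(out) <- c("metric_correlations", "data.frame")
  out
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 on GC3 across genes, both on the
#' fraction scale. A slope near 1 indicates mutation-dominated codon
#' usage; a slope near 0 indicates selection.
#'
#' @param table A [gene_metrics_table()] result (or any data frame with
#'   `gc12` and `gc3` columns).
#' @return Object of class `neutrality_fit`: list with `slope`,
#'   `intercept`, `r`, `r_squared`, `p`, `n`.
#' @export
neutrality_fit <- function(table) {
  dat <- table[stats::complete.cases(table[c("gc3", "gc12")]),
               c("gc3", "gc12")]
  if (nrow(dat) < 3) stop("need at least 3 genes with defined GC values")
  if (stats::sd(dat$gc3) == 0) stop("zero variance in GC3: fit undefined")
  fit <- stats::lm(gc12 ~ gc3, data = dat)
  co <- stats::coef(fit)
  r <- suppressWarnings(stats::cor(dat$gc3, dat$gc12))
  p <- if (stats::sd(dat$gc12) == 0) NA_real_ else
    stats::cor.test(dat$gc3, dat$gc12)$p.value
  structure(list(slope = unname(co[["gc3"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r = if (is.na(r)) 0 else r,
                 r_squared = if (is.na(r)) 0 else r^2,
                 p = p, n = nrow(dat),
                 se_slope = summary(fit)$coefficients["gc3", "Std. Error"]),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality fit (n = %d): GC12 = %.4f x GC3 + %.4f | R^2 = %.5f, p = %.3g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$p))
  invisible(x)
}

#' ENC-ratio histogram with a central band
#'
#' Bins the per-gene ENC ratios into bins of width 0.1 aligned to the
#' central band (default \eqn{[-0.05, 0.05]}, inclusive on both sides).
#' Genes inside the central band have observed ENC close to the mutation-
#' pressure expectation.
#'
#' @param table A [gene_metrics_table()] result.
#' @param band Central band, default `c(-0.05, 0.05)`.
#' @return Object of class `enc_ratio_histogram`: list with `breaks`,
#'   `counts`, `n`, `band`, `band_count`, `band_fraction`.
#' @export
enc_ratio_histogram <- function(table, band = c(-0.05, 0.05)) {
  r <- table$enc_ratio[!is.na(table$enc_ratio)]
  n <- length(r)
  width <- band[2] - band[1]
  if (n == 0) {
    return(structure(list(breaks = band, counts = integer(0), n = 0L,
                          band = band, band_count = 0L,
                          band_fraction = NaN),
                     class = "enc_ratio_histogram"))
  }
  lo <- band[1] - width * ceiling(max(0, band[1] - min(r)) / width)
  hi <- band[2] + width * ceiling(max(0, max(r) - band[2]) / width)
  breaks <- seq(lo, hi, by = width)
  # left-closed bins [a, b); the final bin is closed so counts conserve n
  idx <- pmin(findInterval(r, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  band_count <- sum(r >= band[1] & r <= band[2])
  structure(list(breaks = breaks, counts = counts, n = n, band = band,
                 band_count = band_count, band_fraction = band_count / n),
            class = "enc_ratio_histogram")
}

#' PR2 quadrant summary
#'
#' Counts genes per quadrant of the PR2 plane around the centre
#' (0.5, 0.5): I (x>0.5, y>0.5), II (x<0.5, y>0.5), III (x<0.5, y<0.5),
#' IV (x>0.5, y<0.5). A point exactly on a boundary is assigned to the
#' lowest quadrant index whose closure contains it. Genes with undefined
#' coordinates are counted separately.
#'
#' @param table A [gene_metrics_table()] result.
#' @return Object of class `pr2_summary`: list with `quadrants` (named
#'   counts I-IV), `undefined`, `n`.
#' @export
pr2_summary <- function(table) {
  x <- table$pr2_x; y <- table$pr2_y
  und <- is.na(x) | is.na(y)
  q <- integer(4)
  names(q) <- c("I", "II", "III", "IV")
  for (i in which(!und)) {
    xi <- x[[i]]; yi <- y[[i]]
    cand <- c(I = xi >= 0.5 && yi >= 0.5,
              II = xi <= 0.5 && yi >= 0.5,
              III = xi <= 0.5 && yi <= 0.5,
              IV = xi >= 0.5 && yi <= 0.5)
    qi <- which(cand)[1]  # lowest index among closures containing the point
    q[[qi]] <- q[[qi]] + 1L
  }
  structure(list(quadrants = q, undefined = sum(und), n = length(x)),
            class = "pr2_summary")
}

#' @export
print.pr2_summary <- function(x, ...) {
  cat("PR2 quadrant counts:",
      paste(names(x$quadrants), x$quadrants, sep = "=", collapse = " "),
      sprintf("| undefined=%d | n=%d\n", x$undefined, x$n))
  invisible(x)
}
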