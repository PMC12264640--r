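#' High- and low-expression gene libraries from ENC tails
#'
#' Genes are sorted by observed ENC ascending (ties broken by gene name
#' for determinism) and 10% are taken from each end: the lowest-ENC tail
#' (strongest bias) forms the high-expression library, the highest-ENC
#' tail the low-expression library. Tail size is `max(1, floor(fraction
#' * n))` over genes with defined ENC.
#'
#' @param table A [gene_metrics_table()] result.
#' @param fraction Tail fraction in (0, 0.5); default 0.10.
#' @return Object of class `expression_libraries`: list with `high`,
#'   `low` (gene-name vectors), `fraction`, `tail_size`, `n`.
#' @export
build_expression_libraries <- function(table, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 0.5) stop("fraction must be in (0, 0.5)")
  def <- table[table$enc_defined, c("gene", "enc_obs")]
  n <- nrow(def)
  if (n < 2) stop("need at least 2 genes with defined ENC")
  ord <- def[order(def$enc_obs, def$gene), ]
  k <- max(1L, floor(fraction * n))
  structure(list(high = ord$gene[seq_len(k)],
                 low = ord$gene[seq(n - k + 1L, n)],
                 fraction = fraction, tail_size = k, n = n),
            class = "expression_libraries")
}

#' @export
print.expression_libraries <- function(x, ...) {
  cat(sprintf(
    "<expression_libraries> %d/%d genes per tail (fraction %.2f)\n",
    x$tail_size, x$n, x$fraction))
  invisible(x)
}

#' Per-codon delta-RSCU between two RSCU tables
#'
#' Elementwise RSCU difference (high-expression minus low-expression
#' library), at full precision.
#'
#' @param rscu_high,rscu_low [rscu()] tables over the same code.
#' @return Named numeric vector of 64 differences.
#' @export
delta_rscu <- function(rscu_high, rscu_low) {
  stopifnot(identical(rscu_high$codon, rscu_low$codon))
  stats::setNames(rscu_high$rscu - rscu_low$rscu, rscu_high$codon)
}

#' Optimal-codon report for one species
#'
#' Builds the ENC-tail expression libraries, computes pooled RSCU for the
#' whole set and for each library, takes delta-RSCU = RSCU(high) -
#' RSCU(low), and flags: high-frequency (overall RSCU > 1),
#' high-expression (delta >= `delta_threshold`), and optimal (both).
#'
#' @param cds_set A [cds_set()].
#' @param table Optional precomputed [gene_metrics_table()].
#' @param code A [genetic_code()].
#' @param fraction Tail fraction for the libraries.
#' @param delta_threshold Delta-RSCU threshold, default 0.08.
#' @return Data frame of class `optimal_codon_report` with columns
#'   `codon`, `aa`, `rscu_all`, `rscu_high`, `rscu_low`, `delta_rscu`,
#'   `high_frequency`, `high_expression`, `optimal`; attribute
#'   `species_label`.
#' @export
optimal_codon_report <- function(cds_set, table = NULL,
                                 code = genetic_code(), fraction = 0.10,
                                 delta_threshold = 0.08) {
  if (is.null(table)) table <- gene_metrics_table(cds_set, code)
  libs <- build_expression_libraries(table, fraction)
  counts <- lapply(cds_set$genes$sequence, count_codons)
  names(counts) <- cds_set$genes$gene
  r_all <- rscu(pool_counts(counts), code)
  r_hi <- rscu(pool_counts(counts[libs$high]), code)
  r_lo <- rscu(pool_counts(counts[libs$low]), code)
  d <- delta_rscu(r_hi, r_lo)
  out <- data.frame(
    codon = r_all$codon, aa = r_all$aa,
    rscu_all = r_all$rscu, rscu_high = r_hi$rscu, rscu_low = r_lo$rscu,
    delta_rscu = unname(d),
    absent = r_all$absent,
    stringsAsFactors = FALSE)
  out$high_frequency <- !out$absent & out$rscu_all > 1
  out$high_expression <- out$delta_rscu >= delta_threshold
  out$optimal <- out$high_frequency & out$high_expression
  attr(out, "species_label") <- cds_set$species_label
  attr(out, "libraries") <- libs
  attr(out, "delta_threshold") <- delta_threshold
  class(out) <- c("optimal_codon_report", "data.frame")
  out
}

#' Extract the optimal-codon set from a report
#'
#' Optimal codons satisfy delta-RSCU >= `delta_threshold` and overall
#' RSCU > 1. Comparisons are at full precision by default; with
#' `rounded = TRUE` both quantities are rounded to 2 decimals first
#' (table-reproduction mode, so sets recomputed from printed 2-decimal
#' tables match exactly).
#'
#' @param report An [optimal_codon_report()] result, or any data frame
#'   with `codon`, `rscu_all` (or `rscu`) and `delta_rscu` columns.
#' @param delta_threshold Threshold, default 0.08 (inclusive).
#' @param rounded Apply thresholds to 2-decimal rounded values.
#' @return Character vector of codons.
#' @export
optimal_codon_set <- function(report, delta_threshold = 0.08,
                              rounded = FALSE) {
  rs <- if ("rscu_all" %in% names(report)) report$rscu_all else report$rscu
  d <- report$delta_rscu
  if (rounded) { rs <- round(rs, 2); d <- round(d, 2) }
  absent <- if ("absent" %in% names(report)) report$absent else FALSE
  report$codon[!absent & d >= delta_threshold & rs > 1]
}

#' Shared optimal codons across species
#'
#' Plain intersection of per-species optimal-codon sets, with the
#' third-base ending composition (A/U vs G/C) of the shared set.
#'
#' @param sets List of codon-character vectors (>= 1).
#' @return Character vector of shared codons with attribute `endings`
#'   (counts of third bases) and `n_au`/`n_gc` ending totals.
#' @export
shared_optimal_codons <- function(sets) {
  if (!is.list(sets) || length(sets) < 1) {
    stop("need a non-empty list of codon sets")
  }
  shared <- Reduce(intersect, sets)
  shared <- sort(shared)
  third <- substr(shared, 3, 3)
  endings <- table(factor(third, levels = c("A", "C", "G", "T", "U")))
  structure(shared, endings = endings,
            n_au = sum(endings[c("A", "T", "U")]),
            n_gc = sum(endings[c("G", "C")]))
}

#' Printed per-species RSCU / delta-RSCU table for four Oryza plastomes
#'
#' Loads the published per-codon table shipped with the package (RNA
#' codon labels; delta-RSCU and overall RSCU for *O. rufipogon*,
#' *O. officinalis*, *O. granulata* and *O. sativa*, at the printed
#' 2-decimal precision). Used for table-reproduction analyses.
#'
#' @return Data frame with columns `codon`, `species`, `delta_rscu`,
#'   `rscu` (long format).
#' @export
oryza_printed_rscu <- function() {
  path <- system.file("extdata", "oryza_published_rscu.tsv",
                      package = "cpcub")
  wide <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  species <- c("O_rufipogon", "O_officinalis", "O_granulata", "O_sativa")
  long <- do.call(rbind, lapply(species, function(sp) {
    data.frame(codon = wide$codon, species = sp,
               delta_rscu = wide[[paste0("delta_", sp)]],
               rscu = wide[[paste0("rscu_", sp)]],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Optimal codons from a printed RSCU table
#'
#' Applies the optimal-codon rule (delta-RSCU >= threshold and RSCU > 1)
#' directly to a printed per-species table such as [oryza_printed_rscu()],
#' in table-reproduction (rounded) mode, and intersects across species.
#'
#' @param printed Long data frame with `codon`, `species`, `delta_rscu`,
#'   `rscu`.
#' @param delta_threshold Threshold, default 0.08.
#' @return List with `per_species` (named list of codon sets) and
#'   `shared` (the [shared_optimal_codons()] intersection).
#' @export
optimal_from_printed <- function(printed, delta_threshold = 0.08) {
  sets <- lapply(split(printed, printed$species), function(d) {
    optimal_codon_set(
      data.frame(codon = d$codon, rscu = d$rscu, delta_rscu = d$delta_rscu,
                 stringsAsFactors = FALSE),
      delta_threshold = delta_threshold, rounded = TRUE)
  })
  list(per_species = sets, shared = shared_optimal_codons(sets))
}
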