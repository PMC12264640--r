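#' Genetic code with synonymous-family structure
#'
#' Builds the codon table used by every statistic in the package: the
#' codon-to-amino-acid map, synonymous families (amino acids, plus the stop
#' triplet treated as one family of three), and the degeneracy class of each
#' family. The default is the bacterial/plastid code (translation table 11),
#' whose codon-to-amino-acid assignments coincide with the standard code;
#' it differs only in permitted initiation codons, which the CDS filters in
#' this package handle separately (ATG only).
#'
#' Degeneracy classes: 1-fold (Met, Trp), 2-fold (Phe, Tyr, His, Gln, Asn,
#' Lys, Asp, Glu, Cys), 3-fold (Ile), 4-fold (Val, Pro, Thr, Ala, Gly),
#' 6-fold (Leu, Ser, Arg), and the stop family of size 3.
#'
#' @param table Numeric translation table identifier; only 11 (equivalently
#'   1 for these purposes) is supported.
#' @return An object of class `genetic_code`: a data frame with one row per
#'   codon (DNA alphabet) and columns `codon`, `aa` (one-letter, `*` for
#'   stop), `family` (family label), `family_size`, and `class`
#'   (degeneracy class of the family; stop is reported as class 3).
#' @examples
#' gc <- genetic_code()
#' table(gc$family_size)
#' @export
genetic_code <- function(table = 11) {
  if (!table %in% c(1, 11)) {
    stop("only the standard/plastid code (translation table 11) is supported")
  }
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # standard amino-acid order for TCAG-indexed codons (first base slowest)
  aas <- character(64)
  names(aas) <- codons
  aa_by_codon <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  aa <- unname(aa_by_codon[codons])
  family <- aa
  fam_size <- as.integer(table(family)[family])
  cls <- fam_size
  # the stop family has 3 members but is not a degeneracy class; flag via family
  out <- data.frame(
    codon = codons, aa = aa, family = family,
    family_size = fam_size, class = cls,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genetic_code", "data.frame")
  out
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (translation table 11):", nrow(x), "codons,",
      length(unique(x$family)), "synonymous families\n")
  invisible(x)
}

#' All 64 codons in TCAG order
#' @param code A `genetic_code` object.
#' @return Character vector of 64 DNA codons.
#' @export
codons <- function(code = genetic_code()) code$codon

# families usable for ENC / CAI: multi-codon amino-acid families, no stop
enc_families <- function(code) {
  fams <- unique(code$family[code$family != "*" & code$family_size >= 2])
  fams
}

#' Convert codons between DNA and RNA alphabets
#'
#' Reported codon tables in the literature use the RNA alphabet (U); the
#' package computes in DNA (T). These helpers translate codon labels.
#'
#' @param x Character vector of codons.
#' @return Character vector with T/U substituted.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", x)

# reverse complement of a plain character scalar (ACGTN)
revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# vectorised complement of single bases
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)
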