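#' Amino-acid usage profile for simulated plastid genes
#'
#' A fixed, plausible amino-acid frequency profile for plastid coding
#' sequences, chosen so every degeneracy class (2-, 3-, 4-, 6-fold and the
#' single-codon families) is populated. Used by [simulate_cds_set()];
#' any named profile over the 20 amino acids can be supplied instead.
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes,
#'   summing to 1.
#' @export
plastid_aa_profile <- function() {
  p <- c(L = 0.105, S = 0.075, I = 0.080, F = 0.050, G = 0.070,
         R = 0.050, A = 0.060, T = 0.055, V = 0.060, P = 0.045,
         K = 0.050, N = 0.045, E = 0.050, D = 0.040, Q = 0.035,
         Y = 0.035, H = 0.020, C = 0.011, M = 0.022, W = 0.018)
  p / sum(p)
}

# deterministic child seed below 2^31 (one RNG stream per gene)
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 104729) %% 2147483647
}

# per-family codon weights whose third-position GC equals gc3 exactly:
# GC mass gc3 split over G/C-ending codons, AT mass 1-gc3 over the rest
# (families with only one kind of third base get all mass uniformly)
family_gc3_weights <- function(fam_codons, gc3) {
  third <- substr(fam_codons, 3, 3)
  is_gc <- third %in% c("G", "C")
  w <- numeric(length(fam_codons))
  if (all(is_gc) || all(!is_gc)) {
    w[] <- 1 / length(fam_codons)
  } else {
    w[is_gc] <- gc3 / sum(is_gc)
    w[!is_gc] <- (1 - gc3) / sum(!is_gc)
  }
  w
}

# sample synonymous codons for one family; base NULL means uniform
sample_family_codons <- function(fam_codons, n, gc3_w, preferred, s_i) {
  w <- if (is.null(gc3_w)) rep(1 / length(fam_codons), length(fam_codons))
       else family_gc3_weights(fam_codons, gc3_w)
  hit <- fam_codons %in% preferred
  if (any(hit) && s_i > 0) {
    point <- as.numeric(hit) / sum(hit)
    w <- (1 - s_i) * w + s_i * point
  }
  sample(fam_codons, n, replace = TRUE, prob = w)
}

#' Simulate a coding-sequence set with controlled codon-usage structure
#'
#' Generates genes that pass all CDS filters by construction (ATG start,
#' sampled body without internal stops, stop-codon suffix, length >= 300
#' nt). Three regimes control synonymous-codon choice:
#'
#' * `"mutation"`: third bases are drawn to hit a per-gene target GC3
#'   (codons weighted by third-base composition), so genes fall near the
#'   expected-ENC curve — pure mutation pressure.
#' * `"selection"`: the base synonymous distribution is uniform, mixed
#'   with a point mass on the planted preferred codons with per-gene
#'   weight \eqn{s_i = s \cdot e_i}, where the expression level
#'   \eqn{e_i \sim U(0, 1)} — decouples ENC from GC3 and creates the
#'   high/low-expression contrast the optimal-codon pipeline detects.
#' * `"mixed"`: GC3-weighted base distribution plus the selection mix.
#'
#' One root seed derives a per-gene child seed deterministically, recorded
#' in the ground truth, so identical specs give byte-identical output.
#'
#' @param n_genes Number of genes (default 50).
#' @param len_range Gene length range in codons, including start and stop
#'   (default c(200, 500), minimum 100).
#' @param regime One of "mutation", "selection", "mixed".
#' @param gc3_range Per-gene target GC3 drawn uniformly from this range
#'   (default c(0.25, 0.45)); give a length-1 value for a fixed target.
#' @param preferred Character vector of planted preferred codons (DNA
#'   alphabet), at most one per family is used meaningfully.
#' @param s Selection strength in `[0, 1]` (maximum point-mass weight).
#' @param seed Root seed.
#' @param label Species label for the set.
#' @param aa_profile Amino-acid profile (see [plastid_aa_profile()]).
#' @return A [cds_set()] with attribute `ground_truth`: data frame of
#'   per-gene `gene`, `gc3_target`, `expression`, `s_i`, `seed`, plus
#'   attributes `preferred` and `s`.
#' @export
simulate_cds_set <- function(n_genes = 50, len_range = c(200, 500),
                             regime = c("mutation", "selection", "mixed"),
                             gc3_range = c(0.25, 0.45), preferred = NULL,
                             s = 0, seed = 1, label = "synthetic",
                             aa_profile = plastid_aa_profile()) {
  regime <- match.arg(regime)
  if (min(len_range) < 100) stop("gene length must be >= 100 codons")
  if (s < 0 || s > 1) stop("selection strength s must be in [0, 1]")
  if (length(gc3_range) == 1) gc3_range <- rep(gc3_range, 2)
  if (any(gc3_range < 0 | gc3_range > 1)) stop("gc3 targets must be in [0, 1]")
  if (!is.null(preferred)) {
    preferred <- toupper(to_dna(preferred))
    if (!all(preferred %in% genetic_code()$codon)) {
      stop("preferred codons must be valid codons")
    }
  }
  code <- genetic_code()
  fam_codons <- split(code$codon, code$family)
  aa_profile <- aa_profile / sum(aa_profile)

  genes <- vector("list", n_genes)
  gt <- data.frame(gene = character(n_genes), gc3_target = NA_real_,
                   expression = NA_real_, s_i = NA_real_, seed = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    cs <- child_seed(seed, i)
    set.seed(cs)
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(seq(len_range[1], len_range[2]), 1)
    gc3_t <- stats::runif(1, gc3_range[1], gc3_range[2])
    e_i <- stats::runif(1)
    s_i <- if (regime == "mutation") 0 else s * e_i
    base_gc3 <- if (regime == "selection") NULL else gc3_t
    n_internal <- len - 2L
    aas <- sample(names(aa_profile), n_internal, replace = TRUE,
                  prob = aa_profile)
    cods <- character(n_internal)
    for (fam in unique(aas)) {
      idx <- which(aas == fam)
      cods[idx] <- sample_family_codons(fam_codons[[fam]], length(idx),
                                        base_gc3, preferred, s_i)
    }
    stop_cod <- sample_family_codons(fam_codons[["*"]], 1, base_gc3,
                                     preferred, s_i)
    genes[[i]] <- paste0("ATG", paste(cods, collapse = ""), stop_cod)
    gt$gene[i] <- sprintf("gene%03d", i)
    gt$gc3_target[i] <- gc3_t
    gt$expression[i] <- e_i
    gt$s_i[i] <- s_i
    gt$seed[i] <- cs
  }
  out <- cds_set(stats::setNames(unlist(genes), gt$gene),
                 species_label = label,
                 provenance = sprintf("simulate_cds_set(seed=%s)", seed))
  attr(gt, "preferred") <- preferred
  attr(gt, "s") <- s
  attr(gt, "regime") <- regime
  attr(out, "ground_truth") <- gt
  out
}

# random sequence with target GC (G and C equiprobable, A and T too)
random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a circular genome with a planted quadripartite structure
#'
#' Builds genome = LSC + IRa + SSC + reverse-complement(IRa) with
#' per-region GC targets, plants valid CDS features (>= 300 nt, ATG/stop)
#' inside each region, and mirrors IR-planted genes into the second
#' repeat copy (minus strand, same name). Junction bases are adjusted so
#' the planted repeat cannot be extended by chance, making the planted
#' region lengths exactly recoverable.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp (IR >= 1000).
#' @param gc Named numeric `c(lsc=, ssc=, ir=)` GC fractions.
#' @param n_cds Named integer `c(lsc=, ssc=, ir=)` CDS planted per region.
#' @param seed Root seed.
#' @param id Record id.
#' @return A circular [seq_record()] with attribute `ground_truth`
#'   (planted lengths and gene names).
#' @export
simulate_quadripartite_genome <- function(lsc_len = 10000, ssc_len = 1000,
                                          ir_len = 2000,
                                          gc = c(lsc = 0.37, ssc = 0.33,
                                                 ir = 0.44),
                                          n_cds = c(lsc = 2, ssc = 1,
                                                    ir = 1),
                                          seed = 1,
                                          id = "synthetic_plastome") {
  if (ir_len < 1000) stop("ir_len must be >= 1000")
  set.seed(child_seed(seed, 0))
  lsc <- random_seq(lsc_len, gc[["lsc"]])
  ssc <- random_seq(ssc_len, gc[["ssc"]])
  ira <- random_seq(ir_len, gc[["ir"]])

  total_cds <- sum(n_cds)
  planted <- if (total_cds > 0) {
    simulate_cds_set(n_genes = total_cds, len_range = c(100, 130),
                     regime = "mutation", gc3_range = c(0.3, 0.4),
                     seed = child_seed(seed, 1), label = id)
  } else NULL

  # place CDS sequences inside a region string, sequentially with margins
  margin <- 20L
  place <- function(region, seqs) {
    pos <- margin
    starts <- integer(length(seqs))
    for (j in seq_along(seqs)) {
      w <- nchar(seqs[[j]])
      if (pos + w + margin > nchar(region)) {
        stop("planted CDS features overlap or exceed region length")
      }
      substr(region, pos + 1L, pos + w) <- seqs[[j]]
      starts[[j]] <- pos  # 0-based within region
      pos <- pos + w + margin
    }
    list(region = region, starts = starts)
  }
  gidx <- 0L
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- planted$genes$sequence[gidx + seq_len(k)]
    gidx <<- gidx + k
    out
  }
  seq_lsc <- take(n_cds[["lsc"]])
  seq_ssc <- take(n_cds[["ssc"]])
  seq_ir <- take(n_cds[["ir"]])
  pl <- place(lsc, seq_lsc); lsc <- pl$region; st_lsc <- pl$starts
  ps <- place(ssc, seq_ssc); ssc <- ps$region; st_ssc <- ps$starts
  pi_ <- place(ira, seq_ir); ira <- pi_$region; st_ir <- pi_$starts

  irb <- revcomp_chr(ira)
  genome <- paste0(lsc, ira, ssc, irb)
  L <- nchar(genome)
  l <- lsc_len; m <- ir_len; sc <- ssc_len
  # forbid chance extension of the planted repeat at all four junctions:
  # outward (last LSC base vs first LSC base across the origin) and
  # inward (first SSC base vs last SSC base)
  fix_pair <- function(g, p1, p2) {
    b1 <- substr(g, p1, p1); b2 <- substr(g, p2, p2)
    if (b1 == comp_base(b2)) substr(g, p2, p2) <- b1
    g
  }
  genome <- fix_pair(genome, 1L, l)                 # S[l-1] vs comp(S[0])
  genome <- fix_pair(genome, l + m + 1L, l + m + sc)  # SSC first vs last

  feats <- list()
  add_cds <- function(name, start, len, strand = "+") {
    feats[[length(feats) + 1L]] <<- feature(name, "CDS",
                                            matrix(c(start, start + len),
                                                   ncol = 2),
                                            strand = strand)
  }
  nm <- planted$genes$gene
  ni <- 0L
  for (j in seq_along(st_lsc)) {
    ni <- ni + 1L
    add_cds(nm[[ni]], st_lsc[[j]], nchar(seq_lsc[[j]]))
  }
  for (j in seq_along(st_ir)) {
    ni <- ni + 1L
    w <- nchar(seq_ir[[j]])
    add_cds(nm[[ni]], l + st_ir[[j]], w)
    # mirrored copy in IRb, minus strand
    irb_start <- l + m + sc + (m - st_ir[[j]] - w)
    add_cds(nm[[ni]], irb_start, w, strand = "-")
  }
  for (j in seq_along(st_ssc)) {
    ni <- ni + 1L
    add_cds(nm[[ni]], l + m + st_ssc[[j]], nchar(seq_ssc[[j]]))
  }
  rec <- seq_record(id, genome, circular = TRUE, features = feats)
  attr(rec, "ground_truth") <- list(
    lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
    genes = nm[seq_len(ni)], n_unique_cds = ni)
  rec
}

#' Write a simulated object to a plain-text fixture
#'
#' @param x A [seq_record()] (formats "fasta", "genbank") or [cds_set()]
#'   (format "tsv": columns `gene`, `sequence`).
#' @param path Output path.
#' @param format One of "fasta", "genbank", "tsv".
#' @return `path`, invisibly.
#' @export
write_fixture <- function(x, path, format = c("fasta", "genbank", "tsv")) {
  format <- match.arg(format)
  switch(format,
    fasta = write_fasta(x, path),
    genbank = write_genbank(x, path),
    tsv = {
      stopifnot(inherits(x, "cds_set"))
      utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(path)
}
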