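#' Sequence records and features
#'
#' A `seq_record` is the package's genome container: an identifier, an
#' uppercase nucleotide sequence over A/C/G/T/N, a circular-topology flag,
#' and an ordered list of annotated features. Coordinates are held 0-based
#' half-open internally; all user-facing reports are 1-based inclusive
#' (GenBank convention).
#'
#' @param id Accession or name.
#' @param seq Nucleotide string.
#' @param circular Logical; circular topology.
#' @param features List of features built with [feature()].
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, circular = FALSE, features = list()) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("sequence must be non-empty")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0) {
    stop(sprintf("invalid character '%s' at position %d in record '%s'",
                 substr(seq, bad, bad), bad, id))
  }
  structure(list(id = id, seq = seq, circular = circular,
                 features = features),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp, %s, %d features\n", x$id,
              nchar(x$seq), if (x$circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

#' @param gene Gene name.
#' @param type Feature type: "CDS", "tRNA", "rRNA" or "other".
#' @param intervals Integer matrix with columns `start`, `end`
#'   (0-based half-open), one row per exon in splice order.
#' @param strand "+" or "-".
#' @param pseudo Logical pseudogene flag.
#' @rdname seq_record
#' @export
feature <- function(gene, type = "CDS", intervals, strand = "+",
                    pseudo = FALSE) {
  intervals <- matrix(as.integer(intervals), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  if (any(intervals[, 2] <= intervals[, 1])) {
    stop("feature intervals must satisfy start < end (0-based half-open)")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  type <- if (type %in% c("CDS", "tRNA", "rRNA")) type else "other"
  structure(list(gene = gene, type = type, intervals = intervals,
                 strand = strand, pseudo = isTRUE(pseudo)),
            class = "cp_feature")
}

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet;
#' any other character is rejected with its position. Duplicate record ids
#' are an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param circular Logical, applied to every record (FASTA carries no
#'   topology).
#' @return A list of [seq_record()] objects in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1]])
  recs <- lapply(seq_along(set), function(i) {
    seq_record(ids[[i]], as.character(set[[i]]), circular = circular)
  })
  recs
}

#' Write records to FASTA
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$seq
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ---- GenBank flat-file parsing -------------------------------------------
# Minimal parser for LOCUS / FEATURES / ORIGIN with join() / complement()
# locations; enough for annotated plastome records and the fixtures this
# package writes. Coordinates are converted to 0-based half-open.

parse_gb_location <- function(loc, seq_len, circular) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- rep(as.integer(p), 2)
    }
    se
  }, integer(2)))
  if (any(is.na(iv))) stop("unparseable location: ", loc)
  if (any(iv[, 2] > seq_len) || any(iv[, 1] < 1)) {
    stop("feature location exceeds sequence length (", seq_len, "): ", loc)
  }
  # to 0-based half-open
  iv[, 1] <- iv[, 1] - 1L
  list(intervals = iv, strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS (length, circular/linear topology), FEATURES (CDS, tRNA,
#' rRNA and other features with `join`/`complement` locations, `/gene`,
#' `/locus_tag` and `/pseudo` qualifiers) and ORIGIN. A feature whose
#' location exceeds the sequence length is an error, as is a missing
#' ORIGIN section.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @return A [seq_record()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("GenBank format error: no LOCUS line")
  locus <- lines[locus_i[[1]]]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][[1]]
  circular <- grepl("circular", locus, ignore.case = TRUE)

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("GenBank format error: missing ORIGIN")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[[1]]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[[1]] + 1L):(end_i - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0L) stop("GenBank format error: empty ORIGIN")

  feats <- list()
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i)) {
    block <- lines[(feat_i[[1]] + 1L):(origin_i[[1]] - 1L)]
    # feature keys start at column 6; qualifier/location continuations at 22
    key_rows <- grep("^ {5}\\S", block)
    for (j in seq_along(key_rows)) {
      from <- key_rows[[j]]
      to <- if (j < length(key_rows)) key_rows[[j + 1]] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[[1]])
      if (key == "source") next
      body <- trimws(c(sub("^\\s*\\S+\\s*", "", chunk[[1]]), chunk[-1]))
      qual_start <- grep("^/", body)
      loc_end <- if (length(qual_start)) qual_start[[1]] - 1L else length(body)
      loc <- paste(body[seq_len(loc_end)], collapse = "")
      quals <- body[grep("^/", body)]
      gene <- sub('^/(gene|locus_tag)="?([^"]*)"?$', "\\2",
                  grep('^/(gene|locus_tag)=', quals, value = TRUE))
      gene <- if (length(gene)) gene[[1]] else key
      pseudo <- any(grepl("^/pseudo\\b", quals))
      parsed <- parse_gb_location(loc, nchar(seq), circular)
      type <- if (key %in% c("CDS", "tRNA", "rRNA")) key else "other"
      if (key == "gene") next  # gene features duplicate CDS/tRNA/rRNA spans
      feats[[length(feats) + 1L]] <- feature(
        gene = gene, type = type, intervals = parsed$intervals,
        strand = parsed$strand, pseudo = pseudo)
    }
  }
  seq_record(id, seq, circular = circular, features = feats)
}

#' Write a minimal GenBank flat file
#'
#' Emits LOCUS (with topology), FEATURES (CDS with `/gene`, using
#' `join`/`complement` as needed) and ORIGIN, re-readable by
#' [read_genbank()].
#'
#' @param record A [seq_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- nchar(record$seq)
  topo <- if (record$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     record$id, L, topo, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s synthetic record.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (f in record$features) {
    iv <- f$intervals
    spans <- sprintf("%d..%d", iv[, 1] + 1L, iv[, 2])
    loc <- if (nrow(iv) > 1) paste0("join(", paste(spans, collapse = ","), ")") else spans
    if (f$strand == "-") loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-15s %s", f$type, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
    if (f$pseudo) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(record$seq, p, min(p + 59, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# circular substring: 0-based start, length len, wraps past the end
region_seq <- function(record, start, len) {
  L <- nchar(record$seq)
  start <- start %% L
  if (start + len <= L) {
    substr(record$seq, start + 1, start + len)
  } else {
    paste0(substr(record$seq, start + 1, L),
           substr(record$seq, 1, start + len - L))
  }
}

# ---- quadripartite structure ---------------------------------------------

# maximal inverted-repeat pair via k-mer seeding on S vs revcomp(S),
# diagonal run grouping, then maximal (circular) extension.
find_ir_pair <- function(seq, circular, min_ir_len, max_mismatch = 0, k = 25) {
  L <- nchar(seq)
  if (L < 2 * min_ir_len) return(NULL)
  R <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n <- L - k + 1L
  kS <- substring(seq, 1:n, k:L)
  kR <- substring(R, 1:n, k:L)
  dS <- data.table::data.table(kmer = kS, i = 1:n)
  dR <- data.table::data.table(kmer = kR, x = 1:n)
  # drop hyper-repetitive seeds (low complexity) to bound the join
  tab <- table(dS$kmer)
  busy <- names(tab)[tab > 8]
  if (length(busy)) {
    dS <- dS[!dS$kmer %in% busy, ]
    dR <- dR[!dR$kmer %in% busy, ]
  }
  hits <- merge(dS, dR, by = "kmer", allow.cartesian = TRUE)
  if (!nrow(hits)) return(NULL)
  hits[, d := i - x]
  data.table::setorder(hits, d, i)
  hits[, run := cumsum(c(1L, diff(i) != 1L)), by = "d"]
  runs <- hits[, list(i1 = min(i), i2 = max(i)), by = c("d", "run")]
  runs[, len := i2 - i1 + k]
  # with mismatches a repeat may be split into shorter exact runs
  runs <- runs[runs$len >= min_ir_len - max_mismatch * (k + 1L) * 2L, ]
  if (!nrow(runs)) return(NULL)
  data.table::setorder(runs, -len, i1)
  runs <- runs[seq_len(min(nrow(runs), 200)), ]

  sget <- function(p) substr(seq, p, p)
  best <- NULL
  seen <- character(0)
  for (ri in seq_len(nrow(runs))) {
    i1 <- runs$i1[[ri]]; i2 <- runs$i2[[ri]]; d <- runs$d[[ri]]
    # S segment [a1, a2], partner S segment [b1, b2] (1-based inclusive)
    a1 <- i1; a2 <- i2 + k - 1L
    b1 <- L - (i2 - d) - k + 2L; b2 <- L - (i1 - d) + 1L
    if (a1 > b1) { tmp <- c(a1, a2); a1 <- b1; a2 <- b2; b1 <- tmp[1]; b2 <- tmp[2] }
    if (a2 >= b1) next  # self-overlapping (palindrome on one locus)
    # extend outward: left end of copy A pairs with right end of copy B;
    # origin-wrapping repeats are caught by the caller's rotation retry
    mm <- 0L
    while (a1 > 1L && b2 < L) {
      pa <- a1 - 1L; pb <- b2 + 1L
      if (sget(pa) == comp_base(sget(pb))) { a1 <- pa; b2 <- pb }
      else if (mm < max_mismatch) { mm <- mm + 1L; a1 <- pa; b2 <- pb }
      else break
    }
    # extend inward ends (right end of A pairs with left end of B)
    while (a2 + 1L < b1 - 1L) {
      pa <- a2 + 1L; pb <- b1 - 1L
      if (sget(pa) == comp_base(sget(pb))) { a2 <- pa; b1 <- pb }
      else if (mm < max_mismatch) { mm <- mm + 1L; a2 <- pa; b1 <- pb }
      else break
    }
    len <- a2 - a1 + 1L
    if (len < min_ir_len) next
    key <- paste(a1, a2, b1, b2)
    if (key %in% seen) next
    seen <- c(seen, key)
    cand <- list(a = c(a1, a2), b = c(b1, b2), len = len)
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && cand$a[1] < best$a[1])) best <- cand
  }
  best
}

#' Detect the quadripartite structure of a plastome
#'
#' Finds the maximal pair of disjoint inverted repeats (exact match by
#' default) on a circular genome via k-mer seeding and maximal extension,
#' then labels the longer single-copy gap LSC and the shorter SSC, and
#' computes per-region GC. The two IR copies are identical under
#' `max_mismatch = 0`, so IR GC is reported once.
#'
#' @param record A circular [seq_record()].
#' @param min_ir_len Minimum inverted-repeat length in bp (default 1000,
#'   must be >= 100).
#' @param max_mismatch Mismatches allowed during extension (default 0).
#' @return An object of class `quadripartite` with elements `lsc`, `ssc`,
#'   `ira`, `irb` (each `c(start, length)` with a 0-based circular start),
#'   `gc_lsc`, `gc_ssc`, `gc_ir` (percent) and `genome_length`; or `NULL`
#'   (with a message) when no repeat of the required length exists.
#' @export
detect_quadripartite <- function(record, min_ir_len = 1000, max_mismatch = 0) {
  stopifnot(inherits(record, "seq_record"))
  if (min_ir_len < 100) stop("min_ir_len must be >= 100")
  L <- nchar(record$seq)
  pair <- find_ir_pair(record$seq, record$circular, min_ir_len, max_mismatch)
  if (record$circular) {
    # a repeat spanning the origin is truncated by the linear scan; it
    # cannot span the origin in both the original and a half-rotated copy
    off <- L %/% 2
    rot <- paste0(substr(record$seq, off + 1, L), substr(record$seq, 1, off))
    pair2 <- find_ir_pair(rot, TRUE, min_ir_len, max_mismatch)
    if (!is.null(pair2)) {
      pair2$a <- ((pair2$a - 1L + off) %% L) + 1L
      pair2$b <- ((pair2$b - 1L + off) %% L) + 1L
      if (is.null(pair) || pair2$len > pair$len) pair <- pair2
    }
  }
  if (is.null(pair)) {
    message("no quadripartite structure: no inverted repeat >= ",
            min_ir_len, " bp in ", record$id)
    return(NULL)
  }
  ir_len <- pair$len
  # 0-based circular starts of the two copies (ends may wrap)
  sa <- (pair$a[1] - 1L) %% L
  sb <- (pair$b[1] - 1L) %% L
  if (sb < sa) { tmp <- sa; sa <- sb; sb <- tmp }
  # gaps on the circle between the copies
  gap1_start <- (sa + ir_len) %% L
  gap1_len <- (sb - sa - ir_len) %% L
  gap2_start <- (sb + ir_len) %% L
  gap2_len <- (sa - sb - ir_len) %% L
  a <- c(sa + 1L, sa + ir_len)  # 1-based for GC below (region_seq wraps)
  if (gap1_len >= gap2_len) {
    lsc <- c(gap1_start, gap1_len); ssc <- c(gap2_start, gap2_len)
  } else {
    lsc <- c(gap2_start, gap2_len); ssc <- c(gap1_start, gap1_len)
  }
  gc_pct <- function(start, len) {
    if (len == 0) return(NA_real_)
    s <- region_seq(record, start, len)
    cnt <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c("A", "C", "G", "T", "N")))
    denom <- sum(cnt[c("A", "C", "G", "T")])
    100 * sum(cnt[c("G", "C")]) / denom
  }
  structure(list(
    ira = c(start = sa, length = ir_len),
    irb = c(start = sb, length = ir_len),
    lsc = c(start = lsc[1], length = lsc[2]),
    ssc = c(start = ssc[1], length = ssc[2]),
    gc_lsc = gc_pct(lsc[1], lsc[2]),
    gc_ssc = gc_pct(ssc[1], ssc[2]),
    gc_ir = gc_pct(a[1] - 1L, ir_len),
    genome_length = L
  ), class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf(
    "<quadripartite> total %d bp | LSC %d bp (GC %.2f%%) | SSC %d bp (GC %.2f%%) | IR %d bp (GC %.2f%%)\n",
    x$genome_length, x$lsc[["length"]], x$gc_lsc, x$ssc[["length"]],
    x$gc_ssc, x$ira[["length"]], x$gc_ir))
  invisible(x)
}

#' Per-region GC content
#'
#' GC = (G+C)/(A+C+G+T) per region, as a percentage; N is excluded from the
#' denominator.
#'
#' @param record The [seq_record()] the structure was derived from.
#' @param structure A [detect_quadripartite()] result.
#' @return Named numeric vector `c(lsc, ssc, ir)` of GC percentages.
#' @export
region_gc <- function(record, structure) {
  stopifnot(inherits(structure, "quadripartite"))
  if (structure$genome_length != nchar(record$seq)) {
    stop("structure does not match record length")
  }
  gc_one <- function(start, len) {
    s <- region_seq(record, start, len)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    cnt <- table(factor(v, levels = c("A", "C", "G", "T", "N")))
    100 * sum(cnt[c("G", "C")]) / sum(cnt[c("A", "C", "G", "T")])
  }
  c(lsc = gc_one(structure$lsc[["start"]], structure$lsc[["length"]]),
    ssc = gc_one(structure$ssc[["start"]], structure$ssc[["length"]]),
    ir = gc_one(structure$ira[["start"]], structure$ira[["length"]]))
}

# ---- CDS extraction -------------------------------------------------------

# splice a feature from its record (strand-aware, circular-safe)
splice_feature <- function(record, feat) {
  parts <- apply(feat$intervals, 1, function(iv) {
    substr(record$seq, iv[[1]] + 1L, iv[[2]])
  })
  s <- paste(parts, collapse = "")
  if (feat$strand == "-") s <- revcomp_chr(s)
  s
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# apply the CDS retention filters; returns cleaned sequence or NA
filter_cds_seq <- function(s, code, max_n_codon_frac = 0.05) {
  if (nchar(s) %% 3 != 0) return(NA_character_)
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  has_n <- grepl("N", cods, fixed = TRUE)
  if (any(has_n)) {
    if (mean(has_n) > max_n_codon_frac) return(NA_character_)
    cods <- cods[!has_n]
  }
  if (length(cods) * 3 < 300) return(NA_character_)
  if (cods[[1]] != "ATG") return(NA_character_)
  if (!cods[[length(cods)]] %in% STOP_CODONS) return(NA_character_)
  aa <- code$aa[match(cods, code$codon)]
  if (any(aa[-length(aa)] == "*")) return(NA_character_)
  paste(cods, collapse = "")
}

#' Extract the filtered coding-sequence set from an annotated record
#'
#' Splices every CDS feature (strand-aware, across the origin of circular
#' records), then retains only sequences that pass all filters: length
#' >= 300 nt and a multiple of 3, ATG start, TAA/TAG/TGA stop, and no
#' internal stop. Codons containing N are dropped before the length test;
#' a CDS losing more than 5% of its codons is discarded. Genes duplicated
#' in the inverted repeats are deduplicated by (name, sequence), keeping
#' the first; identical names with differing sequences are kept with
#' suffixed names.
#'
#' @param record A [seq_record()] with CDS features.
#' @param code A [genetic_code()].
#' @param min_len Minimum retained length in nucleotides (default 300).
#' @return An object of class `cds_set`: list with `species_label`,
#'   `genes` (data frame of `gene`, `sequence`) and `provenance`.
#' @export
extract_cds <- function(record, code = genetic_code(), min_len = 300) {
  feats <- Filter(function(f) f$type == "CDS" && !f$pseudo, record$features)
  if (!length(feats)) stop("record has no CDS features")
  rows <- list()
  for (f in feats) {
    s <- splice_feature(record, f)
    s2 <- tryCatch(filter_cds_seq(s, code), error = function(e) NA_character_)
    if (is.na(s2) || nchar(s2) < min_len) next
    rows[[length(rows) + 1L]] <- data.frame(gene = f$gene, sequence = s2,
                                            stringsAsFactors = FALSE)
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), sequence = character(0),
               stringsAsFactors = FALSE)
  # deduplicate IR copies: identical (name, sequence) keeps the first
  genes <- genes[!duplicated(genes[c("gene", "sequence")]), , drop = FALSE]
  # same name, different sequence: suffix for uniqueness
  if (anyDuplicated(genes$gene)) {
    genes$gene <- make.unique(genes$gene, sep = "_")
  }
  rownames(genes) <- NULL
  if (nrow(genes) == 0L) {
    warning("no CDS survived the filters for record ", record$id)
  }
  structure(list(species_label = record$id, genes = genes,
                 provenance = record$id),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("<cds_set> %s: %d genes (from %s)\n", x$species_label,
              nrow(x$genes), x$provenance))
  invisible(x)
}

#' Build a cds_set directly from gene sequences
#' @param genes Named character vector or data frame with `gene`, `sequence`.
#' @param species_label Label for the set.
#' @param provenance Source note.
#' @return A `cds_set`.
#' @export
cds_set <- function(genes, species_label = "set", provenance = "in-memory") {
  if (is.character(genes)) {
    genes <- data.frame(gene = names(genes), sequence = unname(genes),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "sequence") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("gene names must be unique")
  structure(list(species_label = species_label,
                 genes = genes[c("gene", "sequence")],
                 provenance = provenance),
            class = "cds_set")
}

#' Rotate the origin of a circular record
#'
#' Moves the origin forward by `offset` bases, remapping all feature
#' coordinates; intervals that come to span the new origin are split into
#' two adjacent intervals so splice order is preserved.
#'
#' @param record A circular [seq_record()].
#' @param offset Rotation in bases.
#' @return The rotated [seq_record()].
#' @export
rotate_record <- function(record, offset) {
  stopifnot(record$circular)
  L <- nchar(record$seq)
  offset <- offset %% L
  if (offset == 0) return(record)
  newseq <- paste0(substr(record$seq, offset + 1, L),
                   substr(record$seq, 1, offset))
  shift_iv <- function(iv) {
    out <- list()
    for (r in seq_len(nrow(iv))) {
      s <- (iv[r, 1] - offset) %% L
      e <- s + (iv[r, 2] - iv[r, 1])
      if (e <= L) {
        out[[length(out) + 1L]] <- c(s, e)
      } else {  # wraps: split at origin
        out[[length(out) + 1L]] <- c(s, L)
        out[[length(out) + 1L]] <- c(0L, e - L)
      }
    }
    do.call(rbind, out)
  }
  feats <- lapply(record$features, function(f) {
    feature(f$gene, f$type, shift_iv(f$intervals), f$strand, f$pseudo)
  })
  seq_record(record$id, newseq, circular = TRUE, features = feats)
}

#' Fetch a GenBank record from NCBI (plumbing, requires network)
#'
#' Thin convenience wrapper around NCBI efetch for users who want to run
#' the pipeline on deposited accessions; untested plumbing, not used by any
#' computation in the package.
#'
#' @param accession NCBI nucleotide accession.
#' @param path Destination file (default: tempfile).
#' @param timeout Seconds before giving up.
#' @return Path to the downloaded flat file.
#' @export
fetch_genbank <- function(accession, path = tempfile(fileext = ".gb"),
                          timeout = 60) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession,
                "&rettype=gbwithparts&retmode=text")
  old <- options(timeout = timeout)
  on.exit(options(old))
  utils::download.file(url, path, quiet = TRUE, mode = "wb")
  path
}
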