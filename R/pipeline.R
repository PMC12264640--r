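#' Quadripartite structure report for one or more genomes
#'
#' Runs [detect_quadripartite()] and [region_gc()] on each input and
#' writes one TSV per genome with columns `region`, `start`, `end`,
#' `length`, `gc_percent` (1-based inclusive coordinates; GC rounded to 2
#' decimals). A genome without a detectable structure produces an `NA`
#' row with a warning.
#'
#' @param inputs Character paths (FASTA or GenBank, chosen by extension)
#'   or a list of [seq_record()] objects.
#' @param out_dir Output directory (created if needed).
#' @param min_ir_len,max_mismatch Passed to [detect_quadripartite()].
#' @param circular Topology assumed for FASTA inputs.
#' @return Invisibly, a named list of per-genome data frames.
#' @export
run_structure <- function(inputs, out_dir = ".", min_ir_len = 1000,
                          max_mismatch = 0, circular = TRUE) {
  recs <- load_records(inputs, circular)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (rec in recs) {
    st <- detect_quadripartite(rec, min_ir_len, max_mismatch)
    df <- structure_table(rec, st)
    utils::write.table(df, file.path(out_dir,
                                     paste0(rec$id, "_structure.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[rec$id]] <- df
  }
  write_manifest(out_dir, "structure",
                 list(min_ir_len = min_ir_len, max_mismatch = max_mismatch),
                 names(out))
  invisible(out)
}

structure_table <- function(rec, st) {
  if (is.null(st)) {
    warning("no quadripartite structure for ", rec$id)
    return(data.frame(region = NA_character_, start = NA, end = NA,
                      length = NA, gc_percent = NA))
  }
  L <- st$genome_length
  row <- function(name, iv, gcv) {
    s0 <- iv[["start"]]
    data.frame(region = name, start = s0 + 1L,
               end = ((s0 + iv[["length"]] - 1L) %% L) + 1L,
               length = iv[["length"]], gc_percent = round(gcv, 2),
               stringsAsFactors = FALSE)
  }
  rbind(row("LSC", st$lsc, st$gc_lsc), row("SSC", st$ssc, st$gc_ssc),
        row("IRa", st$ira, st$gc_ir), row("IRb", st$irb, st$gc_ir))
}

load_records <- function(inputs, circular = TRUE) {
  if (inherits(inputs, "seq_record")) return(list(inputs))
  if (is.list(inputs)) return(inputs)
  recs <- list()
  for (p in inputs) {
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("gb", "gbk", "genbank")) {
      recs[[length(recs) + 1L]] <- read_genbank(p)
    } else {
      recs <- c(recs, read_fasta(p, circular = circular))
    }
  }
  recs
}

#' Full codon-usage report for one species
#'
#' Extracts (or accepts) the filtered CDS set, assembles the per-gene
#' metrics table, and writes the four diagnostics: metric correlations,
#' neutrality fit, ENC-ratio histogram and PR2 quadrant summary, plus the
#' pooled RSCU table. TSV outputs and a JSON manifest go to `out_dir`.
#'
#' @param input A [seq_record()], [cds_set()], or path (GenBank/FASTA/TSV
#'   gene table).
#' @param out_dir Output directory.
#' @param code A [genetic_code()].
#' @param include_stop Positional-GC convention flag.
#' @return Invisibly, a list with `table`, `correlations`, `neutrality`,
#'   `enc_hist`, `pr2`, `rscu_pooled`.
#' @export
run_codon_report <- function(input, out_dir = ".", code = genetic_code(),
                             include_stop = TRUE) {
  cds <- as_cds_set(input, code)
  if (nrow(cds$genes) == 0L) stop("empty CDS set: nothing to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- gene_metrics_table(cds, code, include_stop = include_stop)
  cor_res <- correlate_metrics(tab)
  neut <- neutrality_fit(tab)
  hist_res <- enc_ratio_histogram(tab)
  pr2 <- pr2_summary(tab)
  pooled <- rscu(pool_counts(stats::setNames(
    lapply(cds$genes$sequence, count_codons), cds$genes$gene)), code)

  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  rep_tab <- tab
  num <- vapply(rep_tab, is.numeric, logical(1))
  rep_tab[num] <- lapply(rep_tab[num], function(v) round(v, 4))
  w(rep_tab, paste0(cds$species_label, "_gene_metrics.tsv"))
  w(as.data.frame(cor_res), paste0(cds$species_label, "_correlations.tsv"))
  w(data.frame(slope = neut$slope, intercept = neut$intercept, r = neut$r,
               r_squared = neut$r_squared, p = neut$p, n = neut$n),
    paste0(cds$species_label, "_neutrality.tsv"))
  pooled_rep <- pooled
  pooled_rep$codon <- to_rna(pooled_rep$codon)
  pooled_rep$rscu <- round(pooled_rep$rscu, 2)
  w(pooled_rep, paste0(cds$species_label, "_rscu.tsv"))
  write_manifest(out_dir, "codon_report",
                 list(include_stop = include_stop,
                      n_genes = nrow(cds$genes)), cds$species_label)
  invisible(list(table = tab, correlations = cor_res, neutrality = neut,
                 enc_hist = hist_res, pr2 = pr2, rscu_pooled = pooled))
}

as_cds_set <- function(input, code = genetic_code()) {
  if (inherits(input, "cds_set")) return(input)
  if (inherits(input, "seq_record")) return(extract_cds(input, code))
  ext <- tolower(tools::file_ext(input))
  if (ext == "tsv") {
    df <- utils::read.delim(input, stringsAsFactors = FALSE)
    return(cds_set(df, species_label = basename(input), provenance = input))
  }
  extract_cds(load_records(input)[[1]], code)
}

#' Per-species and shared optimal-codon reports
#'
#' Runs [optimal_codon_report()] on each species and intersects the
#' optimal sets; writes a per-codon TSV per species (RNA codon labels,
#' 2-decimal RSCU/delta) and a shared-set JSON summary.
#'
#' @param cds_sets List of [cds_set()] objects (>= 1).
#' @param out_dir Output directory.
#' @param fraction,delta_threshold Library and threshold parameters.
#' @param code A [genetic_code()].
#' @return Invisibly, list with `reports` (per species) and `shared`.
#' @export
run_optimal <- function(cds_sets, out_dir = ".", fraction = 0.10,
                        delta_threshold = 0.08, code = genetic_code()) {
  if (!length(cds_sets)) stop("need at least one species")
  if (inherits(cds_sets, "cds_set")) cds_sets <- list(cds_sets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- lapply(cds_sets, optimal_codon_report, code = code,
                    fraction = fraction, delta_threshold = delta_threshold)
  sets <- lapply(reports, optimal_codon_set,
                 delta_threshold = delta_threshold)
  shared <- shared_optimal_codons(sets)
  for (rp in reports) {
    rep_df <- rp
    rep_df$codon <- to_rna(rep_df$codon)
    for (cc in c("rscu_all", "rscu_high", "rscu_low", "delta_rscu")) {
      rep_df[[cc]] <- round(rep_df[[cc]], 2)
    }
    utils::write.table(rep_df,
                       file.path(out_dir, paste0(attr(rp, "species_label"),
                                                 "_optimal_codons.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(shared = to_rna(as.character(shared)),
         n_au_ending = attr(shared, "n_au"),
         n_gc_ending = attr(shared, "n_gc"),
         per_species = lapply(sets, to_rna)),
    file.path(out_dir, "shared_optimal_codons.json"), auto_unbox = TRUE)
  write_manifest(out_dir, "optimal",
                 list(fraction = fraction,
                      delta_threshold = delta_threshold),
                 vapply(reports, attr, "", "species_label"))
  invisible(list(reports = reports, shared = shared))
}

write_manifest <- function(out_dir, step, config, inputs) {
  jsonlite::write_json(
    list(step = step, package = "cpcub",
         version = as.character(utils::packageVersion("cpcub")),
         config = config, inputs = inputs,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, paste0(step, "_manifest.json")), auto_unbox = TRUE)
}
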