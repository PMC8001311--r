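# Seeded synthetic reference genome, gene models and truth table.

.SYNTH_CONTIG <- "chrS"

#' Simulate a reference contig, gene models and planted-site truth table
#'
#' Lays out `n_genes` genes (alternating strand) separated by intergenic
#' spacers on a single random contig, each with contiguous 5'UTR, CDS and
#' 3'UTR intervals, then overwrites the reference base at every planted
#' editing site so the configured conversion is realisable, and plants
#' genomic SNP positions inside gene bodies.  All coordinates are 1-based
#' inclusive.
#'
#' The returned truth table records, for every planted site, the contig,
#' position, genomic reference and alternate base, transcript-level
#' conversion, per-sample efficiency and an `is_snp` flag; it is the oracle
#' against which detection is evaluated and is never consulted by the
#' detection code itself.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `synth_genome` with elements `reference`
#'   (a named [Biostrings::DNAStringSet]), `gene_models` (data frame with
#'   columns `contig`, `start`, `end`, `strand`, `feature`, `gene_id`),
#'   `truth` (the truth table) and `config`.
#' @export
#' @examples
#' sim <- simulate_reference(synth_config(seed = 1, n_genes = 3))
#' sim$gene_models
simulate_reference <- function(config) {
  validate_synth_config(config)
  withr::with_seed(config$seed, .simulate_reference_impl(config))
}

.simulate_reference_impl <- function(config) {
  ng <- config$n_genes
  gl <- config$gene_length
  ig <- config$intergenic_len
  L <- max(ng * (gl + ig) + ig, ig, config$read_length + 1L)
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  gene_models <- data.frame(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), feature = character(0), gene_id = character(0),
    stringsAsFactors = FALSE
  )
  if (ng > 0L) {
    gstart <- ig * seq_len(ng) + gl * (seq_len(ng) - 1L) + 1L
    strand <- rep_len(c("+", "-"), ng)
    gene_id <- sprintf("GENE%03d", seq_len(ng))
    cds_len <- gl - config$utr5_len - config$utr3_len
    rows <- lapply(seq_len(ng), function(i) {
      s <- gstart[i]
      if (strand[i] == "+") {
        feats <- .FEATURES
        lens <- c(config$utr5_len, cds_len, config$utr3_len)
      } else {
        feats <- rev(.FEATURES)  # 3'UTR leftmost on the minus strand
        lens <- c(config$utr3_len, cds_len, config$utr5_len)
      }
      ends <- s + cumsum(lens) - 1L
      starts <- c(s, head(ends, -1L) + 1L)
      data.frame(contig = .SYNTH_CONTIG, start = starts, end = ends,
                 strand = strand[i], feature = feats, gene_id = gene_id[i],
                 stringsAsFactors = FALSE)
    })
    gene_models <- do.call(rbind, rows)
  }

  eff_cols <- paste0("eff_", config$samples)
  truth <- data.frame(
    contig = character(0), pos = integer(0), ref = character(0),
    alt = character(0), strand = character(0), gene_id = character(0),
    feature = character(0), conversion = character(0), is_snp = logical(0),
    stringsAsFactors = FALSE
  )
  for (ec in eff_cols) truth[[ec]] <- numeric(0)

  plan <- config$editing_plan
  if (!is.null(plan) && nrow(plan)) {
    rows <- lapply(seq_len(nrow(plan)), function(i) {
      gm <- gene_models[gene_models$gene_id == sprintf("GENE%03d", plan$gene[i]) &
                          gene_models$feature == plan$feature[i], ]
      pos <- if (gm$strand == "+") gm$start + plan$offset[i] - 1L
             else gm$end - plan$offset[i] + 1L
      dna <- .conversion_to_dna(plan$conversion[i], gm$strand)
      out <- data.frame(contig = .SYNTH_CONTIG, pos = pos, ref = dna$ref,
                        alt = dna$alt, strand = gm$strand, gene_id = gm$gene_id,
                        feature = plan$feature[i],
                        conversion = normalize_conversion(plan$conversion[i]),
                        is_snp = FALSE, stringsAsFactors = FALSE)
      for (s in config$samples)
        out[[paste0("eff_", s)]] <- plan[[paste0("eff_", s)]][i]
      out
    })
    truth <- do.call(rbind, rows)
    if (anyDuplicated(truth$pos))
      stop("invalid config: editing_plan plants two sites at the same position")
    seq_chars[truth$pos] <- truth$ref
  }

  if (config$n_snp_sites > 0L) {
    if (ng == 0L) stop("invalid config: SNP sites require at least one gene")
    body <- unlist(lapply(which(gene_models$feature == "CDS"), function(i)
      seq.int(gene_models$start[i], gene_models$end[i])))
    body <- setdiff(body, truth$pos)
    snp_pos <- sort(sample(body, config$n_snp_sites))
    fo <- .feature_at(rep(.SYNTH_CONTIG, length(snp_pos)), snp_pos, gene_models)
    snp_ref <- seq_chars[snp_pos]
    snp_alt <- vapply(snp_ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    snps <- data.frame(
      contig = .SYNTH_CONTIG, pos = snp_pos, ref = snp_ref, alt = snp_alt,
      strand = fo$strand, gene_id = fo$gene_id, feature = fo$feature,
      conversion = classify_conversion(snp_ref, snp_alt, fo$strand),
      is_snp = TRUE, stringsAsFactors = FALSE
    )
    for (ec in eff_cols) snps[[ec]] <- 0
    truth <- rbind(truth, snps)
  }
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  reference <- Biostrings::DNAStringSet(
    setNames(paste(seq_chars, collapse = ""), .SYNTH_CONTIG))
  structure(list(reference = reference, gene_models = gene_models,
                 truth = truth, config = config),
            class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d contig(s), %d bp total, %d gene(s), %d planted site(s) (%d SNP)\n",
              length(x$reference), sum(Biostrings::width(x$reference)),
              length(unique(x$gene_models$gene_id)), nrow(x$truth),
              sum(x$truth$is_snp)))
  invisible(x)
}

#' Write/read the synthetic genome components
#'
#' Plain-text serialisation: FASTA for the reference, TSV for gene models
#' and the truth table.  Coordinates are written 1-based inclusive.
#'
#' @param sim A `synth_genome` object.
#' @param fasta,gene_models_tsv,truth_tsv Output paths.
#' @return The paths, invisibly.
#' @export
write_synth_genome <- function(sim, fasta, gene_models_tsv, truth_tsv) {
  Biostrings::writeXStringSet(sim$reference, fasta)
  write.table(sim$gene_models, gene_models_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, gene_models_tsv, truth_tsv))
}

#' Read gene models from a GFF3-like TSV
#'
#' Expects columns `contig`, `start`, `end`, `strand`, `feature`, `gene_id`
#' with 1-based inclusive coordinates.
#'
#' @param path TSV path.
#' @return Gene-model data frame.
#' @export
read_gene_models <- function(path) {
  gm <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "strand", "feature", "gene_id")
  miss <- setdiff(need, names(gm))
  if (length(miss))
    stop("gene-model file lacks column(s): ", paste(miss, collapse = ", "))
  gm
}
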