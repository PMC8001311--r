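# End-to-end pipeline: simulate -> qc -> place/pileup -> call -> filter ->
# annotate -> validate -> report.  Two runs with the same configuration are
# byte-identical.

#' Assemble a pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it, so a configuration fully determines all outputs.
#' @param samples Sample names.
#' @param synth Named list of [synth_config()] arguments (without `seed`,
#'   `samples`, `editing_plan`).
#' @param editing_plan Editing plan (see [editing_plan()]), or a list of
#'   per-site named lists as parsed from YAML.
#' @param qc Named list of [qc_params()] arguments.
#' @param call List with `min_alt_reads`, `min_alt_frac`.
#' @param validate List with `secondary_min_frac`, `noise_sd`.
#' @param use_read_simulation Simulate and place individual reads (`TRUE`) or
#'   draw per-site pileups directly (`FALSE`), which scales to high coverage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, samples = c("d12", "d20"),
                            synth = list(), editing_plan = NULL,
                            qc = list(), call = list(), validate = list(),
                            use_read_simulation = TRUE) {
  if (is.list(editing_plan) && !is.data.frame(editing_plan))
    editing_plan <- .plan_from_list(editing_plan, samples)
  cfg <- list(
    seed = as.integer(seed), samples = as.character(samples),
    synth = synth, editing_plan = editing_plan,
    qc = qc,
    call = modifyList(list(min_alt_reads = 2L, min_alt_frac = 0.05), call),
    validate = modifyList(list(secondary_min_frac = 0.10, noise_sd = 0),
                          validate),
    use_read_simulation = isTRUE(use_read_simulation)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

.plan_from_list <- function(rows, samples) {
  do.call(rbind, lapply(rows, function(r) {
    eff <- lapply(samples, function(s) as.numeric(r[[s]]))
    names(eff) <- samples
    editing_plan(gene = r$gene, feature = r$feature, offset = r$offset,
                 conversion = r$conversion, efficiency = eff)
  }))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("pipeline configuration not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

#' Run the complete editing-detection pipeline
#'
#' Stages: synthesise genome and truth table; simulate reads per sample;
#' quality-control them; place the clean reads and build pileups (or draw
#' pileups directly at scale); call RNA-DNA differences; remove known SNPs
#' and fixed polymorphisms; annotate features; synthesise cDNA/gDNA trace
#' pairs for every candidate (driven by the truth table, emulating the
#' wet-lab assay) and apply the confirmation rule.  All intermediate and
#' final tables are written under `outdir` along with a run manifest
#' recording the seed and every parameter.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage count messages.
#' @return Invisibly, a list with the stage outputs (`sim`, `qc`,
#'   `pileup`, `events`, `candidates`, `validation`, `spectrum`,
#'   `utr_fraction`) and `paths` of the written files.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(f) file.path(outdir, f)

  scfg <- do.call(synth_config, c(
    list(seed = config$seed, samples = config$samples,
         editing_plan = config$editing_plan),
    config$synth))

  say("[simulate] seed %d: %d gene(s), coverage %.0f", scfg$seed,
      scfg$n_genes, scfg$coverage)
  sim <- simulate_reference(scfg)
  write_synth_genome(sim, p("reference.fa"), p("gene_models.tsv"),
                     p("truth.tsv"))
  known_snps <- sim$truth[sim$truth$is_snp, c("contig", "pos", "ref", "alt")]
  write.table(known_snps, p("known_snps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  qcp <- do.call(qc_params, c(
    list(adapter_sequence = scfg$adapter_sequence), config$qc))
  pileups <- list()
  qc_reports <- list()
  if (config$use_read_simulation) {
    rd <- simulate_reads(sim, scfg)
    for (s in config$samples) {
      write_fastq(rd$reads[[s]], p(sprintf("reads_%s.fastq", s)))
      qc_reports[[s]] <- qc_summary(rd$reads[[s]], qcp)
      clean <- qc_filter(rd$reads[[s]], qcp)
      say("[qc] %s: %d/%d reads kept", s, nrow(clean), nrow(rd$reads[[s]]))
      aln <- place_reads(clean, sim$reference)
      say("[place] %s: %d/%d reads placed", s, sum(!is.na(aln$start)),
          nrow(aln))
      pileups[[s]] <- build_pileup(aln, clean, sim$reference, sample = s)
    }
  } else {
    say("[pileup] drawing per-site pileups directly")
    pu <- simulate_pileup(sim, scfg)
    pileups <- split(pu, pu$sample)
  }
  pileup <- do.call(rbind, unname(pileups))
  rownames(pileup) <- NULL
  write.table(pileup, p("pileup.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(qc_reports)) write_qc_report(qc_reports, p("qc_report.tsv"))

  events <- call_conversions(pileup, sim$gene_models,
                             min_alt_reads = config$call$min_alt_reads,
                             min_alt_frac = config$call$min_alt_frac)
  say("[call] %d event(s)", nrow(events))
  write.table(events, p("events.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  candidates <- filter_candidates(events, known_snps)
  say("[filter] %d candidate(s) after SNP/polymorphism filters",
      nrow(candidates))
  write.table(candidates, p("candidates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  spectrum <- spectrum_summary(candidates)
  write.table(spectrum, p("spectrum.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  utr <- utr_fraction(candidates)

  # validation assay: trace pairs per candidate, efficiencies from the truth
  # table (decoy single-peak traces for candidates without a planted site)
  validation <- .validate_candidates(candidates, sim, config)
  say("[validate] %d/%d candidate site(s) confirmed",
      sum(validation$confirmed), nrow(validation))
  write.table(validation, p("validated.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    package = "uceditr", version = as.character(packageVersion("uceditr")),
    seed = config$seed, samples = as.list(config$samples),
    parameters = list(
      synth = config$synth, qc = config$qc, call = config$call,
      validate = config$validate),
    counts = list(
      reads_total = if (length(qc_reports))
        sum(vapply(qc_reports, function(x) x$total, integer(1))) else NA,
      reads_kept = if (length(qc_reports))
        sum(vapply(qc_reports, function(x) x$kept, integer(1))) else NA,
      sites_piled = length(unique(paste(pileup$contig, pileup$pos))),
      events = nrow(events), candidates = nrow(candidates),
      confirmed = sum(validation$confirmed)),
    utr_fraction = utr
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(list(sim = sim, qc = qc_reports, pileup = pileup,
                 events = events, candidates = candidates,
                 validation = validation, spectrum = spectrum,
                 utr_fraction = utr,
                 paths = dir(outdir, full.names = TRUE)))
}

# Trace-based validation of each candidate site.
.validate_candidates <- function(candidates, sim, config) {
  out <- data.frame(contig = character(0), position = integer(0),
                    gene_id = character(0), feature = character(0),
                    conversion = character(0), confirmed = logical(0),
                    note = character(0), stringsAsFactors = FALSE)
  for (s in config$samples) out[[paste0("eff_", s)]] <- numeric(0)
  if (!nrow(candidates)) return(out)
  truth <- sim$truth
  sec <- config$validate$secondary_min_frac
  noise <- config$validate$noise_sd
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cd <- candidates[i, ]
    ti <- which(truth$contig == cd$contig & truth$pos == cd$pos &
                  truth$alt == cd$alt & !truth$is_snp)
    # transcript-strand bases for the trace assay
    tb <- .conversion_to_dna(cd$conversion, "+")
    cdna <- list()
    for (k in seq_along(config$samples)) {
      s <- config$samples[k]
      eff <- if (length(ti)) truth[[paste0("eff_", s)]][ti[1]] else 0
      tp <- simulate_trace_pair(
        eff, edited_base = tb$alt, unedited_base = tb$ref,
        noise_sd = noise,
        seed = config$seed + 7919L * (i %% 1000L) + k)
      cdna[[s]] <- tp$cdna
      if (k == 1L) gdna <- tp$gdna
    }
    v <- confirm_site(cdna, gdna, edited_base = tb$alt,
                      unedited_base = tb$ref, secondary_min_frac = sec)
    r <- data.frame(contig = cd$contig, position = cd$pos,
                    gene_id = cd$gene_id, feature = cd$feature,
                    conversion = cd$conversion, confirmed = v$confirmed,
                    note = v$note, stringsAsFactors = FALSE)
    for (s in config$samples) r[[paste0("eff_", s)]] <- v$efficiency_pct[[s]]
    r
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
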