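# Synthetic chromatogram trace pairs (cDNA vs gDNA).

#' Simulate a cDNA/gDNA chromatogram trace pair for one site
#'
#' Traces are idealised as one Gaussian peak per called base on a regular
#' scan grid (`scans_per_base` scans per base, peak standard deviation
#' `peak_sd` scans).  At the assayed site the cDNA trace superposes the
#' edited and unedited channels with amplitudes `efficiency` and
#' `1 - efficiency`; the gDNA trace carries a single unedited peak (or, for
#' modelling heterozygous decoys, a secondary peak of relative amplitude
#' `gdna_secondary_frac`).  Flanking bases are clean single peaks.  Optional
#' additive Gaussian noise with standard deviation `noise_sd` times the full
#' peak amplitude is applied to every scan of both traces (clamped at zero).
#'
#' Because both site channels share the same peak shape and scan window, the
#' trapezoidal peak-area ratio recovers `efficiency` exactly when
#' `noise_sd = 0`.
#'
#' @param efficiency Editing efficiency in `[0, 1]` for the cDNA template.
#' @param context DNA context string; defaults to a random `2*flank + 1`-mer
#'   (seeded) whose central base is `unedited_base`.
#' @param site_index 1-based index of the assayed base within `context`;
#'   defaults to the centre.
#' @param edited_base,unedited_base Transcript bases of the edited and
#'   unedited template (U-to-C editing reads as C against a genomic T).
#' @param flank Flanking bases on each side when `context` is generated.
#' @param noise_sd Noise standard deviation as a fraction of peak amplitude.
#' @param seed Optional seed making context and noise reproducible.
#' @param gdna_secondary_frac Relative amplitude of the edited channel in the
#'   gDNA trace; keep 0 for a true editing site.
#' @param scans_per_base,peak_sd,amplitude Trace geometry.
#' @return List with elements `cdna` and `gdna`, both
#'   [chromatogram_trace()] objects with `site_index` set.
#' @export
#' @examples
#' tp <- simulate_trace_pair(0.5, seed = 1)
#' dual_peak(tp$cdna, tp$cdna$site_index)   # TRUE
#' dual_peak(tp$gdna, tp$gdna$site_index)   # FALSE
simulate_trace_pair <- function(efficiency, context = NULL, site_index = NULL,
                                edited_base = "C", unedited_base = "T",
                                flank = 6L, noise_sd = 0, seed = NULL,
                                gdna_secondary_frac = 0,
                                scans_per_base = 10L, peak_sd = 1.5,
                                amplitude = 1000) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      is.na(efficiency) || efficiency < 0 || efficiency > 1)
    stop("efficiency must be a single value in [0, 1]")
  edited_base <- toupper(edited_base)
  unedited_base <- toupper(unedited_base)
  if (identical(edited_base, unedited_base))
    stop("edited and unedited base must differ")
  build <- function() {
    ctx <- context
    if (is.null(ctx)) {
      ctx <- paste(sample(c("A", "C", "G", "T"), 2L * flank + 1L,
                          replace = TRUE), collapse = "")
      substr(ctx, flank + 1L, flank + 1L) <- unedited_base
      # keep the immediate neighbours off the two assay channels so their
      # peak tails cannot bleed into the site's area ratio
      off <- setdiff(c("A", "C", "G", "T"), c(edited_base, unedited_base))
      substr(ctx, flank, flank) <- sample(off, 1L)
      substr(ctx, flank + 2L, flank + 2L) <- sample(off, 1L)
    }
    nb <- nchar(ctx)
    si <- if (is.null(site_index)) (nb + 1L) %/% 2L else as.integer(site_index)
    if (si < 1L || si > nb) stop("site_index outside the context")
    bases <- strsplit(toupper(ctx), "", fixed = TRUE)[[1]]
    centers <- scans_per_base * seq_len(nb) - scans_per_base / 2
    scan <- seq_len(scans_per_base * nb)

    trace_for <- function(site_weights, source) {
      chan <- matrix(0, nrow = length(scan), ncol = 4L,
                     dimnames = list(NULL, .CHANNELS))
      for (i in seq_len(nb)) {
        w <- setNames(numeric(4L), .CHANNELS)
        if (i == si) w[names(site_weights)] <- site_weights
        else w[bases[i]] <- 1
        for (b in .CHANNELS) {
          if (w[b] > 0)
            chan[, b] <- chan[, b] +
              amplitude * w[b] * exp(-(scan - centers[i])^2 / (2 * peak_sd^2))
        }
      }
      if (noise_sd > 0)
        chan <- pmax(chan + rnorm(length(chan), 0, noise_sd * amplitude), 0)
      called <- bases
      called[si] <- names(site_weights)[which.max(site_weights)]
      chromatogram_trace(
        scans = data.frame(scan = scan, chan, check.names = FALSE),
        basecalls = data.frame(base_index = seq_len(nb), scan_center = centers,
                               called_base = called, stringsAsFactors = FALSE),
        source = source, site_index = si
      )
    }

    cw <- setNames(c(1 - efficiency, efficiency), c(unedited_base, edited_base))
    gw <- setNames(c(1 - gdna_secondary_frac, gdna_secondary_frac),
                   c(unedited_base, edited_base))
    cw <- cw[cw > 0 | names(cw) == unedited_base]
    gw <- gw[gw > 0 | names(gw) == unedited_base]
    list(cdna = trace_for(cw, "cDNA"), gdna = trace_for(gw, "gDNA"))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Synthetic trace set for a validated-site ledger
#'
#' For every row of a validated-site table (see [read_validated_table()])
#' this generates one cDNA trace per sample at the row's planted efficiency
#' plus a clean gDNA trace, all sharing a seeded sequence context.  Decoy
#' sites are appended: half unedited (single peaks everywhere) and half
#' heterozygous (dual peaks in gDNA as well as cDNA), none of which must
#' survive the confirmation rule.
#'
#' @param validated Validated-site table; defaults to the packaged ledger.
#' @param samples Sample names, matched against the table's `eff_*` columns.
#' @param noise_sd,seed Passed to [simulate_trace_pair()]; each entry uses
#'   `seed + entry index`.
#' @param n_decoys Number of decoy sites to append.
#' @return List of entries, each with `gene_id`, `position`, `feature`,
#'   `kind` (`"edited"`, `"unedited-decoy"`, `"het-decoy"`), `cdna` (named
#'   list per sample), `gdna`, `edited_base`, `unedited_base`.
#' @export
validated_trace_set <- function(validated = NULL,
                                samples = c("d12", "d20"),
                                noise_sd = 0, seed = 1L, n_decoys = 12L) {
  if (is.null(validated))
    validated <- read_validated_table(
      system.file("extdata", "validated_sites_table.tsv", package = "uceditr",
                  mustWork = TRUE))
  eff <- validated_efficiencies(validated, samples)
  entries <- list()
  mk_entry <- function(idx, effs, gsf, kind, gene_id, position, feature) {
    ctx <- withr::with_seed(seed + idx, {
      ctx <- paste(sample(c("A", "C", "G", "T"), 13L, replace = TRUE),
                   collapse = "")
      substr(ctx, 7L, 7L) <- "T"
      substr(ctx, 6L, 6L) <- sample(c("A", "G"), 1L)
      substr(ctx, 8L, 8L) <- sample(c("A", "G"), 1L)
      ctx
    })
    cdna <- list()
    for (k in seq_along(samples)) {
      tp <- simulate_trace_pair(effs[k], context = ctx, site_index = 7L,
                                noise_sd = noise_sd,
                                seed = seed + 1000L * idx + k,
                                gdna_secondary_frac = gsf)
      cdna[[samples[k]]] <- tp$cdna
      if (k == 1L) gdna <- tp$gdna
    }
    list(gene_id = gene_id, position = position, feature = feature,
         kind = kind, cdna = cdna, gdna = gdna,
         edited_base = "C", unedited_base = "T")
  }
  for (i in seq_len(nrow(validated))) {
    entries[[i]] <- mk_entry(i, eff[i, ] / 100, 0, "edited",
                             validated$gene_id[i], validated$position[i],
                             validated$edited_site[i])
  }
  n0 <- nrow(validated)
  for (j in seq_len(n_decoys)) {
    het <- j > ceiling(n_decoys / 2)
    entries[[n0 + j]] <- mk_entry(
      n0 + j,
      effs = rep(if (het) 0.5 else 0, length(samples)),
      gsf = if (het) 0.5 else 0,
      kind = if (het) "het-decoy" else "unedited-decoy",
      gene_id = sprintf("DECOY%02d", j), position = NA_integer_,
      feature = NA_character_)
  }
  entries
}

#' Apply the confirmation rule to a trace set
#'
#' Runs [confirm_site()] over every entry of a [validated_trace_set()]-style
#' list and tabulates the results in the layout of a validated-site ledger.
#'
#' @param trace_set List of entries as produced by [validated_trace_set()].
#' @param secondary_min_frac Dual-peak threshold.
#' @return Data frame with one row per entry: `gene_id`, `position`,
#'   `feature`, `confirmed`, `note` and `eff_<sample>` columns in percent.
#' @export
confirm_trace_set <- function(trace_set, secondary_min_frac = 0.10) {
  rows <- lapply(trace_set, function(e) {
    v <- confirm_site(e$cdna, e$gdna,
                      edited_base = e$edited_base,
                      unedited_base = e$unedited_base,
                      secondary_min_frac = secondary_min_frac)
    out <- data.frame(gene_id = e$gene_id, position = e$position,
                      feature = e$feature, confirmed = v$confirmed,
                      note = v$note, stringsAsFactors = FALSE)
    for (s in names(v$efficiency_pct))
      out[[paste0("eff_", s)]] <- v$efficiency_pct[[s]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
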