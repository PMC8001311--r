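# Chromatogram traces: peak areas, dual peaks, editing efficiency and the
# cDNA-versus-gDNA confirmation rule.

.CHANNELS <- c("A", "C", "G", "T")

#' Construct a chromatogram trace
#'
#' A trace holds the four channel intensity series over scan points plus the
#' base-call track locating each called base on the scan axis, as produced by
#' a capillary sequencer (or by [simulate_trace_pair()]).
#'
#' @param scans Data frame with columns `scan`, `A`, `C`, `G`, `T`
#'   (non-negative intensities).
#' @param basecalls Data frame with columns `base_index`, `scan_center`
#'   (strictly increasing) and `called_base`.
#' @param source `"cDNA"` or `"gDNA"`.
#' @param site_index Base index of the assayed position, or `NA`.
#' @return An object of class `chromatogram_trace`.
#' @export
chromatogram_trace <- function(scans, basecalls, source = c("cDNA", "gDNA"),
                               site_index = NA_integer_) {
  source <- match.arg(source)
  stopifnot(is.data.frame(scans), is.data.frame(basecalls))
  miss <- setdiff(c("scan", .CHANNELS), names(scans))
  if (length(miss))
    stop("scans lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("base_index", "scan_center", "called_base"), names(basecalls))
  if (length(miss))
    stop("basecalls lacks column(s): ", paste(miss, collapse = ", "))
  if (any(as.matrix(scans[.CHANNELS]) < 0))
    stop("channel intensities must be non-negative")
  if (is.unsorted(basecalls$scan_center, strictly = TRUE))
    stop("scan centers must be strictly increasing")
  structure(list(scans = scans, basecalls = basecalls, source = source,
                 site_index = as.integer(site_index)),
            class = "chromatogram_trace")
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf("chromatogram trace (%s): %d scans, %d called bases, site at base %s\n",
              x$source, nrow(x$scans), nrow(x$basecalls),
              ifelse(is.na(x$site_index), "<unset>", x$site_index)))
  invisible(x)
}

.base_window <- function(trace, base_index) {
  bc <- trace$basecalls
  i <- match(base_index, bc$base_index)
  if (is.na(i)) stop("base_index ", base_index, " not in basecall track")
  ctr <- bc$scan_center
  lo <- if (i > 1L) (ctr[i - 1L] + ctr[i]) / 2 else min(trace$scans$scan)
  hi <- if (i < nrow(bc)) (ctr[i] + ctr[i + 1L]) / 2 else max(trace$scans$scan)
  c(lo, hi)
}

#' Peak area of one channel at one called base
#'
#' Integrates the channel intensity over the base's scan window (from the
#' midpoint to the previous call to the midpoint to the next call, clipped at
#' the trace edges) by the trapezoidal rule.
#'
#' @param trace A [chromatogram_trace()].
#' @param base_index Base index in the basecall track.
#' @param channel `"A"`, `"C"`, `"G"` or `"T"`.
#' @return Non-negative area in intensity x scan units.
#' @export
peak_area <- function(trace, base_index, channel) {
  channel <- match.arg(toupper(channel), .CHANNELS)
  w <- .base_window(trace, base_index)
  sel <- trace$scans$scan >= w[1] & trace$scans$scan <= w[2]
  if (sum(sel) < 2L) return(0)
  pracma::trapz(trace$scans$scan[sel], trace$scans[[channel]][sel])
}

#' Peak-area editing efficiency at a site
#'
#' The editing efficiency is the edited-channel peak area divided by the sum
#' of the edited and unedited channel areas at the assayed base, in percent.
#' Only the two relevant channels enter the ratio.
#'
#' @inheritParams peak_area
#' @param edited_base Transcript base produced by editing (e.g. `"C"` for
#'   U-to-C).
#' @param unedited_base Unedited base (e.g. `"T"`).
#' @return Efficiency in percent, in `[0, 100]`.
#' @export
#' @examples
#' tp <- simulate_trace_pair(0.773, seed = 7)
#' editing_efficiency(tp$cdna, tp$cdna$site_index, "C", "T")
editing_efficiency <- function(trace, base_index, edited_base, unedited_base) {
  if (toupper(edited_base) == toupper(unedited_base))
    stop("edited and unedited base must differ")
  ae <- peak_area(trace, base_index, edited_base)
  au <- peak_area(trace, base_index, unedited_base)
  if (ae + au <= 0)
    stop("no signal: both channel areas are zero at base ", base_index)
  100 * ae / (ae + au)
}

#' Dual-peak test at a called base
#'
#' A site shows a dual peak when the second-largest channel peak area is at
#' least `secondary_min_frac` times the largest.  In cDNA a dual peak
#' indicates a mixed edited/unedited template; in gDNA it indicates genomic
#' heterozygosity and disqualifies the site.
#'
#' @inheritParams peak_area
#' @param secondary_min_frac Minimum secondary/primary area ratio, in (0, 1);
#'   10% is a conventional chromatogram heterozygosity cutoff.
#' @return Logical.
#' @export
dual_peak <- function(trace, base_index, secondary_min_frac = 0.10) {
  if (secondary_min_frac <= 0 || secondary_min_frac >= 1)
    stop("secondary_min_frac must lie in (0, 1)")
  areas <- vapply(.CHANNELS, function(ch) peak_area(trace, base_index, ch),
                  numeric(1))
  areas <- sort(areas, decreasing = TRUE)
  if (areas[1] <= 0) return(FALSE)
  areas[2] >= secondary_min_frac * areas[1]
}

#' Confirm an editing site from paired cDNA and gDNA traces
#'
#' The confirmation rule: the site is a validated editing event when at least
#' one cDNA sample shows a dual peak at the assayed base while the gDNA trace
#' shows a clean single peak.  A dual peak in gDNA marks the site as genomic
#' heterozygosity or a SNP and the site is rejected.  Per-sample efficiencies
#' are the peak-area ratios; a sample without a dual peak reports 0.
#'
#' @param cdna_traces Named list of [chromatogram_trace()] objects, one per
#'   sample.
#' @param gdna_trace gDNA trace for the same amplicon.
#' @param base_index Assayed base index; defaults to the gDNA `site_index`.
#' @param edited_base,unedited_base The two template bases (see
#'   [editing_efficiency()]).
#' @param secondary_min_frac Dual-peak threshold (see [dual_peak()]).
#' @return A list of class `validation_result`: `confirmed` (logical),
#'   `note` (`""` or `"heterozygous-or-SNP"`), `efficiency_pct` (named
#'   per-sample vector, percent) and `dual` (named per-sample logical).
#' @export
confirm_site <- function(cdna_traces, gdna_trace,
                         base_index = gdna_trace$site_index,
                         edited_base = "C", unedited_base = "T",
                         secondary_min_frac = 0.10) {
  if (is.null(names(cdna_traces)) || any(names(cdna_traces) == ""))
    stop("cdna_traces must be a named list (one trace per sample)")
  dual_c <- vapply(cdna_traces, dual_peak, logical(1),
                   base_index = base_index,
                   secondary_min_frac = secondary_min_frac)
  eff <- vapply(seq_along(cdna_traces), function(i) {
    if (!dual_c[i]) return(0)
    editing_efficiency(cdna_traces[[i]], base_index, edited_base, unedited_base)
  }, numeric(1))
  names(eff) <- names(cdna_traces)
  gdna_dual <- dual_peak(gdna_trace, base_index, secondary_min_frac)
  res <- list(
    confirmed = !gdna_dual && any(dual_c),
    note = if (gdna_dual) "heterozygous-or-SNP" else "",
    efficiency_pct = eff,
    dual = dual_c
  )
  class(res) <- "validation_result"
  res
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation: %s%s; efficiency (%%): %s\n",
              if (x$confirmed) "confirmed" else "not confirmed",
              if (nzchar(x$note)) paste0(" [", x$note, "]") else "",
              paste(sprintf("%s=%.2f", names(x$efficiency_pct),
                            x$efficiency_pct), collapse = ", ")))
  invisible(x)
}

#' Trace TSV serialisation
#'
#' Writes/reads the columnar interchange format: a scan TSV (`scan`, `A`,
#' `C`, `G`, `T`) and a base-call TSV (`base_index`, `scan_center`,
#' `called_base`).
#'
#' @param trace A [chromatogram_trace()].
#' @param scans_path,calls_path TSV paths.
#' @param source,site_index Metadata restored on read (not stored in the
#'   TSVs).
#' @return `write_trace()` the paths invisibly; `read_trace()` a trace.
#' @export
write_trace <- function(trace, scans_path, calls_path) {
  write.table(trace$scans, scans_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(trace$basecalls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(scans_path, calls_path))
}

#' @rdname write_trace
#' @export
read_trace <- function(scans_path, calls_path, source = "cDNA",
                       site_index = NA_integer_) {
  chromatogram_trace(read.delim(scans_path, stringsAsFactors = FALSE),
                     read.delim(calls_path, stringsAsFactors = FALSE),
                     source = source, site_index = site_index)
}
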