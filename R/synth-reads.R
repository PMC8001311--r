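# Seeded read and pileup simulation over a synthetic genome.

#' Simulate sequencing reads per sample
#'
#' Draws reads of fixed length at uniform positions along the contig at the
#' configured mean coverage (read count is Poisson).  Each read overlapping a
#' planted editing site carries the alternate base independently with that
#' site's per-sample efficiency, so the alternate support at a site of
#' realised depth n is Binomial(n, f); SNP sites carry the alternate on every
#' read in every sample.  An i.i.d. substitution error channel is applied at
#' `error_rate`, and configured fractions of reads are contaminated with the
#' adapter sequence or with >10% N bases to exercise quality control.
#'
#' @param sim A `synth_genome` from [simulate_reference()].
#' @param config Configuration; defaults to the one stored in `sim`.
#' @return A list of class `synth_reads`: `reads`, a named list (one data
#'   frame per sample with columns `id`, `seq`, `qual`), and `read_truth`, a
#'   data frame of per-read provenance (`sample`, `id`, `start`,
#'   `contamination` one of `"clean"`, `"adapter"`, `"polyN"`).
#' @export
simulate_reads <- function(sim, config = sim$config) {
  validate_synth_config(config)
  if (config$coverage <= 0) stop("invalid config: coverage must be > 0")
  withr::with_seed(config$seed + 1L, .simulate_reads_impl(sim, config))
}

.simulate_reads_impl <- function(sim, config) {
  contig <- as.character(sim$reference[[1]])
  L <- nchar(contig)
  rl <- config$read_length
  if (rl > L) stop("read_length exceeds contig length")
  truth <- sim$truth
  reads <- list()
  read_truth <- list()

  for (s in config$samples) {
    n_reads <- rpois(1L, config$coverage * L / rl)
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    seqs <- substring(contig, starts, starts + rl - 1L)

    # plant alternate alleles read-by-read at truth sites
    eff <- truth[[paste0("eff_", s)]]
    for (i in seq_len(nrow(truth))) {
      pos <- truth$pos[i]
      idx <- which(starts <= pos & starts > pos - rl)
      if (!length(idx)) next
      carry <- if (truth$is_snp[i]) idx else idx[runif(length(idx)) < eff[i]]
      if (length(carry))
        substr(seqs[carry], pos - starts[carry] + 1L,
               pos - starts[carry] + 1L) <- truth$alt[i]
    }

    # i.i.d. substitution errors
    if (config$error_rate > 0) {
      n_err <- rbinom(1L, n_reads * rl, config$error_rate)
      if (n_err > 0) {
        er <- sample.int(n_reads, n_err, replace = TRUE)
        ep <- sample.int(rl, n_err, replace = TRUE)
        cur <- substr(seqs[er], ep, ep)
        sub <- vapply(cur, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
          USE.NAMES = FALSE)
        substr(seqs[er], ep, ep) <- sub
      }
    }

    # contamination for the QC stage
    u <- runif(n_reads)
    contamination <- rep("clean", n_reads)
    contamination[u < config$adapter_fraction] <- "adapter"
    contamination[u >= config$adapter_fraction &
                    u < config$adapter_fraction + config$n_fraction_high] <- "polyN"
    ad <- which(contamination == "adapter")
    if (length(ad)) {
      la <- min(nchar(config$adapter_sequence), rl)
      substr(seqs[ad], rl - la + 1L, rl) <- substr(config$adapter_sequence, 1L, la)
    }
    pn <- which(contamination == "polyN")
    n_n <- ceiling(0.15 * rl)  # strictly above the 10% QC bound
    for (i in pn) {
      at <- sample.int(rl, n_n)
      for (p in at) substr(seqs[i], p, p) <- "N"
    }

    ids <- sprintf("%s_read%06d", s, seq_len(n_reads))
    reads[[s]] <- data.frame(id = ids, seq = seqs,
                             qual = strrep(rawToChar(as.raw(37L + 33L)), rl),
                             stringsAsFactors = FALSE)
    read_truth[[s]] <- data.frame(sample = s, id = ids, start = starts,
                                  contamination = contamination,
                                  stringsAsFactors = FALSE)
  }
  structure(list(reads = reads, read_truth = do.call(rbind, read_truth)),
            class = "synth_reads")
}

#' Simulate per-site pileup tables directly
#'
#' Skips read simulation and placement: per position and sample, the realised
#' depth is Poisson(`coverage`), the alternate count at a planted site is
#' Binomial(depth, efficiency) (all reads at a SNP), and each remaining
#' reference-supporting read is substituted by a uniformly chosen other base
#' with probability `error_rate`.  Useful for calibration experiments at
#' depths where simulating individual reads is wasteful.
#'
#' @inheritParams simulate_reads
#' @return A pileup data frame (one row per site and sample with depth > 0):
#'   columns `contig`, `pos`, `ref`, `sample`, `A`, `C`, `G`, `T`, `N`,
#'   `depth`.
#' @export
simulate_pileup <- function(sim, config = sim$config) {
  validate_synth_config(config)
  if (config$coverage <= 0) stop("invalid config: coverage must be > 0")
  withr::with_seed(config$seed + 2L, .simulate_pileup_impl(sim, config))
}

.simulate_pileup_impl <- function(sim, config) {
  contig <- as.character(sim$reference[[1]])
  L <- nchar(contig)
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(contig, "", fixed = TRUE)[[1]]
  ref_i <- match(ref, bases)
  truth <- sim$truth
  out <- vector("list", length(config$samples))

  for (si in seq_along(config$samples)) {
    s <- config$samples[si]
    f <- numeric(L)
    alt_base <- rep(NA_character_, L)
    if (nrow(truth)) {
      f[truth$pos] <- ifelse(truth$is_snp, 1, truth[[paste0("eff_", s)]])
      alt_base[truth$pos] <- truth$alt
    }
    n <- rpois(L, config$coverage)
    alt <- rbinom(L, n, f)
    err <- rbinom(L, n - alt, config$error_rate)
    keep_ref <- n - alt - err
    counts <- matrix(0L, nrow = L, ncol = 5L,
                     dimnames = list(NULL, c(bases, "N")))
    counts[cbind(seq_len(L), ref_i)] <- keep_ref
    has_alt <- which(alt > 0L)
    if (length(has_alt)) {
      ai <- match(alt_base[has_alt], bases)
      counts[cbind(has_alt, ai)] <- counts[cbind(has_alt, ai)] + alt[has_alt]
    }
    # distribute error reads uniformly over the three non-reference bases
    e1 <- rbinom(L, err, 1 / 3)
    e2 <- rbinom(L, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    others <- matrix(0L, nrow = L, ncol = 3L)
    for (b in seq_len(4L)) {
      at <- which(ref_i == b)
      others[at, ] <- matrix(rep(setdiff(seq_len(4L), b), each = length(at)),
                             ncol = 3L)
    }
    for (j in 1:3) {
      ej <- list(e1, e2, e3)[[j]]
      idx <- cbind(seq_len(L), others[, j])
      counts[idx] <- counts[idx] + ej
    }
    keep <- which(n > 0L)
    out[[si]] <- data.frame(
      contig = names(sim$reference)[1], pos = keep, ref = ref[keep],
      sample = s, counts[keep, , drop = FALSE],
      depth = n[keep], stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
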