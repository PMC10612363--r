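# Per-locus statistics: allele frequencies and forensic parameters.
#
# Conventions (STRAF-style, haploid Y data): with p_i the allele frequencies
# at one locus, H = sum p_i^2 (the match probability PM) and h = 1 - H,
#   GD  = n/(n-1) * (1 - sum p_i^2)        (unbiased gene diversity)
#   PM  = sum p_i^2;  PD = 1 - PM
#   PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2   (Botstein)
#   PE  = h^2 (1 - 2 h H)                  (Brenner-style, haploid analogue)
#   TPI = 1 / (2 H)
# Records carrying a null or duplicated allele at a locus are excluded from
# that locus's denominator (but still count in full-haplotype identity).
# Microvariants are distinct frequency classes (17 != 17.2).

#' Allele frequencies at a single-copy locus
#'
#' @param sample A `ystr_sample`.
#' @param locus A single-copy marker of the sample's panel.
#' @return List with `locus`, `frequencies` (named numeric vector over
#'   canonical allele tokens, sorted by numeric allele value), `n_eff`
#'   (records counted) and `excluded` (data frame of excluded records with
#'   the anomaly kind that excluded them).
#' @export
allele_frequencies <- function(sample, locus) {
  stopifnot(inherits(sample, "ystr_sample"))
  li <- match(locus, sample$panel$loci$marker)
  if (is.na(li)) stop("locus '", locus, "' not in panel")
  if (sample$panel$loci$copy_number[li] != 1L)
    stop("locus '", locus, "' is not single-copy; use ",
         "dualcopy_haplotype_stats()")
  tok <- sample$data[[locus]]
  drop <- tok == "-" | grepl(",", tok, fixed = TRUE)
  excluded <- data.frame(
    sample_id = sample$data$sample_id[drop],
    kind = ifelse(tok[drop] == "-", "null", "duplication"),
    stringsAsFactors = FALSE)
  kept <- tok[!drop]
  if (!length(kept)) stop("no usable alleles at locus '", locus, "'")
  tab <- table(kept)
  freqs <- as.numeric(tab) / length(kept)
  names(freqs) <- names(tab)
  freqs <- freqs[order(as.numeric(names(freqs)))]
  list(locus = locus, frequencies = freqs, n_eff = length(kept),
       excluded = excluded)
}

#' Forensic parameters from an allele frequency table
#'
#' @param freqs Named numeric vector of allele frequencies (must sum to 1).
#' @param n_eff Number of records the frequencies were estimated from
#'   (`>= 2`).
#' @return One-row data frame with `n_eff`, `n_alleles`, `GD`, `PIC`, `PM`,
#'   `PD`, `PE`, `TPI`.
#' @examples
#' locus_forensic_params(c("14" = 0.5, "15" = 0.5), 10)  # GD = 0.5556
#' @export
locus_forensic_params <- function(freqs, n_eff) {
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("allele frequencies must sum to 1")
  if (n_eff < 2) stop("locus statistics require n_eff >= 2")
  p <- as.numeric(freqs)
  H <- sum(p^2)
  h <- 1 - H
  p2 <- p^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
  pic <- 1 - H - (sum(p2)^2 - sum(p2^2))
  data.frame(
    n_eff = n_eff,
    n_alleles = length(p),
    GD = n_eff / (n_eff - 1) * h,
    PIC = pic,
    PM = H,
    PD = 1 - H,
    PE = h^2 * (1 - 2 * h * H),
    TPI = 1 / (2 * H)
  )
}

#' Per-locus statistics table for all single-copy markers
#'
#' @param sample A `ystr_sample`.
#' @param markers Single-copy markers to report (default: all single-copy
#'   markers of the panel).
#' @return Data frame, one row per locus, with the columns of
#'   [locus_forensic_params()] plus `locus`.
#' @export
locus_stats_table <- function(sample, markers = NULL) {
  stopifnot(inherits(sample, "ystr_sample"))
  if (is.null(markers)) markers <- panel_markers(sample$panel, 1L)
  rows <- lapply(markers, function(m) {
    af <- allele_frequencies(sample, m)
    cbind(data.frame(locus = m, stringsAsFactors = FALSE),
          locus_forensic_params(af$frequencies, af$n_eff))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Haplotype statistics at a dual-copy locus
#'
#' Unordered allele-pair frequencies for a dual-copy marker (e.g. DYS385a/b),
#' with gene diversity computed on the pair frequencies.
#'
#' @param sample A `ystr_sample`.
#' @param locus A dual-copy marker.
#' @return List with `locus`, `pair_frequencies` (named over canonical
#'   `"a-b"` tokens), `n_eff`, `n_pairs` (distinct combinations),
#'   `n_alleles` (distinct allele values across both copies) and `GD`.
#' @export
dualcopy_haplotype_stats <- function(sample, locus) {
  stopifnot(inherits(sample, "ystr_sample"))
  li <- match(locus, sample$panel$loci$marker)
  if (is.na(li)) stop("locus '", locus, "' not in panel")
  if (sample$panel$loci$copy_number[li] != 2L)
    stop("locus '", locus, "' is not dual-copy")
  tok <- sample$data[[locus]]
  kept <- tok[tok != "-"]
  if (!length(kept)) stop("no usable pairs at locus '", locus, "'")
  tab <- table(kept)
  freqs <- as.numeric(tab) / length(kept)
  names(freqs) <- names(tab)
  n_eff <- length(kept)
  alleles <- unique(unlist(strsplit(names(tab), "-", fixed = TRUE)))
  list(locus = locus,
       pair_frequencies = freqs,
       n_eff = n_eff,
       n_pairs = length(freqs),
       n_alleles = length(alleles),
       GD = n_eff / (n_eff - 1) * (1 - sum(freqs^2)))
}
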