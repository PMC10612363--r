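# Haplotype-level forensic parameters.
#
# Everything here derives from the multiplicity spectrum: the histogram
# mapping multiplicity m to the number of distinct haplotypes observed
# exactly m times. With n_i the count of the i-th distinct haplotype and
# p_i = n_i/n:
#   HMP (haplotype match probability)  = sum p_i^2
#   HD  (haplotype diversity)          = n (1 - sum p_i^2) / (n - 1)
#   DC  (discrimination capacity)      = distinct / n
#   unique-haplotype fraction          = singletons / n

#' Build a multiplicity spectrum
#'
#' Counts how many distinct haplotypes occur exactly m times, either from a
#' `ystr_sample` (haplotypes compared on `markers`) or directly from a vector
#' of haplotype keys/labels.
#'
#' @param x A `ystr_sample`, or a vector of haplotype identity keys.
#' @param markers Marker subset used for haplotype identity (samples only;
#'   default all panel markers).
#' @return A `ystr_spectrum`: list with `n` (sample size) and `counts`, a
#'   named integer vector mapping multiplicity to number of distinct
#'   haplotypes with that multiplicity.
#' @examples
#' multiplicity_spectrum(c("A", "A", "B", "C"))  # {2: 1, 1: 2}
#' @export
multiplicity_spectrum <- function(x, markers = NULL) {
  keys <- if (inherits(x, "ystr_sample")) haplotype_keys(x, markers)
          else as.character(x)
  if (!length(keys)) stop("empty sample: no haplotypes to count")
  tab <- table(keys)
  counts <- table(as.integer(tab))
  spec <- structure(list(n = length(keys),
                         counts = stats::setNames(as.integer(counts),
                                                  names(counts))),
                    class = "ystr_spectrum")
  validate_spectrum(spec)
  spec
}

#' Construct a spectrum directly from multiplicity counts
#'
#' @param counts Named vector: `names` are multiplicities, values the number
#'   of distinct haplotypes at that multiplicity, e.g.
#'   `c("10" = 1, "2" = 20, "1" = 401)`.
#' @return A `ystr_spectrum`.
#' @export
spectrum_from_counts <- function(counts) {
  m <- as.integer(names(counts))
  if (any(is.na(m)) || any(m < 1L) || any(counts < 0))
    stop("spectrum counts must map positive multiplicities to nonnegative ",
         "counts")
  keep <- counts > 0
  spec <- structure(list(n = sum(m[keep] * counts[keep]),
                         counts = stats::setNames(as.integer(counts[keep]),
                                                  m[keep])),
                    class = "ystr_spectrum")
  validate_spectrum(spec)
  spec
}

validate_spectrum <- function(spec) {
  m <- as.integer(names(spec$counts))
  stopifnot(sum(m * spec$counts) == spec$n, sum(spec$counts) <= spec$n)
  invisible(spec)
}

#' Number of distinct haplotypes in a spectrum
#' @param spec A `ystr_spectrum`.
#' @export
n_distinct_haplotypes <- function(spec) sum(spec$counts)

# sum of n_i^2 over distinct haplotypes
.sum_sq <- function(spec) {
  m <- as.integer(names(spec$counts))
  sum(spec$counts * m^2)
}

#' Haplotype match probability
#'
#' HMP = sum of squared observed haplotype frequencies; equals the number of
#' matching ordered record pairs (self-pairs included) divided by n^2.
#'
#' @param spec A `ystr_spectrum`.
#' @return HMP in `[1/n, 1]`.
#' @export
match_probability <- function(spec) {
  stopifnot(inherits(spec, "ystr_spectrum"), spec$n >= 1)
  .sum_sq(spec) / spec$n^2
}

#' Haplotype diversity
#'
#' HD = n (1 - sum p_i^2) / (n - 1), the bias-corrected probability that two
#' randomly drawn individuals carry different haplotypes. HD = 1 exactly when
#' all haplotypes are unique, 0 when a single haplotype is shared by all.
#'
#' @param spec A `ystr_spectrum` with `n >= 2`.
#' @return HD in `[0, 1]`.
#' @export
haplotype_diversity <- function(spec) {
  stopifnot(inherits(spec, "ystr_spectrum"))
  if (spec$n < 2) stop("haplotype diversity requires n >= 2")
  n <- spec$n
  n * (1 - .sum_sq(spec) / n^2) / (n - 1)
}

#' Discrimination capacity
#'
#' DC = distinct haplotypes / sample size.
#'
#' @param spec A `ystr_spectrum`.
#' @return DC in `(0, 1]`.
#' @export
discrimination_capacity <- function(spec) {
  stopifnot(inherits(spec, "ystr_spectrum"), spec$n >= 1)
  n_distinct_haplotypes(spec) / spec$n
}

#' Fraction of unique (singleton) haplotypes
#'
#' @param spec A `ystr_spectrum`.
#' @return singletons / n.
#' @export
unique_haplotype_fraction <- function(spec) {
  stopifnot(inherits(spec, "ystr_spectrum"), spec$n >= 1)
  singles <- spec$counts[names(spec$counts) == "1"]
  (if (length(singles)) singles[[1]] else 0L) / spec$n
}

#' Diversity of a categorical label vector
#'
#' Applies the haplotype-diversity formula to category (e.g. haplogroup)
#' frequencies.
#'
#' @param labels Vector of category labels (NAs dropped); needs `n >= 2`.
#' @return Diversity in `[0, 1]`.
#' @export
categorical_diversity <- function(labels) {
  labels <- labels[!is.na(labels)]
  haplotype_diversity(multiplicity_spectrum(labels))
}

#' Haplotype-level forensic summary
#'
#' @param x A `ystr_sample` or `ystr_spectrum`.
#' @param markers Marker subset for haplotype identity (samples only).
#' @param name Row label.
#' @return One-row data frame with `name`, `n`, `distinct`,
#'   `unique_fraction`, `DC`, `HMP`, `HD` (raw, unrounded values).
#' @export
forensic_summary <- function(x, markers = NULL, name = NULL) {
  spec <- if (inherits(x, "ystr_spectrum")) x
          else multiplicity_spectrum(x, markers)
  if (is.null(name))
    name <- if (inherits(x, "ystr_sample")) x$name else "sample"
  data.frame(
    name = name,
    n = spec$n,
    distinct = n_distinct_haplotypes(spec),
    unique_fraction = unique_haplotype_fraction(spec),
    DC = discrimination_capacity(spec),
    HMP = match_probability(spec),
    HD = if (spec$n >= 2) haplotype_diversity(spec) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Round half-up
#'
#' Display rounding used for reported tables: exact halves round away from
#' zero (base `round()` rounds to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.ystr_spectrum <- function(x, ...) {
  cat("Multiplicity spectrum: n =", x$n, ", distinct =",
      n_distinct_haplotypes(x), "\n")
  m <- as.integer(names(x$counts))
  o <- order(-m)
  cat(paste0("  ", x$counts[o], " haplotype(s) seen ", m[o], "x",
             collapse = "\n"), "\n")
  invisible(x)
}
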