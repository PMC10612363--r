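# Haplotype table I/O and allele canonicalization.
#
# Table dialect (YHRD-style): UTF-8, tab-delimited, header required. One row
# per sampled male; columns are the sample ID, population label, optional
# region and haplogroup labels, and one column per panel marker. Allele
# tokens:
#   "14"      single-copy allele (repeat count)
#   "17.2"    microvariant allele (fractional part .1/.2/.3)
#   "11-14"   dual-copy marker: hyphen-joined unordered pair
#   "15,16"   duplication at a single-copy marker: comma-joined
#   "-"       null allele (deletion / no amplification)
# Dual-copy pairs and duplications are canonicalized in nondecreasing order,
# so "14-11" and "11-14" are the same allele state.

.ID_ALIASES   <- c("sample_id", "sampleid", "id", "sample")
.POP_ALIASES  <- c("population", "pop")
.REG_ALIASES  <- c("region")
.HG_ALIASES   <- c("haplogroup", "hg")

.fmt_allele_num <- function(x) {
  # integer repeats print without decimals; microvariants with one decimal
  ifelse(abs(x - round(x)) < 1e-9, format(round(x), trim = TRUE),
         sprintf("%.1f", x))
}

.parse_allele_num <- function(tok, where) {
  x <- suppressWarnings(as.numeric(tok))
  if (is.na(x))
    stop("unparseable allele token '", tok, "' at ", where, call. = FALSE)
  frac <- round((x %% 1) * 10)
  if (abs(x * 10 - round(x * 10)) > 1e-6 || !(frac %in% c(0, 1, 2, 3)))
    stop("invalid allele value '", tok, "' at ", where,
         " (microvariant fractional part must be .1, .2 or .3)",
         call. = FALSE)
  x
}

# Canonicalize one allele token. Returns the canonical token string.
canonical_allele <- function(token, copy_number, min_allele = -Inf,
                             max_allele = Inf, strict = FALSE,
                             where = "<token>") {
  tok <- trimws(token)
  if (is.na(tok) || tok == "" || tok == "-") return("-")
  range_check <- function(vals) {
    bad <- vals < min_allele | vals > max_allele
    if (any(bad)) {
      msg <- paste0("allele ", paste(.fmt_allele_num(vals[bad]),
                                     collapse = ","),
                    " outside plausible range [", min_allele, ",",
                    max_allele, "] at ", where)
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  if (copy_number == 2L) {
    parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("dual-copy marker expects two hyphen-joined alleles, got '",
           token, "' at ", where, call. = FALSE)
    vals <- sort(vapply(parts, .parse_allele_num, numeric(1), where = where))
    range_check(vals)
    return(paste(.fmt_allele_num(vals), collapse = "-"))
  }
  if (grepl("-", tok, fixed = TRUE))
    stop("hyphen-joined pair '", token,
         "' not allowed at single-copy marker (", where, ")", call. = FALSE)
  if (grepl(",", tok, fixed = TRUE)) {
    parts <- strsplit(tok, ",", fixed = TRUE)[[1]]
    vals <- sort(vapply(parts, .parse_allele_num, numeric(1), where = where))
    range_check(vals)
    return(paste(.fmt_allele_num(vals), collapse = ","))
  }
  val <- .parse_allele_num(tok, where)
  range_check(val)
  .fmt_allele_num(val)
}

# Anomaly kinds carried by a canonical token (zero or more of
# "microvariant", "duplication", "null").
allele_anomalies <- function(token) {
  if (token == "-") return("null")
  kinds <- character(0)
  if (grepl(",", token, fixed = TRUE)) kinds <- c(kinds, "duplication")
  vals <- as.numeric(strsplit(token, "[-,]")[[1]])
  if (any(abs(vals - round(vals)) > 1e-9)) kinds <- c(kinds, "microvariant")
  kinds
}

.find_col <- function(nms, aliases) {
  hit <- which(tolower(nms) %in% aliases)
  if (length(hit)) hit[1] else NA_integer_
}

new_ystr_sample <- function(name, panel, data) {
  stopifnot(inherits(panel, "ystr_panel"), is.data.frame(data))
  stopifnot(all(c("sample_id", "population", "region", "haplogroup",
                  panel$loci$marker) %in% names(data)))
  rownames(data) <- NULL
  structure(list(name = name, panel = panel, data = data),
            class = "ystr_sample")
}

#' Parse a Y-STR haplotype table
#'
#' Reads a tab-delimited haplotype table (see the package dialect: `"-"` for
#' null alleles, hyphen-joined dual-copy pairs, comma-joined duplications,
#' `"."` microvariants) against a marker panel, canonicalizes every allele
#' token (dual-copy pairs sorted in nondecreasing order) and validates values
#' against the panel's allele ranges.
#'
#' @param path Path to the file, or a character vector of lines (length > 1 or
#'   containing a newline), allowing tables to be built in code.
#' @param panel A `ystr_panel` describing the marker columns.
#' @param name Sample collection name.
#' @param strict If `TRUE`, alleles outside the panel's plausible range are
#'   errors; by default they are warnings.
#' @return A `ystr_sample`: list with `name`, `panel` and a `data` frame with
#'   columns `sample_id`, `population`, `region`, `haplogroup` and one
#'   canonical-token column per marker. Row order is preserved.
#' @export
parse_haplotype_table <- function(path, panel, name = "sample",
                                  strict = FALSE) {
  stopifnot(inherits(panel, "ystr_panel"))
  txt <- if (length(path) > 1L || any(grepl("\n", path, fixed = TRUE)))
    textConnection(paste(path, collapse = "\n")) else path
  raw <- utils::read.delim(txt, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  nms <- names(raw)
  id_i  <- .find_col(nms, .ID_ALIASES)
  pop_i <- .find_col(nms, .POP_ALIASES)
  if (is.na(id_i) || is.na(pop_i))
    stop("haplotype table must name an ID column (one of ",
         paste(.ID_ALIASES, collapse = "/"), ") and a population column")
  reg_i <- .find_col(nms, .REG_ALIASES)
  hg_i  <- .find_col(nms, .HG_ALIASES)
  missing <- setdiff(panel$loci$marker, nms)
  if (length(missing))
    stop("haplotype table is missing marker columns: ",
         paste(missing, collapse = ", "))

  n <- nrow(raw)
  out <- data.frame(
    sample_id  = raw[[id_i]],
    population = raw[[pop_i]],
    region     = if (!is.na(reg_i)) raw[[reg_i]] else rep(NA_character_, n),
    haplogroup = if (!is.na(hg_i)) raw[[hg_i]] else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(nrow(panel$loci))) {
    m <- panel$loci$marker[j]
    out[[m]] <- vapply(seq_len(n), function(i) {
      canonical_allele(raw[[m]][i], panel$loci$copy_number[j],
                       panel$loci$min_allele[j], panel$loci$max_allele[j],
                       strict = strict,
                       where = paste0("row ", i, ", column ", m))
    }, character(1))
  }
  new_ystr_sample(name, panel, out)
}

#' Write a Y-STR haplotype table
#'
#' Emits the tab-delimited dialect read by [parse_haplotype_table()]; parsing
#' the result reconstructs the sample field-for-field, and re-writing is
#' byte-stable. The optional `region`/`haplogroup` columns are emitted only
#' when they carry at least one non-missing value.
#'
#' @param sample A `ystr_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(sample, path) {
  stopifnot(inherits(sample, "ystr_sample"))
  d <- sample$data
  cols <- c("sample_id", "population",
            if (any(!is.na(d$region))) "region",
            if (any(!is.na(d$haplogroup))) "haplogroup",
            sample$panel$loci$marker)
  utils::write.table(d[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Per-record anomaly list
#'
#' The anomaly flags are a pure function of the canonical allele states:
#' `"-"` is a null, a comma-joined token a duplication, any fractional repeat
#' a microvariant (a token can carry several kinds).
#'
#' @param sample A `ystr_sample`.
#' @return Data frame with columns `sample_id`, `locus`, `kind`, one row per
#'   (record, locus, kind), ordered by record then panel marker order.
#' @export
record_anomalies <- function(sample) {
  stopifnot(inherits(sample, "ystr_sample"))
  d <- sample$data
  markers <- sample$panel$loci$marker
  rows <- list()
  for (i in seq_len(nrow(d))) {
    for (m in markers) {
      kinds <- allele_anomalies(d[[m]][i])
      for (k in kinds)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = d$sample_id[i], locus = m, kind = k,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), locus = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Aggregate allele anomalies per locus and kind
#'
#' @param sample A `ystr_sample`.
#' @return Data frame `locus`, `kind`, `count`, `sample_ids` (comma-joined),
#'   ordered by panel marker order then kind; empty when the sample carries no
#'   anomalous alleles.
#' @examples
#' p <- build_panel("single_copy_23")
#' s <- simulate_sample(simulation_config(p, seed = 1,
#'   anomaly_rates = c(microvariant = 0.01, duplication = 0.01, null = 0.01)))
#' flag_anomalies(s$samples[[1]])
#' @export
flag_anomalies <- function(sample) {
  long <- record_anomalies(sample)
  if (!nrow(long))
    return(data.frame(locus = character(0), kind = character(0),
                      count = integer(0), sample_ids = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(long$locus, long$kind, sep = "\r")
  agg <- lapply(split(long, key), function(g) {
    data.frame(locus = g$locus[1], kind = g$kind[1], count = nrow(g),
               sample_ids = paste(g$sample_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  ord <- order(match(out$locus, sample$panel$loci$marker), out$kind)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Full-haplotype identity keys
#'
#' Two records share a haplotype only if every canonical allele state matches
#' across the compared markers -- including microvariants, duplications and
#' nulls as distinct states.
#'
#' @param sample A `ystr_sample`.
#' @param markers Markers to compare on (default: all panel markers).
#' @return Character vector of one key per record.
#' @export
haplotype_keys <- function(sample, markers = NULL) {
  stopifnot(inherits(sample, "ystr_sample"))
  if (is.null(markers)) markers <- sample$panel$loci$marker
  missing <- setdiff(markers, sample$panel$loci$marker)
  if (length(missing))
    stop("markers not in sample panel: ", paste(missing, collapse = ", "))
  do.call(paste, c(unname(sample$data[markers]), sep = "|"))
}

#' Split a sample by a grouping column
#'
#' @param sample A `ystr_sample`.
#' @param by Grouping column: `"population"` or `"region"`.
#' @return Named list of `ystr_sample` objects, one per group, in order of
#'   first appearance.
#' @export
split_sample <- function(sample, by = "population") {
  stopifnot(inherits(sample, "ystr_sample"))
  if (!by %in% c("population", "region", "haplogroup"))
    stop("unknown grouping column '", by, "'")
  g <- sample$data[[by]]
  if (all(is.na(g))) stop("grouping column '", by, "' has no values")
  lev <- unique(g[!is.na(g)])
  out <- lapply(lev, function(l) {
    new_ystr_sample(l, sample$panel, sample$data[!is.na(g) & g == l, ])
  })
  names(out) <- lev
  out
}

#' @export
print.ystr_sample <- function(x, ...) {
  cat("Y-STR sample '", x$name, "': ", nrow(x$data), " records, panel '",
      x$panel$name, "' (", nrow(x$panel$loci), " markers)\n", sep = "")
  invisible(x)
}
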