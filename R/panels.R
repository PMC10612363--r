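# Marker panel definitions.
#
# A panel is the catalogue of Y-STR markers a haplotype table carries: marker
# name, copy number (dual-copy markers such as DYS385a/b are typed as an
# unordered allele pair), a mutation-rate class used for simulation defaults
# and reporting, and a plausible allele range used for input validation.

# Yfiler Plus marker catalogue: 25 markers, 27 allele values (DYS385 and
# DYF387S1 each carry two). Allele ranges are deliberately generous -- real
# microvariants and rare alleles fall outside textbook ranges, so range
# violations are warnings unless strict validation is requested.
.YFILER_PLUS_MARKERS <- data.frame(
  marker = c("DYS576", "DYS389I", "DYS635", "DYS389II", "DYS627", "DYS460",
             "DYS458", "DYS19", "YGATAH4", "DYS448", "DYS391", "DYS456",
             "DYS390", "DYS438", "DYS392", "DYS518", "DYS570", "DYS437",
             "DYS385", "DYS449", "DYS393", "DYS439", "DYS481", "DYF387S1",
             "DYS533"),
  copy_number = c(1, 1, 1, 1, 1, 1,
                  1, 1, 1, 1, 1, 1,
                  1, 1, 1, 1, 1, 1,
                  2, 1, 1, 1, 1, 2,
                  1),
  min_allele = c(11, 9, 15, 20, 11, 7,
                 10, 9, 8, 14, 6, 11,
                 17, 6, 4, 30, 10, 12,
                 7, 22, 7, 8, 17, 30,
                 7),
  max_allele = c(25, 17, 29, 37, 27, 14,
                 24, 19, 15, 26, 16, 23,
                 28, 16, 20, 49, 26, 18,
                 28, 40, 18, 17, 32, 44,
                 17),
  stringsAsFactors = FALSE
)

# Default rapidly-mutating single-copy marker set; configurable because the
# canonical RM membership varies between kits and publications.
.RM_DEFAULT <- c("DYS576", "DYS627", "DYS570", "DYS518", "DYS449", "DYS460",
                 "DYS533", "DYS389II")

# Yfiler (17-value) subset of the Yfiler Plus catalogue.
.YFILER17_MARKERS <- c("DYS456", "DYS389I", "DYS390", "DYS389II", "DYS458",
                       "DYS19", "DYS385", "DYS393", "DYS391", "DYS439",
                       "DYS635", "DYS392", "YGATAH4", "DYS437", "DYS438",
                       "DYS448")

.BUILTIN_PANELS <- c("yfiler_plus_27", "single_copy_23", "yfiler_17")

new_locus_panel <- function(name, loci) {
  stopifnot(is.data.frame(loci),
            all(c("marker", "copy_number", "mutation_class",
                  "min_allele", "max_allele") %in% names(loci)))
  if (anyDuplicated(loci$marker))
    stop("duplicate marker names in panel: ",
         paste(unique(loci$marker[duplicated(loci$marker)]), collapse = ", "))
  if (!all(loci$copy_number %in% c(1L, 2L)))
    stop("copy_number must be 1 or 2")
  if (any(loci$min_allele >= loci$max_allele))
    stop("allele range must satisfy min < max for every marker")
  rownames(loci) <- NULL
  structure(list(name = name, loci = loci), class = "ystr_panel")
}

#' Build a Y-STR marker panel
#'
#' Returns the catalogue of markers defining the column layout of a haplotype
#' table: marker names, copy numbers (dual-copy markers carry an unordered
#' allele pair), mutation-rate class, and plausible allele ranges used for
#' validation.
#'
#' Built-in panels:
#' \describe{
#'   \item{`yfiler_plus_27`}{the 25-marker, 27-allele-value expanded panel
#'     (23 single-copy markers plus dual-copy DYS385a/b and DYF387S1a/b);}
#'   \item{`single_copy_23`}{its 23 single-copy markers;}
#'   \item{`yfiler_17`}{the classic 16-marker, 17-value subset.}
#' }
#'
#' Alternatively `name` may be a path to a tab-delimited panel configuration
#' with columns `marker`, `copy_number`, `mutation_class`, `min_allele`,
#' `max_allele`.
#'
#' @param name Built-in panel identifier or path to a panel config file.
#' @param rapidly_mutating Character vector of markers to label as class
#'   `"rapidly_mutating"` in the built-in panels (ignored for config files).
#' @return A `ystr_panel` object: a list with `name` and a `loci` data frame.
#' @examples
#' p <- build_panel("yfiler_plus_27")
#' panel_value_count(p)  # 27
#' @export
build_panel <- function(name, rapidly_mutating = .RM_DEFAULT) {
  if (file.exists(name) && !(name %in% .BUILTIN_PANELS))
    return(read_panel_config(name))
  base <- .YFILER_PLUS_MARKERS
  base$mutation_class <- ifelse(base$marker %in% rapidly_mutating,
                                "rapidly_mutating", "standard")
  loci <- switch(name,
    yfiler_plus_27 = base,
    single_copy_23 = base[base$copy_number == 1L, ],
    yfiler_17      = base[match(.YFILER17_MARKERS, base$marker), ],
    stop("unknown panel '", name, "'; built-in panels are: ",
         paste(.BUILTIN_PANELS, collapse = ", "),
         " (or pass a path to a panel config file)")
  )
  new_locus_panel(name, loci)
}

#' Read a panel definition from a config file
#'
#' @param path Tab-delimited file with columns `marker`, `copy_number`,
#'   `mutation_class`, `min_allele`, `max_allele`.
#' @return A `ystr_panel`.
#' @export
read_panel_config <- function(path) {
  cfg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "copy_number", "mutation_class", "min_allele",
            "max_allele")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("panel config ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  cfg$copy_number <- as.integer(cfg$copy_number)
  new_locus_panel(tools::file_path_sans_ext(basename(path)), cfg[need])
}

#' Write a panel definition to a config file
#'
#' @param panel A `ystr_panel`.
#' @param path Output path (tab-delimited).
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "ystr_panel"))
  utils::write.table(panel$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Total number of allele values carried by a panel
#'
#' Dual-copy markers contribute two values, so e.g. the 25-marker expanded
#' panel carries 27.
#'
#' @param panel A `ystr_panel`.
#' @return Integer value count.
#' @export
panel_value_count <- function(panel) {
  stopifnot(inherits(panel, "ystr_panel"))
  sum(panel$loci$copy_number)
}

#' Marker names of a panel
#'
#' @param panel A `ystr_panel`.
#' @param copy_number Optional filter: keep only markers with this copy number.
#' @return Character vector of marker names in panel order.
#' @export
panel_markers <- function(panel, copy_number = NULL) {
  stopifnot(inherits(panel, "ystr_panel"))
  loci <- panel$loci
  if (!is.null(copy_number)) loci <- loci[loci$copy_number %in% copy_number, ]
  loci$marker
}

#' Restrict a panel to a subset of markers
#'
#' @param panel A `ystr_panel`.
#' @param markers Markers to keep (must all be present); panel order is kept.
#' @return A `ystr_panel` named `<name>_subset`.
#' @export
panel_subset <- function(panel, markers) {
  stopifnot(inherits(panel, "ystr_panel"))
  missing <- setdiff(markers, panel$loci$marker)
  if (length(missing))
    stop("markers not in panel '", panel$name, "': ",
         paste(missing, collapse = ", "))
  new_locus_panel(paste0(panel$name, "_subset"),
                  panel$loci[panel$loci$marker %in% markers, ])
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat("Y-STR panel '", x$name, "': ", nrow(x$loci), " markers, ",
      panel_value_count(x), " allele values (",
      sum(x$loci$copy_number == 2L), " dual-copy)\n", sep = "")
  invisible(x)
}
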