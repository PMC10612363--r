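# Pairwise population distances: haploid AMOVA RST on repeat scores, and
# Nei's (1972) standard genetic distance on allele frequencies.
#
# RST assumes stepwise-mutation dynamics: molecular distance between two
# haplotypes is the squared repeat-count difference summed over loci, and
# variance components come from a one-level haploid AMOVA. Dual-copy loci
# are excluded (allele-to-copy assignment is ambiguous) and microvariants
# are rounded half-up to the nearest integer repeat by default.

new_distance_matrix <- function(labels, values, method, panel_used = NA) {
  stopifnot(length(labels) == nrow(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("distance matrix must be symmetric")
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, method = method,
                 panel_used = panel_used),
            class = "ystr_dist")
}

#' @export
print.ystr_dist <- function(x, ...) {
  cat("Pairwise ", x$method, " distance matrix (", length(x$labels),
      " populations)\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Integer repeat-score matrix for distance/network computations
#'
#' Extracts single-copy loci as integer repeat counts. Records carrying a
#' null or duplicated allele at any included locus are excluded (and logged);
#' microvariants are rounded half-up to the nearest integer, or the whole
#' record dropped with `microvariants = "drop"`.
#'
#' @param sample A `ystr_sample`.
#' @param markers Single-copy markers to include (default: all single-copy
#'   panel markers).
#' @param microvariants `"round"` (default) or `"drop"`.
#' @param dys389_adjust If `TRUE` and both DYS389I and DYS389II are
#'   included, the DYS389I repeat count is subtracted from DYS389II (the
#'   DYS389II amplicon contains the DYS389I stretch; subtraction makes the
#'   two scores independent single-step characters).
#' @return List with `scores` (numeric matrix, one row per retained record,
#'   rownames = sample IDs), `excluded` (data frame `sample_id`, `reason`).
#' @export
repeat_score_matrix <- function(sample, markers = NULL,
                                microvariants = c("round", "drop"),
                                dys389_adjust = FALSE) {
  stopifnot(inherits(sample, "ystr_sample"))
  microvariants <- match.arg(microvariants)
  if (is.null(markers)) markers <- panel_markers(sample$panel, 1L)
  cn <- sample$panel$loci$copy_number[match(markers,
                                            sample$panel$loci$marker)]
  if (any(is.na(cn))) stop("markers not in panel")
  if (any(cn != 1L)) stop("repeat scores require single-copy markers")
  d <- sample$data
  n <- nrow(d)
  drop_reason <- rep(NA_character_, n)
  scores <- matrix(NA_real_, n, length(markers),
                   dimnames = list(d$sample_id, markers))
  for (j in seq_along(markers)) {
    tok <- d[[markers[j]]]
    bad_null <- tok == "-"
    bad_dup <- grepl(",", tok, fixed = TRUE)
    val <- suppressWarnings(as.numeric(tok))
    micro <- !is.na(val) & abs(val - round(val)) > 1e-9
    if (microvariants == "round") {
      val[micro] <- floor(val[micro] + 0.5)
      micro[] <- FALSE
    }
    upd <- is.na(drop_reason) & bad_null
    drop_reason[upd] <- paste0("null@", markers[j])
    upd <- is.na(drop_reason) & bad_dup
    drop_reason[upd] <- paste0("duplication@", markers[j])
    upd <- is.na(drop_reason) & micro
    drop_reason[upd] <- paste0("microvariant@", markers[j])
    scores[, j] <- val
  }
  if (dys389_adjust && all(c("DYS389I", "DYS389II") %in% markers))
    scores[, "DYS389II"] <- scores[, "DYS389II"] - scores[, "DYS389I"]
  keep <- is.na(drop_reason)
  list(scores = scores[keep, , drop = FALSE],
       excluded = data.frame(sample_id = d$sample_id[!keep],
                             reason = drop_reason[!keep],
                             stringsAsFactors = FALSE))
}

# One-level haploid AMOVA RST for two populations of repeat-score vectors.
# Sums of squares are computed from the per-locus sum identities; the
# definitional pair-sum route is used as an independent oracle in the tests.
.rst_two_pops <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y); N <- nx + ny
  if (nx < 2 || ny < 2)
    stop("RST requires at least 2 usable records per population")
  ssd_of <- function(M) {
    # sum over loci of sum_i (x_i - mean)^2
    sum(apply(M, 2, function(v) sum((v - mean(v))^2)))
  }
  Z <- rbind(X, Y)
  ssd_total <- ssd_of(Z)
  ssd_within <- ssd_of(X) + ssd_of(Y)
  sigma_w <- ssd_within / (N - 2)
  msd_a <- (ssd_total - ssd_within) / 1
  n_prime <- (N - (nx^2 + ny^2) / N) / 1
  sigma_a <- (msd_a - sigma_w) / n_prime
  denom <- sigma_a + sigma_w
  if (denom <= 0) return(0)
  min(max(sigma_a / denom, 0), 1)
}

#' Pairwise RST distance matrix
#'
#' One-level haploid AMOVA on squared repeat-count differences summed over
#' single-copy loci, for every pair of populations. Negative variance
#' components are clamped so RST lies in `[0, 1]`.
#'
#' @param samples Named list of `ystr_sample` objects sharing a panel (or a
#'   single sample plus `by` to split it).
#' @param markers Single-copy marker subset (default: all single-copy).
#' @param by If `samples` is a single sample, the grouping column to split on.
#' @param microvariants Passed to [repeat_score_matrix()].
#' @param permutations If `> 0`, per-pair permutation p-values (fraction of
#'   label permutations with RST at least the observed value) are attached
#'   as attribute `"p_values"`.
#' @return A `ystr_dist` with `method = "rst"`; attribute `"excluded"` logs
#'   dropped records per population.
#' @export
rst_pairwise <- function(samples, markers = NULL, by = "population",
                         microvariants = "round", permutations = 0) {
  if (inherits(samples, "ystr_sample")) samples <- split_sample(samples, by)
  stopifnot(length(samples) >= 2)
  labels <- names(samples)
  if (is.null(labels)) labels <- vapply(samples, `[[`, "", "name")
  mats <- lapply(samples, repeat_score_matrix, markers = markers,
                 microvariants = microvariants)
  sizes <- vapply(mats, function(m) nrow(m$scores), integer(1))
  if (any(sizes < 2))
    stop("populations with fewer than 2 usable records: ",
         paste(labels[sizes < 2], collapse = ", "))
  P <- length(samples)
  vals <- matrix(0, P, P)
  pvals <- matrix(NA_real_, P, P)
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    Xi <- mats[[i]]$scores; Xj <- mats[[j]]$scores
    obs <- .rst_two_pops(Xi, Xj)
    vals[i, j] <- vals[j, i] <- obs
    if (permutations > 0) {
      Z <- rbind(Xi, Xj)
      ni <- nrow(Xi)
      ge <- 0L
      for (b in seq_len(permutations)) {
        idx <- sample.int(nrow(Z), ni)
        r <- .rst_two_pops(Z[idx, , drop = FALSE],
                           Z[-idx, , drop = FALSE])
        if (r >= obs - 1e-12) ge <- ge + 1L
      }
      pvals[i, j] <- pvals[j, i] <- (ge + 1) / (permutations + 1)
    }
  }
  out <- new_distance_matrix(labels, vals, "rst")
  attr(out, "excluded") <- lapply(mats, `[[`, "excluded")
  if (permutations > 0) attr(out, "p_values") <- pvals
  out
}

#' Pairwise Nei genetic distance
#'
#' The default `"standard"` variant is Nei's (1972) standard distance
#' D = -ln( J_XY / sqrt(J_X J_Y) ) with the gene identities accumulated as
#' sums over shared single-copy loci of per-allele frequency products; the
#' `"da"` variant is Nei et al.'s (1983) Da = 1 - mean_l sum_a
#' sqrt(p_Xa p_Ya). Microvariants are distinct allele states. A zero
#' between-population identity yields `Inf` with a warning (standard variant
#' only).
#'
#' @inheritParams rst_pairwise
#' @param variant `"standard"` (Nei 1972, default) or `"da"` (Nei 1983).
#' @return A `ystr_dist` with `method = "nei"` (or `"nei_da"`).
#' @export
nei_standard_distance <- function(samples, markers = NULL,
                                  by = "population",
                                  variant = c("standard", "da")) {
  variant <- match.arg(variant)
  if (inherits(samples, "ystr_sample")) samples <- split_sample(samples, by)
  stopifnot(length(samples) >= 2)
  labels <- names(samples)
  if (is.null(labels)) labels <- vapply(samples, `[[`, "", "name")
  panel <- samples[[1]]$panel
  if (is.null(markers)) markers <- panel_markers(panel, 1L)
  freq_tabs <- lapply(samples, function(s) {
    lapply(stats::setNames(markers, markers), function(m) {
      tryCatch(allele_frequencies(s, m)$frequencies,
               error = function(e) NULL)
    })
  })
  P <- length(samples)
  vals <- matrix(0, P, P)
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    jx <- jy <- jxy <- da_sum <- 0
    shared <- 0
    for (m in markers) {
      fx <- freq_tabs[[i]][[m]]; fy <- freq_tabs[[j]][[m]]
      if (is.null(fx) || is.null(fy)) next
      shared <- shared + 1
      jx <- jx + sum(fx^2)
      jy <- jy + sum(fy^2)
      common <- intersect(names(fx), names(fy))
      jxy <- jxy + sum(fx[common] * fy[common])
      da_sum <- da_sum + sum(sqrt(fx[common] * fy[common]))
    }
    if (shared == 0) stop("no shared typed loci between '", labels[i],
                          "' and '", labels[j], "'")
    if (variant == "da") {
      vals[i, j] <- vals[j, i] <- 1 - da_sum / shared
    } else if (jxy == 0) {
      warning("zero between-population gene identity between '", labels[i],
              "' and '", labels[j], "'; distance is Inf")
      vals[i, j] <- vals[j, i] <- Inf
    } else {
      vals[i, j] <- vals[j, i] <- max(-log(jxy / sqrt(jx * jy)), 0)
    }
  }
  new_distance_matrix(labels, vals,
                      if (variant == "da") "nei_da" else "nei")
}

#' Write / read a labeled distance matrix as TSV
#'
#' @param D A `ystr_dist`.
#' @param path File path.
#' @return `path` (write) or a `ystr_dist` (read).
#' @export
write_distance_matrix <- function(D, path) {
  stopifnot(inherits(D, "ystr_dist"))
  df <- data.frame(population = D$labels, D$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param method Method label to attach when reading.
#' @export
read_distance_matrix <- function(path, method = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  new_distance_matrix(labels, unname(vals), method)
}
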