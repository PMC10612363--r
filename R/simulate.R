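# Founder-expansion stepwise-mutation simulator.
#
# Each subpopulation draws records from K founder lineages by a mixture.
# A record copies its founder's allele vector (after the subpopulation's own
# shared drift of `divergence_generations` generations) and adds, per locus,
# the net sum of M ~ Poisson(mu_l * G) single-step mutations, each +1 or -1
# with equal probability. Anomalies (microvariants, duplications, nulls) are
# injected at configurable per-record rates and recorded in a truth log.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.default_mu <- function(panel) {
  ifelse(panel$loci$mutation_class == "rapidly_mutating", 1e-2, 2e-3)
}

#' Build a simulation configuration
#'
#' Defaults describe a haplogroup-structured sample: six founder lineages of
#' which one carries a third of the mixture weight (a strong founder-effect
#' cluster), three geographic subpopulations of realistic sizes, 30
#' generations of lineage depth, and per-locus per-generation mutation rates
#' of 2e-3 (standard) / 1e-2 (rapidly mutating).
#'
#' @param panel A `ystr_panel`.
#' @param founders Number of founder lineages, or a list of
#'   `list(label =, vector =)` specs (`vector` optional; named by marker or
#'   in panel order, dual-copy markers as `c(a, b)` encoded `"a-b"` or a
#'   single base value).
#' @param subpops List of `list(name =, n =, weights =)`; `weights` over
#'   founders (default: the shared default mixture).
#' @param generations Lineage depth G (per-record mutation exposure).
#' @param mu Per-locus per-generation mutation rates (panel order); default
#'   by mutation class.
#' @param divergence_generations Shared drift separating subpopulations:
#'   each subpopulation's founder copies drift independently for this many
#'   generations before records are drawn.
#' @param anomaly_rates Named rates `c(microvariant =, duplication =,
#'   null =)` per record.
#' @param seed Integer seed; the whole simulation is reproducible per seed.
#' @return A `ystr_sim_config` list.
#' @export
simulation_config <- function(panel,
                              founders = 6,
                              subpops = NULL,
                              generations = 30,
                              mu = NULL,
                              divergence_generations = 0,
                              anomaly_rates = c(microvariant = 0,
                                                duplication = 0, null = 0),
                              seed = NULL) {
  stopifnot(inherits(panel, "ystr_panel"))
  if (is.numeric(founders) && length(founders) == 1L) {
    K <- as.integer(founders)
    founders <- lapply(seq_len(K), function(k)
      list(label = paste0("F", k), vector = NULL))
  }
  K <- length(founders)
  default_w <- if (K == 1) 1 else {
    w <- rep((1 - 1 / 3) / (K - 1), K); w[1] <- 1 / 3; w
  }
  if (is.null(subpops))
    subpops <- list(list(name = "pop1", n = 80),
                    list(name = "pop2", n = 253),
                    list(name = "pop3", n = 135))
  subpops <- lapply(subpops, function(sp) {
    if (is.null(sp$weights)) sp$weights <- default_w
    if (abs(sum(sp$weights) - 1) > 1e-9)
      stop("founder mixture weights must sum to 1 in subpopulation '",
           sp$name, "'")
    if (sp$n < 1) stop("subpopulation sizes must be >= 1")
    sp
  })
  if (is.null(mu)) mu <- .default_mu(panel)
  stopifnot(length(mu) == nrow(panel$loci), all(mu >= 0), all(mu <= 1))
  ar <- c(microvariant = 0, duplication = 0, null = 0)
  ar[names(anomaly_rates)] <- anomaly_rates
  stopifnot(all(ar >= 0), all(ar <= 1))
  structure(list(panel = panel, founders = founders, subpops = subpops,
                 generations = generations, mu = mu,
                 divergence_generations = divergence_generations,
                 anomaly_rates = ar, seed = seed),
            class = "ystr_sim_config")
}

# net displacement after M ~ Poisson(lambda) symmetric single-step mutations
.net_steps <- function(lambda, n) {
  m <- stats::rpois(n, lambda)
  vapply(m, function(mm) if (mm == 0) 0L else
    sum(sample(c(-1L, 1L), mm, replace = TRUE)), integer(1))
}

.random_founder_values <- function(panel) {
  # integer base allele per marker, uniform within the plausible range
  # (trimmed by 1 to leave mutation headroom)
  vapply(seq_len(nrow(panel$loci)), function(j) {
    lo <- ceiling(panel$loci$min_allele[j]) + 2L
    hi <- floor(panel$loci$max_allele[j]) - 2L
    if (lo >= hi) ceiling((lo + hi) / 2) else sample(lo:hi, 1L)
  }, numeric(1))
}

#' Simulate haplogroup-structured Y-STR samples
#'
#' @param config A `ystr_sim_config` from [simulation_config()].
#' @return List with `samples` (one `ystr_sample` per subpopulation),
#'   `combined` (all records, population = subpopulation name, haplogroup =
#'   founder label), and `truth`: `records` (founder assignment and total
#'   mutation count per record), `anomalies` (injected anomalies:
#'   `sample_id`, `locus`, `kind`), `founder_vectors`.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "ystr_sim_config"))
  .with_seed(config$seed, {
    panel <- config$panel
    loci <- panel$loci
    L <- nrow(loci)
    K <- length(config$founders)
    mu <- config$mu
    # founder base vectors (per marker; dual-copy second value = base + 1)
    base <- lapply(config$founders, function(f) {
      if (!is.null(f$vector)) as.numeric(f$vector)
      else .random_founder_values(panel)
    })
    flabels <- vapply(config$founders, `[[`, "", "label")

    all_rows <- list(); truth_rec <- list(); truth_anom <- list()
    for (si in seq_along(config$subpops)) {
      sp <- config$subpops[[si]]
      # shared subpopulation drift of each founder lineage
      sub_base <- lapply(base, function(b) {
        b + .net_steps(mu * config$divergence_generations, L)
      })
      f_idx <- sample.int(K, sp$n, replace = TRUE, prob = sp$weights)
      for (i in seq_len(sp$n)) {
        sid <- paste0(sp$name, "_", i)
        f <- f_idx[i]
        steps1 <- .net_steps(mu * config$generations, L)
        vec1 <- pmax(sub_base[[f]] + steps1, 1)
        # dual-copy markers carry a second copy, mutated independently
        steps2 <- .net_steps(mu * config$generations, L)
        vec2 <- pmax(sub_base[[f]] + 1 + steps2, 1)
        nmut <- sum(abs(steps1)) + sum(abs(steps2[loci$copy_number == 2L]))
        tok <- character(L)
        for (j in seq_len(L)) {
          tok[j] <- if (loci$copy_number[j] == 2L) {
            paste(.fmt_allele_num(sort(c(vec1[j], vec2[j]))), collapse = "-")
          } else .fmt_allele_num(vec1[j])
        }
        # anomaly injection: distinct loci per kind within a record
        sc <- which(loci$copy_number == 1L)
        avail <- sc
        inject <- function(kind) {
          if (stats::runif(1) < config$anomaly_rates[[kind]] &&
              length(avail) > 0) {
            j <- if (length(avail) == 1L) avail else sample(avail, 1L)
            avail <<- setdiff(avail, j)
            tok[j] <<- switch(kind,
              microvariant = .fmt_allele_num(vec1[j] + 0.2),
              duplication = paste(.fmt_allele_num(c(vec1[j], vec1[j] + 1)),
                                  collapse = ","),
              null = "-")
            truth_anom[[length(truth_anom) + 1L]] <<- data.frame(
              sample_id = sid, locus = loci$marker[j], kind = kind,
              stringsAsFactors = FALSE)
          }
        }
        inject("microvariant"); inject("duplication"); inject("null")
        row <- c(list(sample_id = sid, population = sp$name,
                      region = NA_character_, haplogroup = flabels[f]),
                 stats::setNames(as.list(tok), loci$marker))
        all_rows[[length(all_rows) + 1L]] <- row
        truth_rec[[length(truth_rec) + 1L]] <- data.frame(
          sample_id = sid, subpop = sp$name, founder = flabels[f],
          mutations = nmut, stringsAsFactors = FALSE)
      }
    }
    data <- do.call(rbind, lapply(all_rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    combined <- new_ystr_sample("simulated", panel, data)
    samples <- split_sample(combined, "population")
    anomalies <- if (length(truth_anom)) do.call(rbind, truth_anom) else
      data.frame(sample_id = character(0), locus = character(0),
                 kind = character(0), stringsAsFactors = FALSE)
    list(samples = samples, combined = combined,
         truth = list(records = do.call(rbind, truth_rec),
                      anomalies = anomalies,
                      founder_vectors = stats::setNames(base, flabels)))
  })
}

#' Construct a sample with an exact multiplicity spectrum
#'
#' Builds distinct haplotypes (random base vector plus deterministic
#' per-haplotype offsets, so distinctness is guaranteed) and repeats each as
#' requested, so the resulting sample's [multiplicity_spectrum()] matches
#' `shape` exactly.
#'
#' @param shape Named vector mapping multiplicity to number of distinct
#'   haplotypes, e.g. `c("10" = 1, "4" = 2, "3" = 3, "2" = 20, "1" = 401)`.
#' @param panel A `ystr_panel` (default `"yfiler_plus_27"`).
#' @param name Sample name / population label.
#' @param seed Optional seed for the random base haplotype.
#' @return A `ystr_sample` of size `sum(m * shape[m])`.
#' @export
make_fixture_spectrum <- function(shape, panel = build_panel("yfiler_plus_27"),
                                  name = "fixture", seed = NULL) {
  m <- as.integer(names(shape))
  cnt <- as.integer(shape)
  if (any(is.na(m)) || any(m < 1L) || any(cnt < 0L))
    stop("shape must map positive multiplicities to nonnegative counts")
  .with_seed(seed, {
    loci <- panel$loci
    sc <- which(loci$copy_number == 1L)
    if (length(sc) < 2) stop("panel needs at least 2 single-copy markers")
    # base at the low end of each range so the +0..4 offsets stay in bounds
    base <- ceiling(loci$min_allele) + sample(0:1, nrow(loci),
                                              replace = TRUE)
    distinct <- sum(cnt)
    # deterministic distinct offsets: digits of j in base 5 over the
    # single-copy loci, added to the base alleles
    vecs <- lapply(seq_len(distinct) - 1L, function(j) {
      v <- base
      rem <- j; pos <- 1L
      while (rem > 0) {
        if (pos > length(sc)) stop("spectrum too large for panel capacity")
        v[sc[pos]] <- v[sc[pos]] + rem %% 5L
        rem <- rem %/% 5L
        pos <- pos + 1L
      }
      v
    })
    mult <- rep(m, cnt)
    rows <- list()
    rid <- 0L
    for (h in seq_len(distinct)) {
      v <- vecs[[h]]
      tok <- vapply(seq_len(nrow(loci)), function(j) {
        if (loci$copy_number[j] == 2L)
          paste(.fmt_allele_num(c(v[j], v[j] + 1)), collapse = "-")
        else .fmt_allele_num(v[j])
      }, character(1))
      for (r in seq_len(mult[h])) {
        rid <- rid + 1L
        rows[[rid]] <- c(list(sample_id = paste0("S", rid),
                              population = name,
                              region = NA_character_,
                              haplogroup = NA_character_),
                         stats::setNames(as.list(tok), loci$marker))
      }
    }
    data <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    new_ystr_sample(name, panel, data)
  })
}
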