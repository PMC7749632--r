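#' Protocell state
#'
#' A protocell: its oligonucleotide pool, the genome its fragments map to,
#' a cycle and generation counter, a fixed diameter (volume growth is
#' modeled implicitly by the doubling division trigger), and the multiset
#' of inert dead-end duplexes that no longer denature.
#'
#' @param pool a [vcg_pool()].
#' @param genome the [vcg_genome()] the pool maps onto.
#' @param diameter protocell diameter in meters. The default 50 nm gives a
#'   vesicle holding on the order of a hundred oligonucleotide molecules
#'   under the reference concentration ledger — small enough for exact
#'   molecule-level simulation while preserving the gradient structure.
#' @return an object of class `vcg_protocell`.
#' @export
protocell_state <- function(pool, genome, diameter = 5e-8) {
  stopifnot(inherits(pool, "vcg_pool"), inherits(genome, "vcg_genome"),
            diameter > 0)
  structure(list(pool = pool, genome = genome, cycle = 0L,
                 generation = 0L, diameter = diameter,
                 inert = data.frame(seq_a = character(),
                                    seq_b = character(),
                                    count = numeric(),
                                    stringsAsFactors = FALSE),
                 last = NULL),
            class = "vcg_protocell")
}

#' @export
print.vcg_protocell <- function(x, ...) {
  cat("Protocell (cycle ", x$cycle, ", generation ", x$generation,
      "): ", sum(x$pool$species$count), " oligos, ",
      oligo_units(x$pool), " nt, ", sum(x$inert$count),
      " inert duplexes\n", sep = "")
  invisible(x)
}

#' Divide a protocell by binomial segregation
#'
#' Every molecule — oligonucleotide, fed monomer and bridged dinucleotide,
#' and each inert duplex as a unit — is assigned independently to one of
#' two daughters with probability 1/2. Counts sum exactly to the parent's;
#' there is no machinery controlling the partition.
#'
#' @param state a [protocell_state()].
#' @param seed optional integer seed.
#' @return list of two `vcg_protocell` daughters (`a`, `b`), generation
#'   incremented.
#' @export
divide <- function(state, seed = NULL) {
  stopifnot(inherits(state, "vcg_protocell"))
  if (!is.null(seed)) set.seed(seed)
  split_counts <- function(n)
    stats::setNames(stats::rbinom(length(n), as.integer(n), 0.5), names(n))
  mk <- function() {
    d <- state
    d$generation <- state$generation + 1L
    d
  }
  a <- mk(); b <- mk()
  sa <- split_counts(state$pool$species$count)
  a$pool$species$count <- sa
  b$pool$species$count <- state$pool$species$count - sa
  a$pool$species <- a$pool$species[a$pool$species$count > 0, , drop = FALSE]
  b$pool$species <- b$pool$species[b$pool$species$count > 0, , drop = FALSE]
  for (f in c("monomers", "bridged")) {
    fa <- split_counts(state$pool$fed[[f]])
    a$pool$fed[[f]] <- fa
    b$pool$fed[[f]] <- state$pool$fed[[f]] - fa
  }
  ia <- split_counts(state$inert$count)
  a$inert$count <- ia
  b$inert$count <- state$inert$count - ia
  a$inert <- a$inert[a$inert$count > 0, , drop = FALSE]
  b$inert <- b$inert[b$inert$count > 0, , drop = FALSE]
  # the ledger history stays with the lineage; daughters share it
  list(a = a, b = b)
}

#' Probability of losing a genome region at division
#'
#' With `N` independent molecules covering a region, the probability that
#' at least one daughter inherits none of them is `2 * (1/2)^N = 2^(1-N)`
#' (for `N = 0` the loss is certain). This is the closed form behind the
#' stability of distributed genomes at high copy number.
#'
#' @param N per-region minimum copy number (vectorised).
#' @return probability in \[0, 1\].
#' @examples
#' region_loss_probability(10)  # ~1.95e-3
#' @export
region_loss_probability <- function(N) {
  stopifnot(all(N >= 0))
  ifelse(N == 0, 1, pmin(1, 2^(1 - N)))
}

#' Average per-oligo extension needed to double a gradient genome
#'
#' Under a length-abundance gradient with ratio `r`, shifting every oligo
#' up by `m` length classes (with the bottom class replenished by
#' initiation at its prior inflow) multiplies every class by r^m:
#' class counts obey `c_k = A r^(-k)`, so `c_(k-m) = r^m c_k`. Doubling
#' the ensemble therefore needs the smallest `m` with r^m at least 2;
#' with ratio 2 the elongation of every oligonucleotide by one nucleotide on
#' average replicates the entire genome.
#'
#' @param r gradient ratio (> 1).
#' @return list with `m` (minimal integer extension), `m_real`
#'   (`ln 2 / ln r`), and `growth_factor(m)` giving the per-class
#'   multiplication for an average extension of `m` nt.
#' @export
doubling_extension_requirement <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || r <= 1)
    stop("gradient ratio must exceed 1 for a finite doubling extension")
  m_real <- log(2) / log(r)
  list(m = as.integer(ceiling(m_real - 1e-9)), m_real = m_real,
       growth_factor = function(m) r^m)
}

#' Idealized replication: shift a length distribution up the gradient
#'
#' The deterministic arithmetic of distributed replication: every oligo
#' grows by exactly `m` nucleotides, moving each length class `k` to
#' `k + m`, while initiation replenishes the bottom `m` classes at r^m
#' times their prior occupancy (their steady inflow under the gradient).
#' For counts on an exact gradient every class is multiplied by r^m.
#'
#' @param counts named numeric vector of class counts (names = lengths).
#' @param r gradient ratio.
#' @param m average extension in nucleotides (integer >= 1).
#' @return numeric vector of the same shape: the post-replication counts.
#' @export
ideal_replication_shift <- function(counts, r, m = 1) {
  stopifnot(m >= 1, r > 1, !is.null(names(counts)))
  lens <- as.integer(names(counts))
  out <- counts
  for (i in seq_along(lens)) {
    src <- match(lens[i] - m, lens)
    out[i] <- if (!is.na(src)) counts[src] else counts[i] * r^m
  }
  out
}

# nucleotide-weighted fraction of pool oligos mapping exactly to the circle
exact_mapping_fraction <- function(genome, pool, cache = NULL) {
  sp <- pool$species
  if (!nrow(sp)) return(NA_real_)
  uq <- unique(sp$seq)
  ok <- vapply(uq, function(s) {
    if (!is.null(cache)) {
      hit <- cache[[s]]
      if (!is.null(hit)) return(hit)
    }
    res <- nchar(s) <= genome$L && nrow(map_oligo(genome, s, 0)) > 0
    if (!is.null(cache)) cache[[s]] <- res
    res
  }, logical(1))
  units <- nchar(sp$seq) * sp$count
  sum(units[ok[match(sp$seq, uq)]]) / sum(units)
}

#' Run a protocell lineage through growth and division
#'
#' Iterates [step_cycle()]; when the division trigger fires the protocell
#' divides by binomial segregation and the run follows one random daughter
#' (lineage view). The `mass_doubling` trigger fires when total oligo
#' nucleotide units (including inert duplexes) reach twice their value at
#' the last division — replication defined as doubling of the ensemble;
#' `every_k_cycles` divides on a fixed schedule regardless of growth.
#'
#' @param state a [protocell_state()].
#' @param params a [sim_params()].
#' @param n_generations generations (divisions) to run.
#' @param division_trigger `"mass_doubling"` or `"every_k_cycles"`.
#' @param k_cycles cycles per generation for the fixed schedule.
#' @param max_cycles_per_generation cap on cycles within one generation
#'   for the `mass_doubling` trigger: if the ensemble has not doubled by
#'   then, division happens anyway (protocell division is ultimately
#'   imposed by the environment, not by replication progress).
#' @param max_cycles hard cap on total cycles.
#' @param seed integer master seed; annealing/chemistry and division draw
#'   from substreams derived from it.
#' @return list with `state` (final), `metrics` (one row per generation:
#'   cycle, molecule and nucleotide totals, fitted gradient ratio,
#'   coverage intactness, exact-mapping fraction, inert fraction),
#'   `extinct`, and `generations`.
#' @export
run_lineage <- function(state, params = sim_params(), n_generations = 5,
                        division_trigger = c("mass_doubling",
                                             "every_k_cycles"),
                        k_cycles = 10, max_cycles_per_generation = 60,
                        max_cycles = 2000, seed = NULL) {
  division_trigger <- match.arg(division_trigger)
  stopifnot(inherits(state, "vcg_protocell"))
  if (!is.null(seed)) set.seed(substream_seed(seed, "lineage"))
  map_cache <- new.env(parent = emptyenv())
  metrics <- list()
  record <- function(st) {
    ld <- length_distribution(st$pool)
    r_hat <- tryCatch(estimate_gradient_ratio(st$pool)$ratio,
                      error = function(e) NA_real_)
    cp <- coverage_profile(st$genome, st$pool)
    inert_units <- if (nrow(st$inert))
      sum((nchar(st$inert$seq_a) + nchar(st$inert$seq_b)) *
            st$inert$count) else 0
    metrics[[length(metrics) + 1L]] <<- data.frame(
      generation = st$generation, cycle = st$cycle,
      n_molecules = sum(st$pool$species$count),
      nt_units = oligo_units(st$pool),
      r_hat = r_hat, intact = cp$intact,
      exact_fraction = exact_mapping_fraction(st$genome, st$pool,
                                              map_cache),
      inert_fraction = inert_units /
        max(1, oligo_units(st$pool) + inert_units))
  }
  record(state)
  baseline <- oligo_units(state$pool) + inert_units_of(state)
  extinct <- FALSE
  total_cycles <- 0L
  gen_cycles <- 0L
  while (state$generation < n_generations && total_cycles < max_cycles) {
    state <- step_cycle(state, params)
    total_cycles <- total_cycles + 1L
    gen_cycles <- gen_cycles + 1L
    if (sum(state$pool$species$count) == 0) { extinct <- TRUE; break }
    trigger <- switch(division_trigger,
      mass_doubling = (oligo_units(state$pool) + inert_units_of(state)) >=
        2 * baseline || gen_cycles >= max_cycles_per_generation,
      every_k_cycles = gen_cycles >= k_cycles)
    if (trigger) {
      daughters <- divide(state)
      state <- if (stats::runif(1) < 0.5) daughters$a else daughters$b
      baseline <- max(1, oligo_units(state$pool) + inert_units_of(state))
      gen_cycles <- 0L
      record(state)
      if (sum(state$pool$species$count) == 0) { extinct <- TRUE; break }
    }
  }
  list(state = state, metrics = do.call(rbind, metrics),
       extinct = extinct, generations = state$generation)
}

inert_units_of <- function(state) {
  if (!nrow(state$inert)) return(0)
  sum((nchar(state$inert$seq_a) + nchar(state$inert$seq_b)) *
        state$inert$count)
}
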