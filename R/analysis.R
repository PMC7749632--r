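#' Ribozyme copy number required to sustain a membrane flux
#'
#' How many ribozyme molecules must a protocell assemble per generation for
#' a membrane-modifying activity to matter? With `lipid_count` lipids of
#' which a fraction `modified_fraction` must be modified, at `turnover`
#' catalytic events per ribozyme per minute over a `generation_time` in
#' minutes, the requirement is
#' `lipid_count * modified_fraction / (turnover * generation_time)`.
#' The reference scenario — 2e9 lipids, 5\% modified, 1/min turnover, one
#' day (1e3 min) generation — needs ~1e5 ribozyme molecules.
#'
#' @param lipid_count membrane lipid molecules.
#' @param modified_fraction fraction of lipids to modify (0-1].
#' @param turnover catalytic turnover per ribozyme, per minute.
#' @param generation_time protocell generation time in minutes.
#' @return required ribozyme molecule count.
#' @examples
#' ribozyme_requirement(2e9, 0.05, 1, 1e3)  # 1e5
#' @export
ribozyme_requirement <- function(lipid_count, modified_fraction,
                                 turnover = 1, generation_time = 1e3) {
  stopifnot(lipid_count > 0, modified_fraction >= 0,
            modified_fraction <= 1, turnover > 0, generation_time > 0)
  lipid_count * modified_fraction / (turnover * generation_time)
}

#' Lipid molecules in a protocell's bilayer membrane
#'
#' Two leaflets times the sphere surface area divided by the area per
#' lipid head group. At 0.32 nm^2 per molecule a 10 um vesicle carries
#' about 2e9 lipids.
#'
#' @param diameter vesicle diameter in meters.
#' @param area_per_lipid head-group area in nm^2 (default 0.32, typical
#'   for fatty-acid membranes).
#' @return lipid molecule count.
#' @examples
#' lipid_count(10e-6)  # ~1.96e9
#' @export
lipid_count <- function(diameter, area_per_lipid = 0.32) {
  stopifnot(all(diameter > 0), area_per_lipid > 0)
  area_m2 <- 4 * pi * (diameter / 2)^2
  2 * area_m2 / (area_per_lipid * 1e-18)
}

#' Duplex stability versus length under the concentration gradient
#'
#' Per length class `k`: the pairing stability `k * |dG_bp|`, the
#' concentration correction `RT * ln(c_k / c_anchor)` from the gradient,
#' and their sum. Because melting temperature depends on both strand
#' concentration and length, a steep gradient flattens the stability
#' (hence Tm) versus length slope by `RT * ln r` per added nucleotide: a
#' twofold concentration step per length class is worth `RT ln 2`
#' (0.41 kcal/mol at 298 K) against the ~2.5 kcal/mol a base pair adds.
#' In the constructed limit `|dG_bp| = RT ln r` the net profile is flat —
#' a constant duplex Tm independent of length.
#'
#' @param gradient a [gradient_spec()].
#' @param params an [energy_params()].
#' @param min_len,max_len length range to tabulate.
#' @return data.frame with `length`, `stability`, `concentration`,
#'   `correction`, `net` (kcal/mol); the per-nucleotide flattening
#'   `RT * ln r` is attached as attribute `flattening_per_nt`.
#' @export
tm_profile <- function(gradient = gradient_spec(),
                       params = energy_params(), min_len = 2,
                       max_len = 12) {
  stopifnot(inherits(gradient, "vcg_gradient"), min_len <= max_len)
  rt <- rt_energy(params)
  k <- min_len:max_len
  conc <- gradient_concentration(gradient, k)
  c_ref <- gradient$anchor_concentration
  out <- data.frame(length = k,
                    stability = k * abs(params$dG_bp),
                    concentration = conc,
                    correction = rt * log(conc / c_ref))
  out$net <- out$stability + out$correction
  attr(out, "flattening_per_nt") <- rt * log(gradient$ratio)
  out
}

#' Error-threshold experiment over a grid of incorporation error rates
#'
#' Runs replicate protocell lineages at each per-incorporation error rate
#' `eps` and tracks the decay of genomic identity: the fraction of oligo
#' nucleotides residing in oligos that still map to the circle with zero
#' mismatches, and coverage intactness. The summary statistic `eps_star`
#' is the smallest grid error rate at which the pooled exact-mapping
#' fraction after `n_generations` (total exactly-mapping nucleotides over
#' total nucleotides, pooled across replicate lineages) falls below 0.5 —
#' the simulated analogue of the error-catastrophe bound at roughly the
#' reciprocal genome length.
#'
#' @param genome a [vcg_genome()]; the grid should span both sides of
#'   `1/L`.
#' @param eps_grid increasing vector of error rates.
#' @param n_generations generations per run.
#' @param seeds integer vector; one lineage per (eps, seed).
#' @param params a [sim_params()] (its reaction `eps` is overridden per
#'   grid point).
#' @param diameter protocell diameter (sets the ensemble size); the
#'   default 65 nm keeps several hundred nucleotide units in play through
#'   the final generation.
#' @param gradient a [gradient_spec()] for pool initialisation.
#' @param division_trigger,k_cycles generation schedule; the default —
#'   division every 200 cycles for 3 generations — makes the cumulative
#'   nucleotide synthesis over a run comparable to the initial ensemble
#'   size (roughly one full distributed replication of the genome) while
#'   keeping enough material through the last generation for the pooled
#'   fraction to be informative.
#' @param ... further arguments passed to [run_lineage()].
#' @return list with `table` (eps x generation means of `exact_fraction`
#'   and `intact`), `runs` (per-run final values), `final` (per-eps pooled
#'   final exact fraction with its binomial standard error), and
#'   `eps_star`.
#' @export
error_threshold_experiment <- function(genome,
                                       eps_grid = c(0.01, 0.03, 0.0625,
                                                    0.125, 0.25),
                                       n_generations = 3,
                                       seeds = 1:4,
                                       params = sim_params(),
                                       diameter = 6.5e-8,
                                       gradient = gradient_spec(),
                                       division_trigger = "every_k_cycles",
                                       k_cycles = 200, ...) {
  stopifnot(inherits(genome, "vcg_genome"), all(diff(eps_grid) > 0))
  runs <- list()
  rows <- list()
  for (eps in eps_grid) {
    p <- params
    p$reaction$eps <- eps
    for (sd in seeds) {
      set.seed(substream_seed(sd, paste0("errthr", eps)))
      pool <- init_gradient_pool(genome, gradient,
                                 volume = protocell_volume(diameter),
                                 reaction = p$reaction)
      st <- protocell_state(pool, genome, diameter)
      res <- run_lineage(st, p, n_generations = n_generations,
                         division_trigger = division_trigger,
                         k_cycles = k_cycles, ...)
      m <- res$metrics
      m$eps <- eps
      m$seed <- sd
      rows[[length(rows) + 1L]] <- m
      runs[[length(runs) + 1L]] <- data.frame(
        eps = eps, seed = sd, generations = res$generations,
        extinct = res$extinct,
        final_exact = m$exact_fraction[nrow(m)],
        final_units = m$nt_units[nrow(m)],
        final_intact = m$intact[nrow(m)])
    }
  }
  all_m <- do.call(rbind, rows)
  tab <- stats::aggregate(cbind(exact_fraction, intact) ~ eps + generation,
                          data = all_m, FUN = mean)
  tab <- tab[order(tab$eps, tab$generation), ]
  runs <- do.call(rbind, runs)
  # pooled final fraction per eps: total exact nucleotides / total
  # nucleotides across replicate lineages
  final <- do.call(rbind, lapply(split(runs, runs$eps), function(d) {
    tot <- sum(d$final_units)
    frac <- sum(d$final_exact * d$final_units) / tot
    data.frame(eps = d$eps[1], pooled_exact = frac,
               se = sqrt(frac * (1 - frac) / tot), units = tot)
  }))
  rownames(final) <- NULL
  below <- final$eps[final$pooled_exact < 0.5]
  list(table = tab, runs = runs, final = final,
       eps_star = if (length(below)) min(below) else NA_real_)
}
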