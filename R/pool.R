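# End-state vocabularies for oligonucleotide chemistry.
P5_STATES <- c("hydroxyl", "phosphate", "activated_2AI", "blocked")
P3_STATES <- c("diol", "cyclic_phosphate", "phosphate_2p", "phosphate_3p",
               "blocked_terminator")

# An oligo can be extended at its 3' end by primer extension or ligation
# only from a 2',3'-diol or (via a pyrophosphate linkage) a 3'-phosphate.
extendable_3p <- function(p3) p3 %in% c("diol", "phosphate_3p")
# Only a 2AI-activated 5' phosphate can be attacked by an upstream primer.
ligatable_5p <- function(p5) p5 == "activated_2AI"

species_frame <- function(seq = character(), p5 = character(),
                          p3 = character(), stalled = logical(),
                          pp = character(), count = numeric()) {
  data.frame(seq = seq, p5 = p5, p3 = p3, stalled = stalled, pp = pp,
             count = count, stringsAsFactors = FALSE)
}

validate_species <- function(sp) {
  stopifnot(all(c("seq", "p5", "p3", "stalled", "pp", "count") %in%
                  names(sp)))
  if (nrow(sp)) {
    stopifnot(all(nchar(sp$seq) >= 1), all(sp$p5 %in% P5_STATES),
              all(sp$p3 %in% P3_STATES), all(sp$count >= 0))
  }
  sp
}

aggregate_species <- function(sp) {
  if (!nrow(sp)) return(sp)
  key <- paste(sp$seq, sp$p5, sp$p3, sp$stalled, sp$pp, sep = "\r")
  agg <- rowsum(sp$count, key)
  first <- sp[match(rownames(agg), key), , drop = FALSE]
  first$count <- as.numeric(agg[, 1])
  rownames(first) <- NULL
  first[first$count > 0, , drop = FALSE]
}

dinuc_names <- function(alphabet = "ACGU") {
  b <- alphabet_bases(alphabet)
  as.vector(outer(b, b, paste0))
}

empty_fed <- function(alphabet = "ACGU") {
  b <- alphabet_bases(alphabet)
  list(monomers = stats::setNames(numeric(length(b)), b),
       bridged = stats::setNames(numeric(length(b)^2),
                                 dinuc_names(alphabet)))
}

#' Oligonucleotide pool
#'
#' A pool is the protocell's molecular inventory: a multiset of
#' oligonucleotide species (sequence plus explicit 5'/3' end chemistry),
#' the fed small-molecule species (2AI-activated monomers and
#' imidazolium-bridged dinucleotides, keyed by base / dinucleotide
#' sequence), and a vesicle volume giving the count/concentration duality.
#'
#' @param species data.frame with columns `seq`, `p5`, `p3`, `stalled`,
#'   `pp` (comma-separated 1-based pyrophosphate bond positions, `""` if
#'   none), `count`.
#' @param fed list with named numeric vectors `monomers` and `bridged`
#'   (molecule counts).
#' @param volume vesicle volume in liters.
#' @param alphabet genome alphabet the pool lives on.
#' @return an object of class `vcg_pool`.
#' @export
vcg_pool <- function(species = species_frame(), fed = NULL,
                     volume = 1e-15, alphabet = "ACGU") {
  stopifnot(volume > 0)
  if (is.null(fed)) fed <- empty_fed(alphabet)
  stopifnot(all(fed$monomers >= 0), all(fed$bridged >= 0))
  structure(list(species = validate_species(species), fed = fed,
                 volume = volume, alphabet = alphabet,
                 ledger = list(fed_units = 0, lost_units = 0,
                               lig_leaving = 0)),
            class = "vcg_pool")
}

#' @export
print.vcg_pool <- function(x, ...) {
  cat("VCG oligonucleotide pool: ", sum(x$species$count), " molecules (",
      nrow(x$species), " species, ", oligo_units(x),
      " nt), volume ", format(x$volume, digits = 3), " L\n", sep = "")
  cat("  fed: ", sum(x$fed$monomers), " activated monomers, ",
      sum(x$fed$bridged), " bridged dinucleotides\n", sep = "")
  invisible(x)
}

#' Total oligonucleotide mass of a pool in nucleotide units
#' @param pool a [vcg_pool()].
#' @export
oligo_units <- function(pool) {
  if (!nrow(pool$species)) return(0)
  sum(nchar(pool$species$seq) * pool$species$count)
}

#' Length-vs-abundance gradient specification
#'
#' The defining assumption of the concentration-versus-length profile: the
#' total concentration of length-k oligos is
#' `anchor_concentration * r^(anchor_length - k)`, i.e. consecutive length
#' classes differ by the n/(n+1) abundance ratio `r`. The reference
#' gradient anchors dinucleotides at 1 mM with r = 2 (so trimers sit at
#' 0.5 mM and 12-mers at ~1 uM).
#'
#' @param ratio the n/(n+1) abundance ratio r (> 0; r = 1 is a flat pool).
#' @param anchor_length,anchor_concentration the length class (nt) and its
#'   total concentration (molar) that anchor the gradient.
#' @return an object of class `vcg_gradient`.
#' @export
gradient_spec <- function(ratio = 2, anchor_length = 2,
                          anchor_concentration = 1e-3) {
  stopifnot(ratio > 0, anchor_length >= 1, anchor_concentration > 0)
  structure(list(ratio = ratio, anchor_length = anchor_length,
                 anchor_concentration = anchor_concentration),
            class = "vcg_gradient")
}

#' Total concentration of a length class under a gradient
#' @param gradient a [gradient_spec()].
#' @param k length class (nt).
#' @return molar concentration.
#' @export
gradient_concentration <- function(gradient, k) {
  gradient$anchor_concentration *
    gradient$ratio^(gradient$anchor_length - k)
}

#' Initialise a gradient pool over a virtual circular genome
#'
#' Distributes the total concentration of each length class uniformly over
#' its `2 * L` placements (both strands, every start), converts
#' concentrations to molecule counts for the given volume with stochastic
#' rounding (so sub-single-molecule expectations remain simulable in tiny
#' vesicles), and draws each oligo's 5' activation state: activated (2AI)
#' with probability `p_act0`, else plain phosphate. All 3' termini start as
#' 2',3'-diols. Fed species are stocked to the chemostat set-points in
#' `reaction`.
#'
#' @param genome a [vcg_genome()].
#' @param gradient a [gradient_spec()].
#' @param min_len,max_len fragment length range.
#' @param volume vesicle volume in liters.
#' @param reaction a [reaction_params()] (supplies `p_act0` and the feed
#'   set-points).
#' @param seed optional integer seed.
#' @return a [vcg_pool()].
#' @export
init_gradient_pool <- function(genome, gradient = gradient_spec(),
                               min_len = 2, max_len = 12,
                               volume = protocell_volume(5e-8),
                               reaction = reaction_params(),
                               seed = NULL) {
  stopifnot(inherits(genome, "vcg_genome"),
            inherits(gradient, "vcg_gradient"))
  if (!is.null(seed)) set.seed(seed)
  frags <- enumerate_fragments(genome, min_len, max_len)
  conc_k <- gradient_concentration(gradient, frags$length)
  expected <- conc_k * volume * AVOGADRO / (2 * genome$L)
  counts <- stochastic_round(expected)
  keep <- counts > 0
  if (!any(keep))
    stop("degenerate pool: all expected counts rounded to zero; ",
         "increase volume or concentrations")
  frags <- frags[keep, , drop = FALSE]
  counts <- counts[keep]
  act <- stats::rbinom(length(counts), counts, reaction$p_act0)
  sp <- rbind(
    species_frame(frags$seq, "activated_2AI", "diol", FALSE, "", act),
    species_frame(frags$seq, "phosphate", "diol", FALSE, "",
                  counts - act))
  pool <- vcg_pool(aggregate_species(sp), fed = empty_fed(genome$alphabet),
                   volume = volume, alphabet = genome$alphabet)
  pool <- feed_pool(pool, reaction, record = FALSE)
  pool
}

#' Convert a molar concentration to an expected copy number
#'
#' `conc * (4/3) * pi * (d/2)^3 * 1000 * N_A`: the expected number of
#' molecules of a species at concentration `conc` inside a spherical
#' protocell of the given diameter. Returned as a real-valued expectation
#' (1 uM in a 10 um protocell gives 3.15e5 molecules; quoted copy numbers
#' of ~10^6 at this scale are order-of-magnitude figures).
#'
#' @param conc molar concentration (>= 0).
#' @param diameter protocell diameter in meters.
#' @return expected molecule count.
#' @export
concentration_to_copies <- function(conc, diameter) {
  stopifnot(all(conc >= 0), all(diameter > 0))
  conc * protocell_volume(diameter) * AVOGADRO
}

#' Volume in liters of a spherical protocell
#' @param diameter meters.
#' @export
protocell_volume <- function(diameter) {
  (4 / 3) * pi * (diameter / 2)^3 * 1000
}

#' Length distribution of a pool
#'
#' @param pool a [vcg_pool()].
#' @return data.frame with `length`, `count` and `concentration` (molar,
#'   `count / (volume * N_A)`), one row per occupied length class.
#' @export
length_distribution <- function(pool) {
  stopifnot(inherits(pool, "vcg_pool"))
  if (!nrow(pool$species))
    return(data.frame(length = integer(), count = numeric(),
                      concentration = numeric()))
  len <- nchar(pool$species$seq)
  agg <- rowsum(pool$species$count, len)
  data.frame(length = as.integer(rownames(agg)),
             count = as.numeric(agg[, 1]),
             concentration = as.numeric(agg[, 1]) /
               (pool$volume * AVOGADRO))
}

#' Estimate the gradient ratio of a pool
#'
#' Least-squares fit of log counts against length over the occupied length
#' classes; the fitted slope b gives the abundance ratio estimate
#' `exp(-b)` with a delta-method standard error.
#'
#' @param pool a [vcg_pool()].
#' @param min_len,max_len length window used in the fit.
#' @return list with `ratio`, `se` and `n_classes`.
#' @export
estimate_gradient_ratio <- function(pool, min_len = 2, max_len = 12) {
  ld <- length_distribution(pool)
  ld <- ld[ld$length >= min_len & ld$length <= max_len & ld$count > 0, ]
  if (nrow(ld) < 3)
    stop("need at least 3 non-empty length classes to fit a gradient")
  fit <- stats::lm(log(count) ~ length, data = ld)
  slope <- stats::coef(fit)[["length"]]
  se_slope <- suppressWarnings(
    sqrt(stats::vcov(fit)["length", "length"]))
  r <- exp(-slope)
  list(ratio = r, se = r * se_slope, n_classes = nrow(ld))
}

#' Merge two pools (entrywise sums of all species and fed counts)
#' @param a,b pools sharing one volume and alphabet.
#' @return a [vcg_pool()].
#' @export
merge_pools <- function(a, b) {
  stopifnot(inherits(a, "vcg_pool"), inherits(b, "vcg_pool"),
            a$alphabet == b$alphabet)
  out <- vcg_pool(aggregate_species(rbind(a$species, b$species)),
                  fed = list(monomers = a$fed$monomers + b$fed$monomers,
                             bridged = a$fed$bridged + b$fed$bridged),
                  volume = a$volume, alphabet = a$alphabet)
  out$ledger <- Map(`+`, a$ledger, b$ledger)
  out
}

# Chemostat feed: top up fed species to their set-points (uniformly over
# base / dinucleotide species), recording the added nucleotide units in the
# ledger. Feed is the only mass source of the simulation.
feed_pool <- function(pool, reaction, record = TRUE) {
  tgt_mono <- concentration_copies_in(reaction$monomer_feed, pool$volume) /
    length(pool$fed$monomers)
  tgt_bri <- concentration_copies_in(reaction$bridged_feed, pool$volume) /
    length(pool$fed$bridged)
  add_mono <- pmax(0, stochastic_round(
    pmax(0, tgt_mono - pool$fed$monomers)))
  add_bri <- pmax(0, stochastic_round(pmax(0, tgt_bri - pool$fed$bridged)))
  pool$fed$monomers <- pool$fed$monomers + add_mono
  pool$fed$bridged <- pool$fed$bridged + add_bri
  if (record)
    pool$ledger$fed_units <- pool$ledger$fed_units +
      sum(add_mono) + 2 * sum(add_bri)
  pool
}

concentration_copies_in <- function(conc, volume) conc * volume * AVOGADRO
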