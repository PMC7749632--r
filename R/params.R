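# Physical constants
AVOGADRO <- 6.02214076e23       # molecules / mol
R_KCAL   <- 1.987204e-3         # kcal / (mol K)

#' Duplex energy parameters
#'
#' Per-base-pair additive free energy model for inter-oligonucleotide
#' duplexes. Each Watson-Crick pair in a duplex contributes `dG_bp`
#' (kcal/mol, negative) scaled by a pair-type modifier; mismatched positions
#' contribute nothing. The default of -2.5 kcal/mol is the midpoint of the
#' commonly cited 2-3 kcal/mol stabilisation per added base pair for RNA.
#'
#' `pair_modifiers` multiply `dG_bp` for specific pair types and are the hook
#' for variant chemistries: inosine-containing genomes pair I:C more weakly
#' than G:C (default modifier 0.6), and a 2-thio-U alphabet can be emulated
#' by raising the `AU` modifier above 1.
#'
#' `dG_assoc` is the translational association penalty (kcal/mol, positive)
#' paid once per duplex formed. With the default `NULL` it is derived at
#' annealing time from the vesicle volume as -RT*log(1/(V*NA)), i.e. the
#' entropy cost of co-locating two molecules at single-molecule concentration
#' in the protocell; this is what makes two-base-pair contacts mostly
#' transient while 4+ bp duplexes are stable, and it carries the
#' concentration dependence of duplex stability (RT*log terms) into the
#' annealing model.
#'
#' @param dG_bp per-base-pair free energy, kcal/mol; must be negative.
#' @param temperature kelvin.
#' @param pair_modifiers named positive multipliers; names are two-letter
#'   pair codes in either order (`"AU"`, `"GC"`, `"IC"`).
#' @param dG_assoc association penalty in kcal/mol, or `NULL` to derive it
#'   from the pool volume.
#' @return an object of class `vcg_energy_params`.
#' @export
energy_params <- function(dG_bp = -2.5, temperature = 298.15,
                          pair_modifiers = c(AU = 1, GC = 1, IC = 0.6),
                          dG_assoc = NULL) {
  stopifnot(is.numeric(dG_bp), length(dG_bp) == 1L, dG_bp < 0,
            is.numeric(temperature), temperature > 0)
  mods <- c(AU = 1, GC = 1, IC = 0.6)
  if (length(pair_modifiers)) {
    key <- vapply(strsplit(toupper(names(pair_modifiers)), ""),
                  function(x) paste(sort(x), collapse = ""), "")
    canon <- c(AU = "AU", CG = "GC", CI = "IC")
    if (any(!key %in% names(canon)))
      stop("unknown pair modifier: ", paste(names(pair_modifiers), collapse = ", "))
    if (any(pair_modifiers <= 0)) stop("pair modifiers must be > 0")
    mods[canon[key]] <- unname(pair_modifiers)
  }
  structure(list(dG_bp = dG_bp, temperature = temperature,
                 pair_modifiers = mods, dG_assoc = dG_assoc),
            class = "vcg_energy_params")
}

#' @return RT in kcal/mol for the parameter set.
#' @rdname energy_params
#' @export
rt_energy <- function(params) R_KCAL * params$temperature

# Per-pair dG lookup matrix over the base codes of an alphabet (0-based codes
# as used by the C++ kernel). Entry 0 marks a non-pairing combination.
pair_dg_matrix <- function(params, alphabet = "ACGU") {
  b <- alphabet_bases(alphabet)
  n <- length(b)
  m <- matrix(0, n, n, dimnames = list(b, b))
  comp <- complement_map(alphabet)
  mods <- params$pair_modifiers
  for (x in b) {
    y <- comp[[x]]
    key <- paste(sort(c(x, y)), collapse = "")
    mod <- switch(key, AU = mods[["AU"]], CG = mods[["GC"]],
                  CI = mods[["IC"]], 1)
    m[x, y] <- params$dG_bp * mod
  }
  m
}

#' Reaction and fate-process parameters
#'
#' Per-cycle probabilities for the reaction repertoire and the off-template
#' fate processes. Reactions fire as independent Bernoulli trials per
#' classified site per denature/anneal cycle.
#'
#' @param p_ext probability an extension site fires per cycle.
#' @param f_last multiplier (<= 1) applied at last-base sites, where the
#'   incoming bridged dinucleotide can form only one base pair and extension
#'   slows dramatically.
#' @param p_lig probability a ligation site fires; ligation is slow and
#'   inefficient relative to extension.
#' @param p_init probability an initiation site (two adjacent bridged
#'   dinucleotides on an open template stretch) fires.
#' @param eps per-incorporation error rate; on error a uniformly chosen
#'   wrong base is added.
#' @param p_stall_after_mismatch multiplier (<= 1) on the extension
#'   probability of a primer whose last incorporation was a mismatch, until
#'   one further successful extension.
#' @param p_ara probability an incorporation is a chain-terminating
#'   (e.g. arabino-) nucleotide, leaving a blocked 3' terminus.
#' @param k_hyd,k_act per-cycle hydrolysis / re-activation probabilities of
#'   5'-2-aminoimidazole groups; the stationary activated fraction is
#'   k_act / (k_act + k_hyd).
#' @param p_cleave per-internal-bond cleavage probability per denatured
#'   cycle.
#' @param h_cp per-cycle hydrolysis probability of a 2',3'-cyclic phosphate
#'   terminus to a 2'- or 3'-phosphate (equal odds).
#' @param p_pp per-cycle cleavage probability of an internal pyrophosphate
#'   linkage in the single-stranded state.
#' @param p_cyc per-cycle cyclization loss probability for oligos of length
#'   <= `cyc_len`.
#' @param cyc_len maximum length subject to cyclization loss.
#' @param dead_end_len duplex match length at or above which a duplex never
#'   denatures and becomes inert.
#' @param min_duplex minimum matched length of any annealed duplex; the
#'   default of 2 mirrors the two-base-pair template binding of bridged
#'   dinucleotides.
#' @param toehold_min minimum 5'-overhang length (nt) usable as a toehold by
#'   an invader strand.
#' @param p_invade probability that a qualifying toehold invasion displaces
#'   the occluding strand in a cycle.
#' @param p_act0 probability a freshly initialised pool oligo carries an
#'   activated (2AI) 5' phosphate.
#' @param p_ext_purine_mult optional multiplier on `p_ext` when the
#'   templated incoming base is a purine; values > 1 reproduce the
#'   purine-strand abundance bias.
#' @param monomer_feed,bridged_feed chemostat set-points (molar, totals over
#'   species) to which activated monomers and imidazolium-bridged
#'   dinucleotides are replenished at each cycle's feed step.
#' @return an object of class `vcg_reaction_params`.
#' @export
reaction_params <- function(p_ext = 0.5, f_last = 0.1, p_lig = 0.05,
                            p_init = 0.02, eps = 0,
                            p_stall_after_mismatch = 0.1, p_ara = 0,
                            k_hyd = 0.1, k_act = 0.1, p_cleave = 0.001,
                            h_cp = 0.1, p_pp = 0.5, p_cyc = 0.005,
                            cyc_len = 3, dead_end_len = 12, min_duplex = 2,
                            toehold_min = 3, p_invade = 0.5, p_act0 = 0.5,
                            p_ext_purine_mult = 1,
                            monomer_feed = 5e-3, bridged_feed = 1e-3) {
  p <- list(p_ext = p_ext, f_last = f_last, p_lig = p_lig, p_init = p_init,
            eps = eps, p_stall_after_mismatch = p_stall_after_mismatch,
            p_ara = p_ara, k_hyd = k_hyd, k_act = k_act,
            p_cleave = p_cleave, h_cp = h_cp, p_pp = p_pp, p_cyc = p_cyc,
            cyc_len = cyc_len, dead_end_len = dead_end_len,
            min_duplex = min_duplex, toehold_min = toehold_min,
            p_invade = p_invade, p_act0 = p_act0,
            p_ext_purine_mult = p_ext_purine_mult,
            monomer_feed = monomer_feed, bridged_feed = bridged_feed)
  probs <- c("p_ext", "f_last", "p_lig", "p_init", "eps",
             "p_stall_after_mismatch", "p_ara", "k_hyd", "k_act",
             "p_cleave", "h_cp", "p_pp", "p_cyc", "p_invade", "p_act0")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  stopifnot(p$cyc_len >= 1, p$dead_end_len >= 2, p$min_duplex >= 2,
            p$toehold_min >= 1, p$p_ext_purine_mult >= 0,
            p$monomer_feed >= 0, p$bridged_feed >= 0)
  class(p) <- "vcg_reaction_params"
  p
}

#' Bundle energy and reaction parameters for a simulation
#'
#' @param energy a [energy_params()] object.
#' @param reaction a [reaction_params()] object.
#' @return an object of class `vcg_sim_params`.
#' @export
sim_params <- function(energy = energy_params(),
                       reaction = reaction_params()) {
  stopifnot(inherits(energy, "vcg_energy_params"),
            inherits(reaction, "vcg_reaction_params"))
  structure(list(energy = energy, reaction = reaction),
            class = "vcg_sim_params")
}

# Derive a 31-bit substream seed from a master seed and a stream name, so
# that the annealing, chemistry, division and fixture streams are decoupled
# but fully determined by the master seed.
substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 69069 + h * 104729) %% 2147483647)
}

# Stochastic rounding: floor(x) + Bernoulli(frac(x)), preserving expectation
# for sub-integer expected molecule counts.
stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}
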