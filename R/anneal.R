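# Expand a pool's species multiset into one row per molecule (the
# representation used during a denature/anneal cycle) and compact back.
expand_pool <- function(pool) {
  sp <- pool$species
  if (!nrow(sp)) return(sp[0, names(sp) != "count"])
  idx <- rep(seq_len(nrow(sp)), times = sp$count)
  mol <- sp[idx, names(sp) != "count", drop = FALSE]
  rownames(mol) <- NULL
  mol
}

compact_molecules <- function(mol, pool) {
  if (nrow(mol)) mol$count <- 1 else mol$count <- numeric(0)
  pool$species <- aggregate_species(mol)
  pool
}

#' Duplex free energy of one antiparallel alignment
#'
#' Sums the per-pair free energies over the Watson-Crick matched positions
#' of the overlap between `seq_a` and `seq_b` at the given alignment;
#' mismatched positions contribute nothing. The alignment convention:
#' the 3'-terminal base of `seq_a` pairs position `offset` (0-based) of
#' `seq_b`, and earlier bases of `seq_a` pair successively higher
#' positions of `seq_b`.
#'
#' @param seq_a,seq_b sequences written 5'->3'.
#' @param offset 0-based position of `seq_b` paired with the 3' end of
#'   `seq_a`.
#' @param params an [energy_params()].
#' @param alphabet pairing alphabet.
#' @return free energy in kcal/mol (0 for zero overlap).
#' @export
duplex_energy <- function(seq_a, seq_b, offset = 0,
                          params = energy_params(), alphabet = "ACGU") {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  dg <- pair_dg_matrix(params, alphabet)
  la <- length(a)
  e <- 0
  for (t in 0:(la - 1)) {
    ia <- la - t            # 1-based index into a (3' end first)
    ib <- offset + t + 1    # 1-based index into b
    if (ia < 1 || ib < 1 || ib > length(b)) next
    e <- e + dg[a[ia], b[ib]]
  }
  e
}

#' Anneal a pool into one kinetically trapped duplex configuration
#'
#' Models the return to annealing conditions after a denaturing
#' environmental spike. All maximal perfectly complementary runs of at
#' least `min_duplex` base pairs between molecule pairs are candidate
#' duplexes; they form
#' in a random order biased by their Boltzmann weights
#' `exp((-dG - dG_assoc)/RT)`, each molecule also carrying a unit-weight
#' "stay unbound" alternative. Accepted duplexes lock their template
#' positions (no position is claimed twice) and molecule roles (an oligo
#' bound to a template neither templates others nor binds elsewhere). The
#' result is one sampled metastable configuration, not the thermodynamic
#' minimum.
#'
#' @param pool a [vcg_pool()].
#' @param params an [energy_params()] (or a [sim_params()], whose `energy`
#'   and `reaction` components are used).
#' @param seed optional integer seed.
#' @param min_duplex minimum matched duplex length (ignored when a
#'   [sim_params()] is given, which carries its own).
#' @return an object of class `vcg_duplex_config`: list with `mol` (the
#'   expanded molecule table), `bindings` (data.frame `templ`, `oligo`,
#'   `t_start`, `o_start`, `len`, `energy`; molecule ids are row indices
#'   into `mol`, positions 0-based on the template), and `unbound`.
#' @export
anneal <- function(pool, params = energy_params(), seed = NULL,
                   min_duplex = 2) {
  if (inherits(params, "vcg_sim_params")) {
    min_duplex <- params$reaction$min_duplex
    params <- params$energy
  }
  stopifnot(inherits(pool, "vcg_pool"),
            inherits(params, "vcg_energy_params"))
  if (!is.null(seed)) set.seed(seed)
  mol <- expand_pool(pool)
  if (!nrow(mol)) {
    return(new_duplex_config(mol, empty_bindings(), logical(0),
                             pool$alphabet))
  }
  dg <- pair_dg_matrix(params, pool$alphabet)
  enc <- encode_seqs(mol$seq, pool$alphabet)
  rt <- rt_energy(params)
  dga <- params$dG_assoc
  if (is.null(dga)) dga <- -rt * log(1 / (pool$volume * AVOGADRO))
  res <- anneal_cpp(enc, dg, as.integer(min_duplex), rt, dga)
  new_duplex_config(mol, res$bindings, res$unbound, pool$alphabet)
}

empty_bindings <- function() {
  data.frame(templ = integer(), oligo = integer(), t_start = integer(),
             o_start = integer(), len = integer(), energy = numeric())
}

#' Construct a duplex configuration directly
#'
#' Mainly useful for building small scenarios by hand (tests, worked
#' figures); [anneal()] is the sampling route.
#'
#' @param mol molecule data.frame (`seq`, `p5`, `p3`, `stalled`, `pp`).
#' @param bindings data.frame with `templ`, `oligo` (row indices into
#'   `mol`), `t_start`, `o_start` (0-based), `len`.
#' @param alphabet pairing alphabet.
#' @export
duplex_config <- function(mol, bindings = empty_bindings(),
                          alphabet = "ACGU") {
  if (!nrow(bindings)) bindings <- empty_bindings()
  if (is.null(bindings$energy)) bindings$energy <- NA_real_
  unbound <- !(seq_len(nrow(mol)) %in%
                 c(bindings$templ, bindings$oligo))
  new_duplex_config(mol, bindings, unbound, alphabet)
}

new_duplex_config <- function(mol, bindings, unbound, alphabet) {
  structure(list(mol = mol, bindings = bindings, unbound = unbound,
                 alphabet = alphabet),
            class = "vcg_duplex_config")
}

#' @export
print.vcg_duplex_config <- function(x, ...) {
  cat("Duplex configuration: ", nrow(x$mol), " molecules, ",
      nrow(x$bindings), " duplexes, ", sum(x$unbound), " unbound\n",
      sep = "")
  invisible(x)
}

# Per-molecule paired-position masks (list of logical vectors, 1-based):
# for each duplex both the template run and the bound oligo's paired region
# are marked, so free stretches on either strand can be found uniformly.
coverage_masks <- function(config) {
  cov <- lapply(nchar(config$mol$seq), logical)
  b <- config$bindings
  for (i in seq_len(nrow(b))) {
    t <- b$templ[i]
    o <- b$oligo[i]
    cov[[t]][(b$t_start[i] + 1):(b$t_start[i] + b$len[i])] <- TRUE
    cov[[o]][(b$o_start[i] + 1):(b$o_start[i] + b$len[i])] <- TRUE
  }
  cov
}

mol_bound_as_oligo <- function(config) {
  seq_len(nrow(config$mol)) %in% config$bindings$oligo
}

#' Classify the reaction sites of a duplex configuration
#'
#' Each paired recessed 3' end is a primer: a bound oligo whose 3'-terminal
#' base is paired extends along the template's free downstream positions,
#' and symmetrically a template whose own 3' end is paired extends along
#' the bound oligo's unpaired 5' tail. Each primer yields at most one
#' site: an *extension* site if the template has a downstream
#' overhang of at least one free position and a complementary
#' imidazolium-bridged dinucleotide is in stock (an overhang of exactly one
#' free position is flagged `last_base`: the dinucleotide can pair only one
#' base and extension slows dramatically); a *ligation* site if a
#' 5'-activated oligo is bound contiguously downstream (zero gap);
#' otherwise the primer is *blocked*. Both productive kinds additionally
#' require an extendable 3' terminus (2',3'-diol or 3'-phosphate).
#' *Initiation* sites are open template stretches of >= 4 free positions
#' whose first window can seat two adjacent complementary bridged
#' dinucleotides from stock.
#'
#' @param config a `vcg_duplex_config`.
#' @param pool the [vcg_pool()] supplying the fed species.
#' @param params a [reaction_params()] (or [sim_params()]).
#' @return data.frame of sites: `kind` (`extension`, `ligation`,
#'   `initiation`, `blocked`), `primer`, `templ` (the strand being read),
#'   `binding`, `role` (which duplex strand is the primer), `overhang`,
#'   `last_base`, `t_next`, `down_binding`, `d1`, `d2`.
#' @export
classify_sites <- function(config, pool, params = reaction_params()) {
  if (inherits(params, "vcg_sim_params")) params <- params$reaction
  mol <- config$mol
  b <- config$bindings
  comp <- complement_map(config$alphabet)
  cov <- coverage_masks(config)
  tchars <- strsplit(mol$seq, "")
  mol_len <- nchar(mol$seq)
  bridged <- pool$fed$bridged
  bridged_first <- rowsum(bridged, substr(names(bridged), 1L, 1L))

  cap <- 2L * nrow(b) + nrow(mol) + 8L
  kind <- character(cap); primer <- integer(cap); templ <- integer(cap)
  binding <- integer(cap); role <- character(cap)
  overhang <- integer(cap); last_base <- logical(cap)
  t_next_v <- integer(cap); down_b <- integer(cap)
  d1_v <- character(cap); d2_v <- character(cap)
  n <- 0L
  add <- function(k, pr, tm, bi, ro, ov, lb, tn, db, d1, d2) {
    n <<- n + 1L
    kind[n] <<- k; primer[n] <<- pr; templ[n] <<- tm; binding[n] <<- bi
    role[n] <<- ro; overhang[n] <<- ov; last_base[n] <<- lb
    t_next_v[n] <<- tn; down_b[n] <<- db; d1_v[n] <<- d1; d2_v[n] <<- d2
  }

  # A duplex presents up to two primers: the bound oligo (extending along
  # the template's free downstream positions) and, symmetrically, the
  # template strand itself when its own 3' end is paired (extending along
  # the oligo's unpaired 5' tail).
  classify_primer <- function(i, ro) {
    if (ro == "oligo") {
      pr <- b$oligo[i]; tm <- b$templ[i]
      three_paired <- (b$o_start[i] + b$len[i]) == mol_len[pr]
      t_next <- b$t_start[i] - 1L
      ov <- 0L
      q <- t_next
      cv <- cov[[tm]]
      while (q >= 0L && !cv[q + 1L]) { ov <- ov + 1L; q <- q - 1L }
    } else {
      pr <- b$templ[i]; tm <- b$oligo[i]
      three_paired <- (b$t_start[i] + b$len[i]) == mol_len[pr]
      t_next <- b$o_start[i] - 1L
      ov <- b$o_start[i]  # the oligo's 5' tail is free in a pairwise duplex
    }
    if (!three_paired) return(invisible())
    if (extendable_3p(mol$p3[pr])) {
      if (ov >= 1L) {
        x <- comp[[tchars[[tm]][t_next + 1L]]]
        if (ov >= 2L) {
          y <- comp[[tchars[[tm]][t_next]]]  # position t_next - 1 (0-based)
          key <- paste0(x, y)
          if (bridged[[key]] > 0)
            return(add("extension", pr, tm, i, ro, ov, FALSE, t_next,
                       NA_integer_, key, NA_character_))
        } else if (bridged_first[x, 1L] > 0) {
          return(add("extension", pr, tm, i, ro, ov, TRUE, t_next,
                     NA_integer_, NA_character_, NA_character_))
        }
      } else if (ro == "oligo") {
        # zero overhang: contiguous downstream oligo with activated 5' end?
        down <- which(b$templ == b$templ[i] &
                        b$t_start + b$len == b$t_start[i] & b$o_start == 0L)
        down <- down[ligatable_5p(mol$p5[b$oligo[down]])]
        if (length(down))
          return(add("ligation", pr, tm, i, ro, 0L, FALSE, NA_integer_,
                     down[1L], NA_character_, NA_character_))
      }
    }
    add("blocked", pr, tm, i, ro, ov, FALSE, NA_integer_, NA_integer_,
        NA_character_, NA_character_)
    invisible()
  }

  for (i in seq_len(nrow(b))) {
    classify_primer(i, "oligo")
    classify_primer(i, "templ")
  }

  # initiation: open single-stranded stretches >= 4 nt anywhere — gaps on
  # templates, unpaired 5' tails of bound oligos, and free molecules alike
  for (t in seq_len(nrow(mol))) {
    free <- !cov[[t]]
    if (length(free) < 4L) next
    r <- rle(free)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < 4L) next
      q <- starts[j] - 1L  # 0-based stretch start; use its first 4-window
      tc <- tchars[[t]]
      d1 <- paste0(comp[[tc[q + 4L]]], comp[[tc[q + 3L]]])
      d2 <- paste0(comp[[tc[q + 2L]]], comp[[tc[q + 1L]]])
      need2 <- if (d1 == d2) 2 else 1
      if (bridged[[d1]] >= need2 && bridged[[d2]] >= 1)
        add("initiation", NA_integer_, t, NA_integer_, "templ",
            r$lengths[j], FALSE, q, NA_integer_, d1, d2)
    }
  }

  idx <- seq_len(n)
  data.frame(kind = kind[idx], primer = primer[idx], templ = templ[idx],
             binding = binding[idx], role = role[idx],
             overhang = overhang[idx], last_base = last_base[idx],
             t_next = t_next_v[idx], down_binding = down_b[idx],
             d1 = d1_v[idx], d2 = d2_v[idx], stringsAsFactors = FALSE)
}

#' Open occluded templates by toehold strand invasion
#'
#' For each blocked primer whose downstream template position is occluded
#' by another duplex, checks whether the occluding strand exposes a
#' 5'-overhang toehold of at least `toehold_min` unpaired nucleotides that
#' is complementary to some free invader oligo. If so, with probability
#' `p_invade` the occluding strand is displaced: its binding is removed and
#' it is re-annealed locally onto the invader, converting the nonproductive
#' configuration into a productive one.
#'
#' @param config a `vcg_duplex_config`.
#' @param pool the [vcg_pool()] (fed species, volume, alphabet).
#' @param params a [reaction_params()] (or [sim_params()]).
#' @param seed optional integer seed.
#' @return the updated `vcg_duplex_config`.
#' @export
invasion_open <- function(config, pool, params = reaction_params(),
                          seed = NULL) {
  if (inherits(params, "vcg_sim_params")) {
    energy <- params$energy
    params <- params$reaction
  } else energy <- energy_params()
  if (!is.null(seed)) set.seed(seed)
  if (params$p_invade <= 0 || !nrow(config$bindings)) return(config)
  mol <- config$mol
  b <- config$bindings
  cov <- coverage_masks(config)
  dg <- pair_dg_matrix(energy, config$alphabet)
  enc <- encode_seqs(mol$seq, config$alphabet)
  drop_bind <- integer(0)
  new_bind <- list()
  claimed_invaders <- integer(0)

  for (i in seq_len(nrow(b))) {
    o <- b$oligo[i]; t <- b$templ[i]
    if ((b$o_start[i] + b$len[i]) != nchar(mol$seq[o])) next
    if (!extendable_3p(mol$p3[o])) next
    t_next <- b$t_start[i] - 1L
    if (t_next < 0L || !cov[[t]][t_next + 1L]) next  # not occluded
    occ <- which(b$templ == t & b$t_start <= t_next &
                   b$t_start + b$len > t_next)
    occ <- setdiff(occ, c(i, drop_bind))
    if (!length(occ)) next
    occ <- occ[1L]
    od <- b$oligo[occ]
    toehold <- b$o_start[occ]  # unpaired 5' region of the occluder
    if (toehold < params$toehold_min) next
    # free invaders complementary to >= toehold_min nt of the 5' tail
    free_idx <- setdiff(which(config$unbound), claimed_invaders)
    hit <- NULL
    for (v in free_idx) {
      runs <- complementary_runs_cpp(enc[[v]], enc[[od]], dg,
                                     as.integer(params$toehold_min))
      runs <- runs[runs$t_start < toehold, , drop = FALSE]
      if (nrow(runs)) {
        runs <- runs[order(runs$energy), , drop = FALSE]
        hit <- list(v = v, run = runs[1L, ])
        break
      }
    }
    if (is.null(hit)) next
    if (stats::runif(1) > params$p_invade) next
    drop_bind <- c(drop_bind, occ)
    claimed_invaders <- c(claimed_invaders, hit$v)
    new_bind[[length(new_bind) + 1L]] <- data.frame(
      templ = od, oligo = hit$v, t_start = hit$run$t_start,
      o_start = hit$run$o_start, len = hit$run$len,
      energy = hit$run$energy)
  }
  if (!length(drop_bind)) return(config)
  b <- b[-drop_bind, , drop = FALSE]
  b <- rbind(b, do.call(rbind, new_bind))
  rownames(b) <- NULL
  unbound <- !(seq_len(nrow(mol)) %in% c(b$templ, b$oligo))
  new_duplex_config(mol, b, unbound, config$alphabet)
}
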